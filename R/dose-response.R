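# Four-parameter logistic dose-response modelling.
#
# r(x) = bottom + (top - bottom) / (1 + (x / mid)^slope)
# With slope > 0 the curve falls from `top` (x -> 0) to `bottom`
# (x -> Inf) and `mid` is the IC50; slope < 0 gives a rising curve with
# `mid` as EC50.

.logistic4 <- function(x, bottom, top, mid, slope) {
  ratio <- ifelse(x == 0, if (slope > 0) 0 else Inf, (x / mid)^slope)
  bottom + (top - bottom) / (1 + ratio)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Deterministic least-squares fit of
#' `r(x) = bottom + (top - bottom) / (1 + (x / mid)^slope)` to
#' concentration/response data (growth inhibition for IC50, or any other
#' sigmoidal readout). Initialization is rule-based so identical data always
#' give identical fits: bottom/top from the response extremes, `mid` by
#' log-interpolating the concentration at half-range (zero doses are offset
#' by half the smallest nonzero dose for initialization only; the model is
#' evaluated at x = 0 exactly), slope magnitude 1 with sign from the
#' observed trend. Non-convergence and flat data are flagged, not raised.
#'
#' @param concentration Dose vector in uM (>= 0); replicates are passed as
#'   repeated concentrations.
#' @param response Response vector, same length.
#' @return An object of class `"fit4pl"` with components `coefficients`
#'   (`bottom, top, mid, slope`; `mid` is the IC50/EC50 in uM), `fitted`,
#'   `residuals`, `resid_norm`, `converged`, `flat`, and the data. All
#'   standard accessors work: [coef()], [predict()], [residuals()],
#'   `summary()`, `plot()`.
#' @examples
#' x <- c(0, 0.5, 1, 2, 4, 8, 16, 32)
#' y <- 1 / (1 + (x / 4.6)^1.5)
#' coef(fit_4pl(x, y))
#' @export
fit_4pl <- function(concentration, response) {
  if (length(concentration) != length(response))
    stop("`concentration` and `response` must have the same length")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  keep <- is.finite(concentration) & is.finite(response)
  x <- concentration[keep]; y <- response[keep]
  if (length(unique(x)) < 4)
    stop("need >= 4 distinct concentrations to fit a 4PL")

  out <- structure(list(coefficients = NULL, data = data.frame(
    concentration = x, response = y), fitted = NULL, residuals = NULL,
    resid_norm = NA_real_, converged = FALSE, flat = FALSE),
    class = "fit4pl")

  rng <- diff(range(y))
  if (rng <= 1e-10 * max(1, max(abs(y)))) {
    out$flat <- TRUE
    return(out)
  }

  # deterministic initialization
  xz <- x; xz[xz == 0] <- min(x[x > 0]) / 2
  mu <- tapply(y, x, mean)
  xs <- sort(unique(x)); xs0 <- xs; xs0[xs0 == 0] <- min(x[x > 0]) / 2
  half <- (max(mu) + min(mu)) / 2
  below <- which(mu[as.character(xs)] <= half)
  mid0 <- if (length(below) && length(below) < length(xs)) {
    i <- below[1]
    if (i == 1) xs0[1] else {
      # log-interpolate between the doses bracketing the half-range
      y1 <- mu[as.character(xs[i - 1])]; y2 <- mu[as.character(xs[i])]
      w <- (y1 - half) / max(y1 - y2, .Machine$double.eps)
      exp((1 - w) * log(xs0[i - 1]) + w * log(xs0[i]))
    }
  } else exp(mean(log(xs0)))
  slope0 <- if (cor(log(xz), y) < 0) 1 else -1
  # a fixed ladder of fallback starts guards against the occasional
  # singular numeric gradient at an otherwise reasonable start
  starts <- list(
    list(bottom = min(y), top = max(y), mid = unname(mid0), slope = slope0),
    list(bottom = min(y), top = max(y), mid = unname(mid0),
         slope = 1.2 * slope0),
    list(bottom = min(y), top = max(y), mid = 2 * unname(mid0),
         slope = slope0),
    list(bottom = min(y), top = max(y), mid = unname(mid0) / 2,
         slope = 0.8 * slope0))
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (x / mid)^slope),
        start = start,
        lower = c(bottom = -Inf, top = -Inf, mid = 1e-12, slope = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(out)
  par <- coef(fit)
  # canonical form: bottom <= top (swapping bottom/top and negating the
  # slope leaves the curve unchanged)
  if (par["bottom"] > par["top"]) {
    par[c("bottom", "top")] <- par[c("top", "bottom")]
    par["slope"] <- -par["slope"]
  }
  out$coefficients <- par
  out$fitted <- .logistic4(x, par["bottom"], par["top"], par["mid"],
                           par["slope"])
  out$residuals <- y - out$fitted
  out$resid_norm <- sqrt(sum(out$residuals^2))
  out$converged <- TRUE
  out
}

#' @export
print.fit4pl <- function(x, ...) {
  if (x$flat) {
    cat("fit4pl: flat data, no parameters estimated\n")
  } else if (!x$converged) {
    cat("fit4pl: fit did not converge\n")
  } else {
    p <- x$coefficients
    cat(sprintf(
      "fit4pl: bottom %.4g, top %.4g, mid (IC50/EC50) %.4g uM, slope %.4g\n",
      p["bottom"], p["top"], p["mid"], p["slope"]))
    cat(sprintf("residual norm %.4g on %d observations\n",
                x$resid_norm, nrow(x$data)))
  }
  invisible(x)
}

#' @export
coef.fit4pl <- function(object, ...) object$coefficients

#' @export
residuals.fit4pl <- function(object, ...) object$residuals

#' @export
predict.fit4pl <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  x <- if (is.null(newdata)) object$data$concentration
  else if (is.data.frame(newdata)) newdata$concentration
  else newdata
  p <- object$coefficients
  .logistic4(x, p["bottom"], p["top"], p["mid"], p["slope"])
}

#' @export
summary.fit4pl <- function(object, ...) {
  structure(list(fit = object), class = "summary.fit4pl")
}

#' @export
print.summary.fit4pl <- function(x, ...) {
  print(x$fit)
  if (x$fit$converged) {
    cat("residual quartiles:\n")
    print(quantile(x$fit$residuals))
  }
  invisible(x)
}

#' @export
plot.fit4pl <- function(x, ...) {
  d <- x$data
  xpos <- d$concentration
  xpos[xpos == 0] <- min(d$concentration[d$concentration > 0]) / 2
  plot(xpos, d$response, log = "x", xlab = "concentration (uM)",
       ylab = "response", ...)
  if (x$converged) {
    grid_x <- exp(seq(log(min(xpos)), log(max(xpos)), length.out = 200))
    lines(grid_x, predict(x, grid_x))
    abline(v = x$coefficients["mid"], lty = 2)
  }
  invisible(x)
}

#' Dose-dependent induction profile with shape classification
#'
#' Converts per-dose metabolite intensities to fold changes over the
#' uninduced control, `(I + c) / (I_ctrl + c)` with pseudo-count
#' `c = pseudo_frac * control`, and classifies the profile shape:
#' `"flat"` when no dose reaches `flat_fold`; `"biphasic"` when the maximum
#' sits at an interior dose and the top dose has dropped to at most half of
#' it (the signature of induction that collapses at growth-inhibitory
#' doses); `"monotone"` otherwise.
#'
#' @param concentration Dose grid (replicated entries allowed; replicates
#'   are aggregated by median).
#' @param intensity Metabolite intensities, same length.
#' @param control_intensity Uninduced (zero-dose) intensity.
#' @param pseudo_frac Pseudo-count fraction (default 0.05).
#' @param flat_fold Maximum fold below which the profile is flat
#'   (default 1.5).
#' @return A list of class `"induction_profile"`: `profile` (data frame
#'   `concentration, fold`) and `shape`.
#' @export
induction_profile <- function(concentration, intensity, control_intensity,
                              pseudo_frac = 0.05, flat_fold = 1.5) {
  if (length(concentration) != length(intensity))
    stop("`concentration` and `intensity` must have the same length")
  if (control_intensity < 0) stop("control intensity must be >= 0")
  c0 <- pseudo_frac * control_intensity
  if (c0 <= 0) c0 <- pseudo_frac * max(median(intensity), 1)
  med <- tapply(intensity, concentration, median)
  conc <- as.numeric(names(med))
  ord <- order(conc)
  conc <- conc[ord]; med <- as.numeric(med)[ord]
  fold <- (med + c0) / (control_intensity + c0)
  imax <- which.max(fold)
  shape <- if (max(fold) < flat_fold) "flat"
  else if (imax < length(fold) && imax > 1 &&
           fold[length(fold)] <= fold[imax] / 2) "biphasic"
  else "monotone"
  structure(list(profile = data.frame(concentration = conc, fold = fold),
                 shape = shape),
            class = "induction_profile")
}

#' @export
print.induction_profile <- function(x, ...) {
  cat(sprintf("induction_profile: shape %s, max fold %.2f at %.3g uM\n",
              x$shape, max(x$profile$fold),
              x$profile$concentration[which.max(x$profile$fold)]))
  invisible(x)
}
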