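# Writes minimal centroided (or profile-flagged) mzML files for the
# import tests, using base64-encoded uncompressed 64-bit arrays.

b64_doubles <- function(x)
  jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                endian = "little"))

write_mini_mzml <- function(path, scans, centroided = TRUE) {
  mode_cv <- if (centroided)
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  spec <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    mzb <- b64_doubles(s$mz); inb <- b64_doubles(s$intensity)
    sprintf('
      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">
        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>
        %s
        <scanList count="1">
          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>
          <scan>
            <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
            <binary>%s</binary>
          </binaryDataArray>
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
            <binary>%s</binary>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
      i - 1L, i, length(s$mz), mode_cv, s$rt_sec,
      nchar(mzb), mzb, nchar(inb), inb)
  }, character(1))
  xml <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
    </fileContent>
  </fileDescription>
  <softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="writer"/></software></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="%d" defaultDataProcessingRef="dp">%s
    </spectrumList>
  </run>
</mzML>', length(scans), paste(spec, collapse = ""))
  writeLines(xml, path)
  invisible(path)
}
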