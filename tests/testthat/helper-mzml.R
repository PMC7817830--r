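# Minimal mzML writer used only to build test fixtures for the mzML
# reading path (uncompressed 64-bit little-endian arrays).

.mzml_b64 <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

.mzml_spectrum <- function(i, ms_level, rt, mz, int, lo = NA, hi = NA) {
  prec <- ""
  if (ms_level == 2) {
    prec <- sprintf(paste0(
      '<precursorList count="1"><precursor><isolationWindow>',
      '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%g"/>',
      '<cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="%g"/>',
      '<cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="%g"/>',
      '</isolationWindow><selectedIonList count="1"><selectedIon>',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%g"/>',
      '</selectedIon></selectedIonList><activation>',
      '<cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation" value=""/>',
      '</activation></precursor></precursorList>'),
      (lo + hi) / 2, (hi - lo) / 2, (hi - lo) / 2, (lo + hi) / 2)
  }
  b_mz <- .mzml_b64(mz)
  b_in <- .mzml_b64(int)
  sprintf(paste0(
    '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '<scanList count="1"><scan>',
    '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%g" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>',
    '</scan></scanList>%s<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
    '<binary>%s</binary></binaryDataArray>',
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    '<binary>%s</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    i, i + 1, length(mz), ms_level, rt, prec,
    nchar(b_mz), b_mz, nchar(b_in), b_in)
}

# run: a spectrum_run tibble (as produced by simulate_dia)
write_test_mzml <- function(run, path) {
  ord <- order(run$cycle, run$ms_level, run$window_id, na.last = FALSE)
  run <- run[ord, ]
  specs <- vapply(seq_len(nrow(run)), function(i) {
    .mzml_spectrum(i - 1, run$ms_level[i], run$rt_s[i],
                   run$mz[[i]], run$intensity[[i]],
                   run$window_low[i], run$window_high[i])
  }, character(1))
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="branchms"/>',
    '</software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">\n%s\n',
    '</spectrumList></run></mzML>'),
    nrow(run), paste(specs, collapse = "\n"))
  writeLines(doc, path)
  invisible(path)
}
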