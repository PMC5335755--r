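## shared small fixtures, built in code

## a spectrum with explicit fields, terse
spec <- function(mz, int = rep(1, length(mz)), scan = 1L, premz = 500,
                 charge = 2L, rt = NA_real_) {
  Spectrum(mz = mz, intensity = int, scanNumber = scan, precursorMz = premz,
           precursorCharge = charge, retentionTime = rt)
}

## minimal mzML 1.1 document for round-trip tests; spectra is a list of
## lists(msLevel, scan, premz, charge, rt, mz, int); arrays are uncompressed
## little-endian base64
writeTestMzML <- function(spectra, path, zlib = FALSE) {
  enc <- function(x, size) {
    raw <- writeBin(as.numeric(x), raw(), size = size, endian = "little")
    if (zlib) raw <- memCompress(raw, type = "gzip")
    jsonlite::base64_enc(raw)
  }
  comp <- if (zlib)
    '<cvParam accession="MS:1000574" name="zlib compression" value=""/>'
  else
    '<cvParam accession="MS:1000576" name="no compression" value=""/>'
  blocks <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    pre <- if (s$msLevel == 2) sprintf('
      <precursorList count="1"><precursor><selectedIonList count="1">
        <selectedIon>
          <cvParam accession="MS:1000744" name="selected ion m/z" value="%.10g"/>
          %s
        </selectedIon>
      </selectedIonList></precursor></precursorList>',
      s$premz,
      if (is.null(s$charge) || is.na(s$charge)) ""
      else sprintf('<cvParam accession="MS:1000041" name="charge state" value="%d"/>',
                   s$charge)) else ""
    rt <- if (!is.null(s$rt) && !is.na(s$rt)) sprintf('
      <scanList count="1"><scan>
        <cvParam accession="MS:1000016" name="scan start time" value="%.10g"
                 unitAccession="UO:0000010" unitName="second"/>
      </scan></scanList>', s$rt) else ""
    sprintf('
    <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">
      <cvParam accession="MS:1000511" name="ms level" value="%d"/>
      %s%s
      <binaryDataArrayList count="2">
        <binaryDataArray>
          <cvParam accession="MS:1000523" name="64-bit float" value=""/>
          %s
          <cvParam accession="MS:1000514" name="m/z array" value=""/>
          <binary>%s</binary>
        </binaryDataArray>
        <binaryDataArray>
          <cvParam accession="MS:1000521" name="32-bit float" value=""/>
          %s
          <cvParam accession="MS:1000515" name="intensity array" value=""/>
          <binary>%s</binary>
        </binaryDataArray>
      </binaryDataArrayList>
    </spectrum>', i - 1L, s$scan, length(s$mz), s$msLevel, rt, pre,
      comp, enc(s$mz, 8L), comp, enc(s$int, 4L))
  }, character(1))
  doc <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <run id="testrun">
    <spectrumList count="%d">%s
    </spectrumList>
  </run>
</mzML>', length(spectra), paste(blocks, collapse = ""))
  writeLines(doc, path)
  invisible(path)
}

## small synthetic config for fast tests
tinyConfig <- function(seed = 42, ...) {
  syntheticConfig(nSpecies = 2, replicatesPerSpecies = 2, spectraPerRun = 30,
                  peaksPerSpectrum = c(8, 15), seed = seed, ...)
}

## does every species form its own clade? true iff, for each group, the
## largest within-group cophenetic distance is below the smallest cophenetic
## distance to any leaf outside the group
groupsFormClades <- function(tree, groups) {
  cm <- copheneticMatrix(tree)
  labs <- rownames(cm)
  for (g in unique(groups)) {
    inside <- labs[groups == g]
    outside <- setdiff(labs, inside)
    if (length(inside) < 2 || length(outside) == 0) next
    if (max(cm[inside, inside]) >= min(cm[inside, outside]))
      return(FALSE)
  }
  TRUE
}
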