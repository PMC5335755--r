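#' @include AllClasses.R
NULL

#' Read a Mascot generic format (MGF) peak list
#'
#' Parses `BEGIN IONS`/`END IONS` blocks into one [Spectrum] each. `PEPMASS`
#' (first field) gives the precursor m/z and is required; `CHARGE` (`2+`,
#' `3+`, or a bare integer) gives the precursor charge, absent charge is kept
#' as unknown; the scan number is taken from `SCANS`, else from a
#' `scan=<int>` token in `TITLE`, else the block order; `RTINSECONDS` gives
#' the retention time. Peaks are sorted ascending by m/z when needed; blocks
#' with zero peaks are retained (preprocessing excludes them later).
#'
#' @param path path to an MGF file.
#' @param runId run identifier; defaults to the file name without extension.
#' @return An [MsRun].
#' @examples
#' mgf <- system.file("extdata", "example.mgf", package = "disms2")
#' run <- readMgf(mgf)
#' nSpectra(run)
#' @export
readMgf <- function(path, runId = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(runId))
        runId <- tools::file_path_sans_ext(basename(path))
    lines <- readLines(path)
    begins <- which(lines == "BEGIN IONS")
    ends <- which(lines == "END IONS")
    if (length(begins) != length(ends) || any(ends < begins))
        stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
    spectra <- vector("list", length(begins))
    for (b in seq_along(begins)) {
        body <- lines[seq.int(begins[b] + 1L, ends[b] - 1L)]
        body <- body[nzchar(body)]
        isKey <- grepl("^[A-Za-z][A-Za-z0-9_]*=", body)
        keys <- body[isKey]
        kv <- regmatches(keys, regexpr("=", keys), invert = TRUE)
        keymap <- stats::setNames(
            vapply(kv, function(x) if (length(x) == 2L) x[2] else "", ""),
            vapply(kv, `[`, "", 1L))
        if (!"PEPMASS" %in% names(keymap))
            stop("malformed MGF block ", b, ": missing PEPMASS")
        pepmass <- as.numeric(strsplit(trimws(keymap[["PEPMASS"]]),
                                       "[ \t]+")[[1]][1])
        if (is.na(pepmass))
            stop("malformed MGF block ", b, ": unparseable PEPMASS")
        charge <- NA_integer_
        if ("CHARGE" %in% names(keymap)) {
            cs <- trimws(keymap[["CHARGE"]])
            charge <- as.integer(sub("^([0-9]+)\\+?$", "\\1", cs))
            if (is.na(charge))
                stop("malformed MGF block ", b, ": unparseable CHARGE '", cs, "'")
        }
        scan <- NA_integer_
        if ("SCANS" %in% names(keymap))
            scan <- as.integer(keymap[["SCANS"]])
        else if ("TITLE" %in% names(keymap) &&
                 grepl("scan=[0-9]+", keymap[["TITLE"]]))
            scan <- as.integer(sub(".*scan=([0-9]+).*", "\\1",
                                   keymap[["TITLE"]]))
        if (is.na(scan))
            scan <- b
        rt <- if ("RTINSECONDS" %in% names(keymap))
            as.numeric(keymap[["RTINSECONDS"]]) else NA_real_
        peakLines <- body[!isKey]
        if (length(peakLines)) {
            fields <- strsplit(trimws(peakLines), "[ \t]+")
            bad <- which(lengths(fields) < 2L)
            if (length(bad))
                stop("malformed MGF block ", b, ": bad peak line '",
                     peakLines[bad[1]], "'")
            pmz <- as.numeric(vapply(fields, `[`, "", 1L))
            pint <- as.numeric(vapply(fields, `[`, "", 2L))
            if (anyNA(pmz) || anyNA(pint))
                stop("malformed MGF block ", b, ": non-numeric peak values")
        } else {
            pmz <- numeric()
            pint <- numeric()
        }
        spectra[[b]] <- Spectrum(mz = pmz, intensity = pint,
                                 scanNumber = scan, precursorMz = pepmass,
                                 precursorCharge = charge,
                                 retentionTime = rt)
    }
    MsRun(spectra, runId)
}

#' Write a run as MGF
#'
#' Inverse of [readMgf()]: one `BEGIN IONS` block per spectrum with
#' `TITLE`, `SCANS`, `PEPMASS`, `CHARGE` (omitted when unknown) and
#' `RTINSECONDS` (omitted when absent). Values are printed with full
#' precision so a read-back reproduces the run.
#'
#' @param run an [MsRun].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMgf <- function(run, path) {
    stopifnot(is(run, "MsRun"))
    con <- file(path, "w")
    on.exit(close(con))
    for (s in run@spectra) {
        cat("BEGIN IONS\n", file = con)
        cat(sprintf("TITLE=%s scan=%d\n", run@runId, s@scanNumber),
            file = con)
        cat(sprintf("SCANS=%d\n", s@scanNumber), file = con)
        if (!is.na(s@retentionTime))
            cat(sprintf("RTINSECONDS=%.10g\n", s@retentionTime), file = con)
        cat(sprintf("PEPMASS=%.10g\n", s@precursorMz), file = con)
        if (!is.na(s@precursorCharge))
            cat(sprintf("CHARGE=%d+\n", s@precursorCharge), file = con)
        if (length(s@mz))
            writeLines(sprintf("%.10g %.10g", s@mz, s@intensity), con)
        cat("END IONS\n", file = con)
    }
    invisible(path)
}

## first cvParam value with the given accession under node, or NA
.cvValue <- function(node, accession) {
    p <- xml2::xml_find_first(
        node, sprintf(".//cvParam[@accession='%s']", accession))
    if (inherits(p, "xml_missing")) NA_character_
    else xml2::xml_attr(p, "value")
}

.hasCv <- function(node, accession) {
    !inherits(xml2::xml_find_first(
        node, sprintf(".//cvParam[@accession='%s']", accession)),
        "xml_missing")
}

## decode one <binaryDataArray>: base64, optional zlib, 32/64-bit float
.decodeBinaryArray <- function(node) {
    txt <- xml2::xml_text(xml2::xml_find_first(node, ".//binary"))
    size <- if (.hasCv(node, "MS:1000521")) 4L else 8L    # default 64-bit
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (.hasCv(node, "MS:1000574"))                       # zlib compression
        raw <- memDecompress(raw, type = "gzip")
    if (length(raw) == 0L)
        return(numeric())
    readBin(raw, what = "double", n = length(raw) %/% size, size = size,
            endian = "little")
}

#' Read MS2 spectra from an mzML file
#'
#' Minimal mzML 1.1 reader: retains only MS-level-2 spectra
#' (cvParam MS:1000511 = 2), taking the precursor m/z (MS:1000744) and
#' charge state (MS:1000041) from the first selected ion, the retention time
#' from the scan start time (MS:1000016; minutes are converted to seconds),
#' and the scan number from a `scan=<int>` token of the spectrum `id`
#' attribute, else the spectrum `index` + 1. m/z and intensity arrays may be
#' 32- or 64-bit floats, zlib-compressed or not.
#'
#' @param path path to an mzML file.
#' @param runId run identifier; defaults to the file name without extension.
#' @return An [MsRun]; empty (with a warning) when the file has no MS2
#'   spectra.
#' @export
readMzML <- function(path, runId = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(runId))
        runId <- tools::file_path_sans_ext(basename(path))
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
    spectra <- list()
    for (node in nodes) {
        level <- .cvValue(node, "MS:1000511")
        if (is.na(level) || as.integer(level) != 2L)
            next
        id <- xml2::xml_attr(node, "id")
        scan <- if (!is.na(id) && grepl("scan=[0-9]+", id))
            as.integer(sub(".*scan=([0-9]+).*", "\\1", id))
        else as.integer(xml2::xml_attr(node, "index")) + 1L
        rt <- NA_real_
        rtNode <- xml2::xml_find_first(
            node, ".//scan/cvParam[@accession='MS:1000016']")
        if (!inherits(rtNode, "xml_missing")) {
            rt <- as.numeric(xml2::xml_attr(rtNode, "value"))
            unit <- xml2::xml_attr(rtNode, "unitAccession")
            if (identical(unit, "UO:0000031"))    # minutes
                rt <- rt * 60
        }
        ion <- xml2::xml_find_first(node, ".//selectedIon")
        premz <- NA_real_
        charge <- NA_integer_
        if (!inherits(ion, "xml_missing")) {
            premz <- as.numeric(.cvValue(ion, "MS:1000744"))
            cs <- .cvValue(ion, "MS:1000041")
            if (!is.na(cs))
                charge <- as.integer(cs)
        }
        mzArr <- numeric()
        intArr <- numeric()
        for (arr in xml2::xml_find_all(node, ".//binaryDataArray")) {
            if (.hasCv(arr, "MS:1000514"))
                mzArr <- .decodeBinaryArray(arr)
            else if (.hasCv(arr, "MS:1000515"))
                intArr <- .decodeBinaryArray(arr)
        }
        spectra[[length(spectra) + 1L]] <-
            Spectrum(mz = mzArr, intensity = intArr, scanNumber = scan,
                     precursorMz = premz, precursorCharge = charge,
                     retentionTime = rt)
    }
    if (!length(spectra))
        warning("no MS2 spectra found in ", path, "; returning an empty run")
    MsRun(spectra, runId)
}

#' Write a run distance matrix as TSV
#'
#' Tab-separated square matrix with run labels as header row and first
#' column; distances printed with at least 6 significant digits.
#'
#' @param d a [RunDistanceMatrix] (or a symmetric labelled matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
    if (is(d, "RunDistanceMatrix"))
        d <- d@values
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d))))
        stop("distance matrix must be square and symmetric")
    labels <- rownames(d)
    if (is.null(labels))
        stop("distance matrix must carry run labels")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("run", labels), collapse = "\t"), con)
    for (i in seq_len(nrow(d)))
        writeLines(paste(c(labels[i], sprintf("%.17g", d[i, ])),
                         collapse = "\t"), con)
    invisible(path)
}

#' Read a run distance matrix written by [writeDistanceMatrix()]
#'
#' @param path path to the TSV file.
#' @return A [RunDistanceMatrix].
#' @export
readDistanceMatrix <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = 1L)
    m <- as.matrix(tab)
    colnames(m) <- rownames(m)          # header may mangle label characters
    m <- (m + t(m)) / 2                 # heal last-digit rounding asymmetry
    runDistanceMatrixFromValues(m)
}

#' Read a peptide annotation table
#'
#' TSV with columns `run_id`, `scan_number`, `peptide`: at most one rank-1
#' peptide-to-spectrum match per spectrum; spectra absent from the table are
#' unannotated.
#'
#' @param path path to the TSV file.
#' @return A data.frame with columns `run_id`, `scan_number`, `peptide`.
#' @export
readAnnotations <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("run_id", "scan_number", "peptide")
    if (!all(need %in% names(tab)))
        stop("annotation table must have columns ",
             paste(need, collapse = ", "))
    tab$scan_number <- as.integer(tab$scan_number)
    key <- paste(tab$run_id, tab$scan_number)
    if (anyDuplicated(key))
        stop("annotation table assigns more than one peptide to a spectrum")
    tab[need]
}
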