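#' @include spectra-io.R
NULL

#' Construct a SyntheticConfig
#'
#' Defaults describe a small multi-species benchmark: 3 species measured in
#' 3 technical replicates of 150 MS2 spectra each, disjoint species
#' libraries, fragment m/z jitter well below the default bin width, 25%
#' whole-spectrum dropout per replicate (so that, together with occasional
#' match misses caused by peak dropout and intensity noise, the distance
#' between technical replicates lands near the ~30% observed on real
#' data-dependent acquisitions) and 40% of spectra left without a peptide
#' annotation.
#'
#' @param nSpecies number of species.
#' @param replicatesPerSpecies technical replicates per species.
#' @param spectraPerRun template spectra per species library.
#' @param peaksPerSpectrum integer (min, max) peaks per template.
#' @param mzRange fragment m/z interval in Th.
#' @param precursorRange precursor m/z interval in Th.
#' @param chargeWeights sampling weights for precursor charges 2 and 3.
#' @param precursorJitterPpm sd of the per-replicate precursor mass error in
#'   ppm.
#' @param mzJitterSd sd of the per-replicate fragment m/z jitter in Th.
#' @param intensityNoiseCv coefficient of variation of the multiplicative
#'   lognormal intensity noise.
#' @param peakDropoutRate per-peak dropout probability.
#' @param spectrumDropoutRate per-spectrum dropout probability.
#' @param sharedLibraryFraction fraction of each library drawn from a pool
#'   shared across species.
#' @param retentionShuffleWindow window size of the local retention-order
#'   shuffle.
#' @param unannotatedFraction fraction of run spectra left unannotated.
#' @param seed integer RNG seed.
#' @return A [SyntheticConfig].
#' @export
syntheticConfig <- function(nSpecies = 3, replicatesPerSpecies = 3,
                            spectraPerRun = 150,
                            peaksPerSpectrum = c(20, 50),
                            mzRange = c(100, 1500),
                            precursorRange = c(300, 1200),
                            chargeWeights = c(`2` = 0.6, `3` = 0.4),
                            precursorJitterPpm = 2,
                            mzJitterSd = 0.005, intensityNoiseCv = 0.2,
                            peakDropoutRate = 0.05,
                            spectrumDropoutRate = 0.25,
                            sharedLibraryFraction = 0,
                            retentionShuffleWindow = 10,
                            unannotatedFraction = 0.4, seed = 1) {
    new("SyntheticConfig", nSpecies = as.integer(nSpecies),
        replicatesPerSpecies = as.integer(replicatesPerSpecies),
        spectraPerRun = as.integer(spectraPerRun),
        peaksPerSpectrum = as.integer(peaksPerSpectrum),
        mzRange = as.numeric(mzRange),
        precursorRange = as.numeric(precursorRange),
        chargeWeights = as.numeric(chargeWeights),
        precursorJitterPpm = as.numeric(precursorJitterPpm),
        mzJitterSd = as.numeric(mzJitterSd),
        intensityNoiseCv = as.numeric(intensityNoiseCv),
        peakDropoutRate = as.numeric(peakDropoutRate),
        spectrumDropoutRate = as.numeric(spectrumDropoutRate),
        sharedLibraryFraction = as.numeric(sharedLibraryFraction),
        retentionShuffleWindow = as.integer(retentionShuffleWindow),
        unannotatedFraction = as.numeric(unannotatedFraction),
        seed = as.integer(seed))
}

## run `expr` under a derived seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(expr)
}

## one random template spectrum; id carries its identity (the ground-truth
## "peptide")
.randomTemplate <- function(config, id) {
    p <- sample(seq.int(config@peaksPerSpectrum[1],
                        config@peaksPerSpectrum[2]), 1L)
    list(id = id,
         mz = sort(stats::runif(p, config@mzRange[1], config@mzRange[2])),
         intensity = stats::rlnorm(p, meanlog = log(1e4), sdlog = 1),
         precursorMz = stats::runif(1, config@precursorRange[1],
                                    config@precursorRange[2]),
         charge = sample(c(2L, 3L), 1L, prob = config@chargeWeights))
}

#' Template spectrum library of one synthetic species
#'
#' Generates `spectraPerRun` template spectra for species `speciesIndex`.
#' The first `round(sharedLibraryFraction * spectraPerRun)` templates are
#' drawn from a pool common to all species (same identities and peaks for
#' every species); the rest are species-specific. Deterministic given the
#' config seed.
#'
#' @param config a [SyntheticConfig].
#' @param speciesIndex 1-based species index.
#' @return A list of template spectra (plain lists with elements `id`, `mz`,
#'   `intensity`, `precursorMz`, `charge`), with attribute `speciesIndex`.
#' @export
generateSpeciesLibrary <- function(config, speciesIndex) {
    stopifnot(is(config, "SyntheticConfig"))
    nShared <- round(config@sharedLibraryFraction * config@spectraPerRun)
    shared <- if (nShared > 0)
        .withSeed(config@seed, lapply(seq_len(nShared), function(t)
            .randomTemplate(config, sprintf("SHARED_T%04d", t))))
    else list()
    own <- .withSeed(config@seed + 7919 * speciesIndex,
        lapply(seq_len(config@spectraPerRun - nShared), function(t)
            .randomTemplate(config, sprintf("SP%d_T%04d", speciesIndex, t))))
    structure(c(shared, own), speciesIndex = as.integer(speciesIndex))
}

#' Simulate one technical-replicate run from a species library
#'
#' Each template survives with probability `1 - spectrumDropoutRate`;
#' surviving templates get centred Gaussian m/z jitter on every fragment
#' peak, a small ppm-scale precursor mass error, multiplicative lognormal
#' intensity noise of the configured coefficient of variation, independent
#' per-peak dropout, and a local shuffle of the elution (scan) order within
#' windows of `retentionShuffleWindow` templates. Scan numbers are assigned
#' 1..n after shuffling; retention times are one second per scan.
#'
#' @param library output of [generateSpeciesLibrary()].
#' @param config a [SyntheticConfig].
#' @param replicateIndex 1-based replicate index.
#' @return An [MsRun] whose spectra carry an attribute-free 1:1
#'   correspondence to surviving templates via the returned
#'   `attr(, "templateIds")` (template id per spectrum, in scan order).
#' @export
generateRun <- function(library, config, replicateIndex) {
    stopifnot(is(config, "SyntheticConfig"))
    speciesIndex <- attr(library, "speciesIndex")
    if (is.null(speciesIndex)) speciesIndex <- 0L
    runSeed <- config@seed + 104729 * speciesIndex + 7907 * replicateIndex
    .withSeed(runSeed, {
        keep <- stats::runif(length(library)) >= config@spectrumDropoutRate
        kept <- library[keep]
        ## local retention reordering: permute within consecutive windows
        n <- length(kept)
        ord <- seq_len(n)
        w <- max(1L, config@retentionShuffleWindow)
        for (start in seq(1L, n, by = w)) {
            win <- seq.int(start, min(start + w - 1L, n))
            if (length(win) > 1L)
                ord[win] <- sample(ord[win])
        }
        kept <- kept[ord]
        sdlog <- sqrt(log(1 + config@intensityNoiseCv^2))
        spectra <- vector("list", n)
        for (s in seq_len(n)) {
            tp <- kept[[s]]
            p <- length(tp$mz)
            keepPeak <- stats::runif(p) >= config@peakDropoutRate
            mz <- tp$mz[keepPeak] +
                stats::rnorm(sum(keepPeak), 0, config@mzJitterSd)
            int <- tp$intensity[keepPeak] *
                stats::rlnorm(sum(keepPeak), -sdlog^2 / 2, sdlog)
            premz <- tp$precursorMz *
                (1 + stats::rnorm(1, 0, config@precursorJitterPpm * 1e-6))
            spectra[[s]] <- Spectrum(mz = mz, intensity = int,
                                     scanNumber = s, precursorMz = premz,
                                     precursorCharge = tp$charge,
                                     retentionTime = as.numeric(s))
        }
        run <- MsRun(spectra,
                     sprintf("S%d_R%d", speciesIndex, replicateIndex))
        attr(run, "templateIds") <- vapply(kept, `[[`, "", "id")
        run
    })
}

#' Generate a full synthetic multi-species dataset
#'
#' `nSpecies * replicatesPerSpecies` runs plus species group labels and a
#' synthetic peptide annotation table. The "peptide" of a spectrum is the
#' identity of its generating template, giving exact ground truth for
#' same/different-peptide questions; a configurable fraction of spectra is
#' left unannotated, mimicking spectra without a database hit.
#'
#' @param config a [SyntheticConfig].
#' @return A list with elements `runs` (list of [MsRun]), `groups`
#'   (character vector, one species label per run), `annotations`
#'   (data.frame `run_id`, `scan_number`, `peptide`) and `templateIds`
#'   (list: template id per spectrum of each run, ground truth without
#'   missingness).
#' @examples
#' ds <- generateDataset(syntheticConfig(nSpecies = 2,
#'     replicatesPerSpecies = 2, spectraPerRun = 20, seed = 7))
#' vapply(ds$runs, runId, character(1))
#' @export
generateDataset <- function(config = syntheticConfig()) {
    stopifnot(is(config, "SyntheticConfig"))
    runs <- list()
    groups <- character()
    templateIds <- list()
    annRows <- list()
    for (s in seq_len(config@nSpecies)) {
        lib <- generateSpeciesLibrary(config, s)
        for (r in seq_len(config@replicatesPerSpecies)) {
            run <- generateRun(lib, config, r)
            ids <- attr(run, "templateIds")
            attr(run, "templateIds") <- NULL
            runs[[length(runs) + 1L]] <- run
            groups <- c(groups, sprintf("species%d", s))
            templateIds[[length(templateIds) + 1L]] <- ids
            annotated <- .withSeed(
                config@seed + 15485863 * s + 32452843 * r,
                stats::runif(length(ids)) >= config@unannotatedFraction)
            if (any(annotated))
                annRows[[length(annRows) + 1L]] <- data.frame(
                    run_id = run@runId,
                    scan_number = vapply(run@spectra, slot, integer(1),
                                         "scanNumber")[annotated],
                    peptide = ids[annotated],
                    stringsAsFactors = FALSE)
        }
    }
    names(templateIds) <- vapply(runs, runId, character(1))
    ann <- if (length(annRows)) do.call(rbind, annRows)
           else data.frame(run_id = character(), scan_number = integer(),
                           peptide = character(), stringsAsFactors = FALSE)
    rownames(ann) <- NULL
    list(runs = runs, groups = groups, annotations = ann,
         templateIds = templateIds)
}

#' Write a synthetic dataset to disk
#'
#' Emits one MGF per run plus `groups.tsv` (`run_id`, `group`) and
#' `psms.tsv` (`run_id`, `scan_number`, `peptide`).
#'
#' @param dataset output of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    for (run in dataset$runs)
        writeMgf(run, file.path(dir, paste0(runId(run), ".mgf")))
    utils::write.table(
        data.frame(run_id = vapply(dataset$runs, runId, character(1)),
                   group = dataset$groups),
        file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(dataset$annotations, file.path(dir, "psms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
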