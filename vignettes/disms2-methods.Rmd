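---
title: "Run-level proteome distances from unidentified MS2 spectra: methods and design"
author: "disms2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run-level proteome distances from unidentified MS2 spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disms2)
```

## The problem

Shotgun proteomics compares biological samples through thousands of tandem
(MS2) spectra per liquid-chromatography run. The standard route — database
search, then comparison of identified peptide lists — fails for organisms
without a sequenced genome and discards the 30–60% of spectra that typically
receive no confident identification. `disms2` instead computes a distance
between two runs *directly from the unidentified spectra*: two runs are
similar when most spectra of one run have a closely matching spectrum in the
other.

## The run distance

For runs $i$ and $j$, every MS2 spectrum $k$ of run $i$ is matched against a
constrained candidate set in run $j$. The directed distance

$$d^*(i,j) = \frac{\#\{k : \text{no candidate within } cdis\}}{n_i}$$

is the fraction of spectra of run $i$ without a sufficiently similar partner
in run $j$, and the reported distance is the symmetrized mean
$d(i,j) = (d^*(i,j) + d^*(j,i))/2 \in [0,1]$. Filling an $N \times N$ matrix
costs $N(N-1)$ directed computations.

### Preprocessing (step 1)

Each spectrum is optionally reduced to its `topn` most intense peaks and then
binned at fixed width `bin` (Th): all peaks in the half-open interval
$[n^* \cdot bin, (n^*+1) \cdot bin)$ are replaced by their maximum intensity
at the representative position $(n^*+0.5)\cdot bin$. A peak exactly on a
boundary belongs to the upper bin — the half-open convention is honored
bit-exactly, which also makes binning idempotent at a fixed width. Ties at
the `topn`-th intensity are resolved toward the lower-m/z peak so results are
deterministic. Spectra emptied by preprocessing (only possible when they were
already empty on disk) are flagged and can never match.

### Candidate constraints (steps 2–3)

Candidates for spectrum $k$ must satisfy, checked in this order:

* **(a) rank window** — candidate rank $l \in [k-\texttt{ret}, k+\texttt{ret}]$,
  where ranks are positions in the scan-number-ordered MS2 list; at most
  $2\cdot\texttt{ret}+1$ spectra remain. This is a cheap surrogate for
  retention-time alignment: peptides elute at similar positions in replicate
  acquisitions.
* **(b) equal precursor charge** — fragmentation patterns of different charge
  states are not comparable. A spectrum with *unknown* charge only matches
  unknown charge (conservative reading of "same charge state"); parsers
  preserve unknown charge rather than guessing.
* **(c) precursor mass** — $|m_{l_j}-m_{k_i}|/m_{k_i}\cdot 10^6 \le
  \texttt{prec}$ (ppm). The test is applied to precursor m/z as read from the
  file; under (b) the charges are already equal, so ppm on m/z and on neutral
  mass coincide.

An empty candidate set is a legal outcome and counts the query as unmatched.

### Spectrum distances (step 4)

Three measures are available; all see the *same* preprocessed spectra
(cosine uses binned intensities, the other two use the representative
positions after the same binning, so no measure bypasses step 1):

* **cosine**: $d_{\cos} = 1 - \langle \tilde I_a, \tilde I_b\rangle /
  (\|\tilde I_a\| \|\tilde I_b\|)$ over the union of occupied bins; in
  $[0,1]$ because intensities are non-negative.
* **angle** ($\varepsilon$): $\arccos\!\big(c / \sqrt{p_a p_b}\big)$ where
  $c$ counts peaks of $a$ with some partner of $b$ within $\varepsilon$.
  The count is *directional* (it runs over the first argument's peaks), and
  we implement it exactly as defined; the measured asymmetry on random
  spectra is small and the unit tests characterize precisely when symmetry
  holds (equal directed match counts). Because several peaks of $a$ can
  share one partner, $c$ may exceed the denominator; the arccos argument is
  clamped to $[0,1]$ to keep the function total.
* **parametrized Hausdorff** ($\delta$, $k$): per peak, the minimal absolute
  position difference $m_q$ to the other spectrum contributes
  $(m_q \cdot 1\{m_q > \delta\})^{1/k}$; the directed value is the mean over
  peaks and the distance the maximum of the two directions. We define
  $0^{1/k}=0$ (continuity) and apply the root to the product, following the
  parenthesization of the definition.

A distance against an empty spectrum is *undefined* (`NA`) and is converted
to "no match" by the callers, never propagated as `NaN`.

**Match rule.** A query matches when its minimal candidate distance is
*strictly* below `cdis`. The boundary case is not defined by the original
description ("greater than" for no-match, "smaller than" for match); we
chose strict `<` and state it here. Only the minimum matters, so ties among
candidates are irrelevant.

### Defaults

`matchParams()` defaults to the best setting found by the published
parameter optimization: `topn = Inf`, `bin = 0.2` Th, `ret = 3000`,
`prec = 10` ppm, cosine distance, `cdis = 0.3`. The distance
hyperparameters default to $\varepsilon = 0.05$ Th, $\delta = 0.05$ Th,
$k = 50$.

## Parameter optimization by PERMANOVA

With technical replicates available, good parameters are those that make
replicate runs close and different species distant. `permanovaSS()`
decomposes squared distances one-way, Anderson style:
$SS_T = \frac1N\sum_{i<j}d_{ij}^2$,
$SS_W = \sum_g \frac1{n_g}\sum_{i<j\in g} d_{ij}^2$, $SS_B = SS_T - SS_W$,
with pseudo-F $\frac{SS_B/(g-1)}{SS_W/(N-g)}$ and partial
$R^2 = SS_B/SS_T$ (defined as 0 for an all-zero matrix, and scale-invariant
since every term scales with the square of the distances).
`permanovaTest()` shuffles labels uniformly (the standard Monte-Carlo
permutation test, 10000 permutations by default) and reports
$p = (\#\{F_{perm}\ge F_{obs}\}+1)/(n_{perm}+1)$. The implementation is
authored here from the closed forms and is cross-checked in the test suite
against `vegan::adonis2`, the reference implementation of this analysis.

A caveat worth knowing: the permutation p-value has a combinatorial floor.
Nine runs in three balanced groups admit only $9!/(3!)^3 = 1680$ distinct
label assignments, of which the $3!$ group relabelings tie the observed
pseudo-F, so no degree of separation can push $p$ below
$6/1680 \approx 0.0036$. Five or more groups of three make $p \le 0.001$
attainable. The tests demonstrate both facts.

`factorialDesign()` reproduces the two published evaluation designs (72 + 9
= 81 settings; design 2 exists because the angle distance is not bounded by
1, so higher cutoffs are sensible for it), and `gridSearch()` ranks settings
by partial $R^2$, ties keeping grid order.

`compareMethodsCV()` implements the method-comparison statistic: the
coefficient of variation (sd/mean, $n-1$ denominator) of the absolute
entrywise differences between two distance matrices over the upper triangle.
A zero mean difference is undefined and returns `NA` with a warning.

## Annotation comparison modes

When database annotations exist, `modeDistanceMatrix()` generalizes the
directed search over five switches (search method, spectrum universe,
annotation check, filter check, duplicate handling); the six named presets
of `annotationModePresets()` cover the standard combinations. Design
choices: peptide equality is exact string equality of the supplied
sequence-plus-modification strings (no isoleucine/leucine or modification
collapsing); with duplicates removed, the directed denominator is the number
of unique peptides of the query run; an unannotated *query* under an
annotation check counts as no hit (not only unannotated candidates); and
database modes without a filter check search the entire partner run. The
`DISMS2.f` preset is bit-identical to `runDistanceMatrix()` by construction,
and the tests assert it.

## Clustering

`averageLinkageTree()` is a from-scratch UPGMA with a deterministic
tie-break (merge the pair whose smallest member labels sort first) so output
is reproducible; the suite checks exact agreement with
`stats::hclust(method = "average")` on random matrices. Newick export halves
merge heights so the tree is ultrametric with leaf depth = root height / 2;
the path length between two leaves then equals their cophenetic distance,
which the tests verify through an `ape` round trip. Children are ordered by
smallest leaf label.

## The synthetic world

No public data accompany this package; all tests run on a generator
(`generateDataset()`) that emulates a multi-species experiment with
technical replicates:

* each species owns a library of template spectra (uniform random peak
  positions in 100–1500 Th, 20–50 peaks, lognormal intensities, precursors
  in 300–1200 Th, charges 2:3 at 60:40) — by default libraries are disjoint
  between species;
* a technical replicate re-acquires the library with whole-spectrum dropout
  (default 25%, emulating stochastic precursor selection in data-dependent
  acquisition), fragment m/z jitter (sd 5 mTh, typical of high-resolution
  instruments and well below the 0.2 Th bin), precursor mass error (2 ppm
  sd, well inside the 10 ppm gate), multiplicative lognormal intensity
  noise (CV 0.2), per-peak dropout (5%), and a local shuffle of elution
  order (window 10, well inside `ret`);
* the generating template of each spectrum is its ground-truth "peptide";
  40% of spectra are left unannotated, mirroring the typical fraction of
  spectra without a database hit.

The dropout default was calibrated once so that the run distance between
replicates lands near the ~30% observed for real technical replicates
(dropout 0.25 plus a ~4% same-template miss rate from the noise terms, the
latter mirroring the published true-positive rate of the cosine cutoff);
between-species distances saturate near 1 because disjoint random libraries
essentially never pass the precursor gate at 10 ppm. Real data differ in
ways the generator does not model: fragment peaks follow b/y-ion series
rather than uniform positions, intensities are structured, chimeric spectra
and shared peptides blur species boundaries, and between-species distances
on real organisms (~0.9–0.95, lower for related species) do not saturate. A
green end-to-end test therefore establishes that the pipeline recovers a
*stated* similarity structure, not that it reproduces any particular real
dataset's numbers.

All generation is deterministic given the config seed; per-species and
per-replicate streams are derived with fixed offsets so that a library is
reproducible regardless of call order.

## Numerical and interface choices

* Half-open binning uses `floor(x / bin)`; exact boundary peaks go up.
* `NA` (undefined distance), not `NaN`, signals empty spectra; callers turn
  it into "no match".
* Distance matrices are written as TSV with 17 significant digits so a
  read-back is exact.
* The command-line entry point (`disms2Main()`, wrapper script in
  `inst/scripts/disms2`) accepts a JSON config file whose values are
  overridden by explicit flags; JSON was chosen over YAML to avoid an extra
  dependency.
* The mzML reader is a minimal, dependency-light parser (MS level, selected
  ion m/z/charge, scan start time, 32/64-bit float arrays, optional zlib);
  it does not aim to cover the full standard (no chromatograms, no indexed
  wrapper, no vendor quirks). MGF is the canonical text format for fixtures
  and synthetic output.

## Known limitations

* Runtime is quadratic in run count and linear in spectra per run times
  candidates per spectrum; the implementation is plain R, adequate for the
  package's test scale (tens of thousands of pairwise spectrum comparisons
  per second) but not tuned for 27 runs of 35000 spectra.
* No retention-time alignment (the rank window replaces it by design), no
  spectral clustering before matching, no intensity normalization or
  deisotoping.
* The angle distance is asymmetric as defined; symmetrizing it would change
  published semantics, so it is left as is and documented.
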