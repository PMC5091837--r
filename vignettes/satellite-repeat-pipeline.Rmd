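---
title: "Quantifying satellite-repeat ChIP enrichment, chromocentre counts and qPCR fold changes"
author: "satrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying satellite-repeat ChIP enrichment, chromocentre counts and qPCR fold changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satrep)
```

## Scope and model

Mouse pericentromeres are built from tandem arrays of major satellite
repeats; their heterochromatinisation drives the clustering of
pericentromeres into DAPI/DRAQ5-dense nuclear foci called chromocentres.
`satrep` implements the computational workflow used to study protein binding
and transcriptional de-repression at these repeats:

1. **Repeat annotation** (`parse_repeat_annotation`, `group_by_family`):
   RepeatMasker-style annotations are parsed into a uniform instance model
   and grouped into repeat families.
2. **Repeat genomes** (`build_repeat_genome`, `add_consensus`,
   `map_offset`): all annotated copies of one family are concatenated into a
   single artificial reference, copies separated by an `NNNNN` spacer so that
   short reads cannot align across copy boundaries. A published consensus
   (e.g. the 120-nt minor satellite consensus shipped as
   `minor_satellite_consensus`) can be appended as an extra segment.
3. **Hit counting and enrichment** (`naive_align`, `count_hits`,
   `enrichment`): reads are aligned per family ("hits" are distinct reads
   with at least one reported alignment; multi-mapping is allowed), and ChIP
   binding is quantified as library-size-normalised fold enrichment over
   input.
4. **Chromocentre counting** (`detect_spots`, `count_chromocentres`,
   `compare_distributions`): bright nuclear spots are segmented per cell,
   filtered at an equivalent radius of 2.75 px, and per-cell count
   distributions of two treatment arms are compared with a pooled Pearson
   chi-squared test.
5. **qPCR quantification** (`relative_expression`, `percent_input`,
   `relative_to_h3`, `fit_exponential_decay`): comparative-Ct fold changes,
   percent-of-input ChIP-qPCR with background subtraction, ratios to total
   H3, and exponential transcript-decay fits.
6. **Synthetic data** (`make_toy_genome`, `simulate_reads`,
   `simulate_nucleus_image`, `simulate_ct_table`): seeded generators with
   exact ground truth, so every stage above is testable end to end without
   any external data.

## Repeat genomes and the N spacer

A repeat genome for family $F$ with instances $s_1,\dots,s_n$ is the string
$s_1 \,\texttt{NNNNN}\, s_2 \,\texttt{NNNNN}\, \dots\, s_n$, one FASTA record
per family. Since the aligner charges every `N` as a mismatch, a read of
length $\ell$ crossing a segment boundary must absorb at least
$\min(5, \ell)$ mismatches, so with the conventional mismatch budgets
($\le 4$) boundary-spanning reads can never map — the spacer enforces the
"no mapping across instance boundaries" construction literally. The builder
warns when a non-default spacer is shorter than the expected read length,
because that guarantee then disappears.

Minus-strand instances are reverse-complemented by default
(`strand_policy = "reverse_complement_minus"`), so all segments read in
consensus orientation; the literal `as_plus` variant is available because
the original construction's strand handling is not documented. The chosen
policy is recorded in the object and its sidecar file. `map_offset` inverts
the construction exactly: every non-spacer offset maps back to its source
instance and genomic coordinate (strand-aware), which is verified
exhaustively in the test suite.

Coordinates are 0-based half-open everywhere inside the package; the only
conversions happen at the parse/write boundary (`rm_out` is 1-based
inclusive with strand `C` for minus; the UCSC `rmsk` table is already
0-based). Overlapping instances are kept as-is; no merging is performed.

## The internal aligner

`naive_align` is intentionally simple — ungapped, substitution-only, `N`
always a mismatch — because its role is to close the simulation loop, not to
replace a production aligner (real alignments enter through SAM/BAM via
`count_hits_sam`). Two implementations are provided and proven equivalent:

* an exhaustive scan over all offsets and both orientations, and
* a pigeonhole-seeded search: the read is split into $m+1$ non-overlapping
  chunks for mismatch budget $m$; any alignment with $\le m$ mismatches
  leaves one chunk intact, whose seed k-mer is found exactly in a hash index
  of the reference. The seeded search therefore finds *every* in-budget
  alignment, and both methods return identical results (tested against an
  independent brute-force oracle). Reads containing `N`, or too short for
  informative seeds (< 8 nt per chunk), silently fall back to the scan.

Ties between equally good alignments are resolved deterministically:
fewest mismatches, then smallest offset, then forward orientation.

## Enrichment and its confidence interval

For hit counts $h_c$ of $T_c$ ChIP reads and $h_i$ of $T_i$ input reads,

$$\widehat{\text{fold}} = \frac{h_c/T_c}{h_i/T_i},\qquad
\mathrm{CI}_{95} = \exp\!\Big(\log \widehat{\text{fold}} \pm 1.96
\sqrt{\tfrac{1}{h_c}-\tfrac{1}{T_c}+\tfrac{1}{h_i}-\tfrac{1}{T_i}}\Big),$$

the normal approximation for a log ratio of two binomial proportions. The
interval is the package's addition (the original analysis reported none).
With zero input hits the fold is flagged undefined rather than infinite;
with zero ChIP hits the fold is 0 with no interval. A `normalize = "raw"`
mode reproduces pipelines that assumed equal library sizes. Note the
estimand is the *ratio of mapping rates*: when an enriched family occupies a
non-negligible fraction of the genome, renormalisation of the ChIP library
shrinks the ratio slightly below the generative enrichment factor — with
the default toy-genome geometry (each family ≈ 0.3% of the genome) this
bias is an order of magnitude below the CI width at 100,000 reads, which is
why the CI-coverage checks pass without correction.

## Chromocentre detection

The only published rule for the imaging analysis is the radius filter:
bright spots count as chromocentres when strictly greater than 2.75 px in
radius. Everything upstream of that rule in the proprietary instrument
software is unpublished, so the segmentation here is the package's own,
fixed, documented design: Gaussian smoothing (σ = 1 px), per-nucleus
background as the median intensity inside the nuclear mask, thresholding at
1.3 × background restricted to the mask, 8-connected components, one spot
per component.

Spot *size* is measured on the half-maximum contour within each component
(`size_from = "half_max"`): the raw thresholded component of a blurred disk
extends out to where the smoothed edge profile crosses only 30% above
background, which overstates a radius-2 disk's equivalent radius past the
2.75 px cutoff; the half-way-to-peak contour sits at the disk's true edge
(the FWHM convention) and recovers generated radii nearly unbiased from
radius 2 upward. The raw-component convention remains available
(`size_from = "threshold"`). The equivalent radius is $\sqrt{A/\pi}$ from
pixel area — deterministic and rotation-invariant; whether the original
instrument used pixel areas or fitted morphologies is unknown, so the
convention is recorded in the parameter object rather than asserted as
equivalent.

For the distribution comparison, per-cell counts are binned by chromocentre
number and bins are pooled *inward from both extremes* (always merging at
the extreme with the smallest expected count) until every expected cell of
the 2 × k table reaches 5 (Cochran's rule). Count histograms are sparse at
both ends, so pooling only the right tail would collapse the table around a
sparse head bin and destroy power; both-ended pooling keeps the informative
centre of the distribution intact. `pearson_chi2` exposes the plain
statistic for pre-binned tables.

```{r chromo-example}
sim <- simulate_nucleus_image(seed = 1, n_spots = 12, radii = c(2, 3, 4, 6))
spots <- detect_spots(sim$image, sim$mask)
count_chromocentres(spots)       # spots with radius 2 are filtered out
sum(sim$truth$radius > 2.75)     # generator truth
```

## qPCR quantification

`relative_expression` implements comparative Ct with a configurable
efficiency base (default 2.0, classic perfect doubling; the study reports no
measured efficiencies). Per replicate $r$,
$\Delta Ct_r = Ct_{\text{target},r} - Ct_{\text{ref},r}$, and the fold
change of a condition over vehicle is
$E^{-(\overline{\Delta Ct}_{\text{cond}} - \overline{\Delta Ct}_{\text{veh}})}$
— the geometric mean of per-replicate folds. The geometric form is used for
the point estimate because it makes vehicle-versus-vehicle exactly 1 for any
table (an arithmetic mean of per-replicate folds cannot, by Jensen's
inequality); per-replicate folds and their SEM are reported alongside, as in
the usual "mean ± SEM of biological replicates" presentation. Spike-in
normalisation is simply the same computation with the spiked RNA as the
reference target.

`percent_input` adjusts the input Ct for its dilution
($Ct' = Ct_{\text{input}} - \log_E(1/\text{input fraction})$), converts the
ChIP-input Ct difference to the percent scale, subtracts the no-antibody
background *on the percent scale*, and floors at zero. The input fraction
has no default — it is an experimental fact that must be supplied.
`relative_to_h3` is a guarded ratio for histone-mark ChIP normalised to
total H3, flagging zero-H3 cells as undefined rather than dividing.

`fit_exponential_decay` fits $y = A e^{-kt}$ (optionally $+C$) by
Levenberg–Marquardt least squares with parameter tolerance $10^{-8}$,
started from the log-linear regression slope with $k$ bounded at 0;
half-life is $\ln 2 / k$. Constant series are reported as "no decay"
($k = 0$, infinite half-life) instead of a convergence failure. The fitted
optimum is checked in the tests against a coarse grid-search oracle (the fit
must never have larger SSE).

## What the generators emulate — and what they do not

* `make_toy_genome`: one background chromosome (default 240 kb) with, per
  family, 3 instances of a ~200–300 nt random consensus at 5% divergence,
  random strands, non-overlapping placements. Each family occupies ≈ 0.3% of
  the toy genome — satellite-like in being a small minority of mappable
  sequence, and deliberately small so the fold estimand equals the
  generative factor to well within CI width (see above).
* `simulate_reads`: 100,000 reads of 36 nt per library (the scale and read
  length of the early ChIP-seq libraries the workflow was built for), per-base
  substitution errors at 0.005, input uniform, ChIP with instance start
  positions up-weighted by the family's enrichment factor and renormalised.
  No indels (the test aligner is ungapped), no fragment-length or GC model,
  no duplicates — enrichment acts as a uniform region weight, the simplest
  model consistent with fold-vs-input semantics.
* `simulate_nucleus_image`: elliptical nucleus, uniform background 50,
  disk spots of intensity 200 at integer-pixel centres (so each generated
  radius has a well-defined discrete disk area), optional Gaussian profile
  and noise. Real DRAQ5 images have textured chromatin, intensity gradients
  and touching chromocentres; passing the exact-recovery tests therefore
  shows the *pipeline arithmetic* is right, not that segmentation of real
  images is solved.
* `simulate_ct_table`: reference Ct ~ N(20, sd), target vehicle Ct ~
  N(25, sd), treatment shifts of $-\log_E(\text{fold})$ cycles, default 6
  replicates and 0.1-cycle noise (typical technical scatter).

Every generator runs under a locally seeded Mersenne–Twister stream
(`with_seed`), restoring the caller's RNG state; a given seed fixes outputs
byte for byte, and FASTQ/TSV writers record the generating parameters in
sidecar files.

## Numerical and design choices

* Strict ">" at the 2.75 px radius boundary, reading the rule literally.
* Family identity is the repeat *name*; class-level grouping
  (`level = "repclass"`) is offered because published per-family panels mix
  name-level units (major/minor satellite) with class-level units (LINE L1,
  SINEs), and which column defined each category is not stated.
* Hit = distinct read, never alignment records: record-level counting would
  depend on the aligner's report mode (secondary/supplementary flags are
  ignored for counting, unmapped flags define the denominator).
* Whether multi-family reads were reassigned is unstated; each family is
  counted independently against its own repeat genome.
* SAM streams with no unmapped records cannot reveal the library size, so
  an explicit `total_reads` is demanded instead of silently using hits.
* Degenerate inputs fail loudly: empty masks, empty families, absent
  conditions and out-of-range offsets are errors, not empty results.

Problem sizes used by the test suite and the acceptance script — 100
replicate library pairs of 2 × 100,000 reads per enrichment setting, 200
noiseless nuclei with 0–25 spots, 10,000 boundary and 10,000 within-instance
reads, 500 random contingency tables, 50 noisy decay series — were chosen as
the smallest scales at which the stochastic claims (CI coverage,
significance rates) are sharp.

## Known limitations

* The naive aligner is ungapped; indel-containing reads are unmappable by
  construction. Production data should be aligned externally and counted
  through the SAM path.
* Percent-input assumes a single efficiency for all targets.
* The imaging pipeline assumes one nucleus per (cropped) image, as produced
  by imaging flow cytometry; it does not segment fields of multiple cells.
* The chi-squared comparison treats cells as independent; replicate
  structure (e.g. biological replicates of arms) is not modelled.
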