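---
title: "Quantifying somatic CAG expansion with quantile-cell statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic CAG expansion with quantile-cell statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagdrift)
```

## The measurement and its model

Fragment analysis of a PCR-amplified CAG tract yields an electropherogram:
signal intensity as a function of product size in base pairs. Because the
amplicon carries a fixed non-repeat flank, repeat number is an affine
function of size; `cagdrift` uses

$$(CAG)_n = \frac{\mathrm{size_{bp}} - 122}{3} \times 1.0425 + 1.2088$$

with all four constants overridable through `cag_calibration()`. The slope
and intercept are an empirical mobility correction — CAG-rich DNA runs
anomalously in sizing matrices — so calibrated repeat numbers are
non-integral by construction and are kept as reals throughout.

A somatic tissue is a mosaic: different cells carry different repeat
lengths, so a bulk trace is a *distribution* of lengths, not a genotype.
The pipeline treats each sample as a normalized weight function over repeat
numbers and expresses somatic change as $\Delta$CAG relative to the
animal's germline allele, taken as the **modal repeat of the tail sample
collected at weaning**. Using a scalar modal anchor (rather than a
full-distribution deconvolution) is the only subtraction that keeps the
tissue weights a valid probability distribution; the tail trace's own
stutter therefore does not propagate into the tissue $\Delta$
distribution.

## Peak calling

`call_peaks()` takes local maxima of intensity versus size, treating
plateaus of equal intensity as a single peak at their leftmost point, and
discards peaks below `min_rel_height` (default 0.10) of the global
maximum. The default is a common stutter floor for STR data whose vendor
processing is unknown; it is deliberately conservative and configurable.
Two properties are guaranteed and tested: peak calling is invariant to
uniform intensity rescaling, and lowering the threshold never removes a
peak. Modal ties resolve to the shortest allele — deterministic, and
conservative against inflating apparent expansion. No stutter
deconvolution is attempted: thresholding is the only correction, so
reported distributions are distributions of *signal*, as in the source
assay.

## Quantile cells and the two constructions

To localize where along the distribution a treatment acts, the
$\Delta$CAG axis is divided into `n_cells = 100` equal-mass quantile cells
and the first and last `n_exclude_each_end = 5` are excluded (retained
cells 6–95), trimming the noisy extreme tails. We read the published
"divided into 100 cells ... excluding the first and last 5 quantiles" as
five cells per end; a 99-cell variant is the same construction with 99
cells (interior edges versus cells differ by one) and both are plain
arguments.

Two ways of assigning per-animal means to cells are implemented:

* **Equal-mass quantile slices** (`compare_groups(cells =
  "quantile_slices")`, the default). Each animal's $\Delta$ distribution
  is cut into its own 100 equal-mass slices and cell $k$ gets the weighted
  mean $\Delta$ inside slice $k$; an atom straddling a slice boundary
  contributes to both sides in proportion. Cell $k$ then indexes the same
  quantile range of every animal, every cell holds mass $1/n$ for every
  animal, and two exact properties follow: the average of the cell means
  equals the distribution mean, and adding a constant to one group's
  support moves every cell difference by exactly that constant.
* **Shared combined edges** (`cells = "shared_edges"`). Interior weighted
  quantiles of the mass-averaged combined distribution of the two groups
  define fixed $\Delta$-axis intervals (half-open left, closed right);
  each animal's mean within each interval is compared, with empty cells
  missing and cells holding fewer than two animals per group flagged
  untested.

The slice construction is the default because repeat-length support is
lattice-like (peaks sit ~1 repeat apart): sub-repeat-wide shared-edge
cells are empty for most animals in dense regions, which silently starves
the tests, whereas slices are always populated. It is also the reading
that makes per-cell standard errors and t-tests well defined from a pooled
"global distribution" description: the biological replicates are the
animals, so per-cell replicates must be per-animal quantile-cell means.
That reconstruction is an explicit modeling choice of this package — the
shared-edge variant remains available for sensitivity analysis.

## Per-cell tests, gate, and conventions

For each retained cell the untreated and treated per-animal means are
compared with a two-sided two-sample t-test at $\alpha = 0.05$; a
preliminary two-sided F-test of variance equality at the same level picks
Welch's test when it rejects, Student's otherwise (`variance_gate()`).
The reported difference is untreated − treated with the SE from the chosen
test. No multiple-testing correction is applied by default, matching the
per-cell $p < 0.05$ coloring convention of this analysis style;
`analysis_config(p_adjust = "BH")` enables Benjamini–Hochberg. The group
effect on overall expansion is tested with one-way ANOVA of per-animal
mean $\Delta$CAG.

Degenerate inputs follow fixed conventions rather than erroring mid-run:
identical constant samples give $p = 1$ (difference 0), distinct constant
samples $p = 0$; cells with fewer than two non-missing animals in a group
are reported `tested = FALSE`, never dropped silently; an all-constant
ANOVA returns $F = 0$, $p = 1$. Weighted quantiles use the left-continuous
inverse CDF (smallest support value whose cumulative weight reaches the
target, with $10^{-12}$ slack for accumulated rounding). Serialized tables
carry 6 significant digits, which is what makes rerun outputs
byte-identical.

## The synthetic generator

`simulate_cohort()` emulates the features of the assay that matter to the
statistics:

* **Germline variation** — each animal's modal repeat drawn from
  $N(255, 1)$ (`trace_model()`), the reported spread of the transgene line.
* **Somatic drift** — per tissue, a $\Delta$ distribution with a Gaussian
  core (`within_sd`, the within-animal mosaic spread) convolved with a
  geometric right tail (`skew`, the leading-edge asymmetry of active
  expansion), centred so its total mean equals `mean_shift` exactly; each
  animal draws its own mean from $N(\mathrm{mean\_shift},
  \mathrm{inter\_animal\_sd})$.
* **Assay artifacts** — a geometric PCR stutter ladder toward shorter
  sizes (ratio `stutter_decay`, default 0.2), per-peak Gaussian sizing
  jitter (0.1 bp, typical capillary sizing error), additive intensity
  noise truncated at zero, and finite sampling of the trace
  (`n_points`).

The drift presets encode the study's qualitative regimes, not measured
values: `week8_null` (no drift, no skew — the age at which no animal shows
expansion), `week12_veh` (mean +8 repeats, skew 4, within-animal SD 3 — a
prominent right-skewed expansion), and `week12_xjb` (mean +1, skew 1 —
strong suppression under treatment). Inter-animal SD is 0.5 in both
12-week presets. Sizing jitter means a recovered modal $\Delta$ is exact
only to sub-repeat precision; "no modal drift" is therefore asserted as
$|\Delta| < 0.5$, i.e. rounding to zero repeats.

What the generator does **not** emulate: raw capillary signal, dye
bleed-through, ladder miscalibration, inter-run calibration drift,
sample-specific PCR efficiency, or any mechanistic model of expansion.
Passing tests show the statistical pipeline recovers truth under the
modeled artifact classes; they cannot certify behaviour under artifact
classes the generator omits.

## Verification choices and problem sizes

All stochastic routines take explicit seeds and are deterministic given
one. The test-suite problem sizes were chosen to make the Monte-Carlo
bands meaningful at interactive runtimes: oracle-equivalence checks run
200 random instances per operation against naive brute-force
implementations (tolerance $10^{-9}$); null calibration uses 500 replicate
3-vs-3 cohorts with identical drift, with the binomial band taken over
cohorts — within a cohort the 90 cell tests share the same six animals and
are strongly correlated, so cohorts, not cells, are the independent unit;
effect recovery uses 5 cohorts under the 12-week presets; the week-8
regime 20 cohorts; traces render at 400 grid points for cohort
simulations. Under the null conditions the measured per-cell rejection
rate sits slightly below the nominal 0.05 (the F-gate two-stage procedure
and the non-normal, lattice-quantized slice means with $n = 3$ both push
in that direction) but within the binomial band; the ANOVA type-I rate is
nominal.

## Known limitations

* The germline baseline is the tail *modal*; heteroplasmy of the baseline
  itself (germline mosaicism) is collapsed to one number.
* With $n = 3$ animals per group, per-cell Welch tests have ~2 degrees of
  freedom; significance calls at the leading edge rely on the consistency
  of the effect across cells more than on any single cell.
* No stutter correction: a treatment that changed stutter chemistry rather
  than biology would register as a distribution change.
* Group labels are free-form; the package does not enforce a specific
  experimental design beyond the tail-baseline pairing.
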