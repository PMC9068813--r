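---
title: "Models and methods behind nelfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nelfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nelfkit)
```

# Scope

`nelfkit` implements the quantitative procedures used to characterise how
enhancer RNAs (eRNAs) strip the negative elongation factor (NELF) off
promoter-proximally paused RNA polymerase II: apparent-Kd estimation from
EMSA densitometry via a quadratic ligand-depletion binding model, pausing
indices from strand-specific nascent coverage, single-nucleotide TSS
calling from 5'-end read pileups, eCLIP crosslink-site distance
statistics, SHAPE-MaP reactivity normalisation and structure
classification, and per-residue aggregation of protein–RNA crosslinking
mass-spectrometry spectral counts. Upstream read alignment, peak calling,
transcript-unit discovery, secondary-structure prediction and spectral
searching are out of scope: the package consumes their flat-file outputs
(BED6, bedGraph pairs, site tables, TSV count tables).

Every stage is paired with a synthetic-data generator that emits ground
truth alongside the data, so the whole pipeline is testable — and this
vignette's claims checkable — without downloading anything.

# The quadratic binding model for NELF release

An EMSA release titration mixes a fixed concentration of paused elongation
complex (PEC; Pol II–DSIF–NELF) with increasing eRNA. Densitometry of each
lane gives the released fraction

$$f = \frac{I_{\mathrm{Pol\,II\text{-}DSIF}}}
{I_{\mathrm{Pol\,II\text{-}DSIF}} + I_{\mathrm{Pol\,II\text{-}DSIF\text{-}NELF}}},$$

implemented in `release_fraction()`. Because the PEC (receptor, total
$R = 0.1$ µM by default) and the eRNA (ligand, total $L$ from 0.15 to 1.8
µM) are at comparable concentrations, free-ligand approximations fail and
the fraction follows the ligand-depletion ("quadratic") form

$$f(L) = A\,\frac{(R + L + K_d) - \sqrt{(R + L + K_d)^2 - 4RL}}{2R},$$

implemented in `quadratic_model()`. For $K_d \gg R$ this converges to the
hyperbola $A\,L/(L+K_d)$ (verified to <1% relative deviation at
$K_d = 100R$ in the test suite). The released fraction is a dissociation
readout rather than an equilibrium titration, so the fitted $K_d$ is an
*apparent* value, useful as a comparative measure between RNAs and NELF
variants.

`fit_binding()` estimates $(K_d, A)$ by Levenberg–Marquardt nonlinear
least squares (`minpack.lm::nlsLM`) with $K_d > 0$ and $A \in (0, 1.2]$.
Initialisation uses $A_0 = \max f$ and $K_d$ at the concentration nearest
half-maximum, plus a multistart over five log-spaced $K_d$ values spanning
an order of magnitude beyond the concentration series on both sides; the
best residual wins. This makes recovery robust for $K_d$ well outside the
titration window (the suite round-trips $K_d$ from 0.05 to 20 µM to <1%).
Flat curves are reported `converged = FALSE` (unidentifiable) rather than
fitted. Design choices here were genuinely open:

* **Amplitude is fitted by default.** Gels rarely reach complete
  conversion, so constraining $A = 1$ biases $K_d$ upward when the
  plateau falls short. `fix_amplitude = 1` reproduces the strictest
  one-parameter reading.
* **Replicates.** Published curves are typically means of two gel
  replicates; `fit_binding()` fits the pointwise mean of replicate
  columns by default and exposes `per_replicate = TRUE`.
* **Uncertainty.** A standard error for $K_d$ is taken from the Jacobian
  curvature at the optimum; it quantifies fit precision only, not
  gel-to-gel variability.

The synthetic generator (`simulate_binding_curve()`) adds Gaussian noise
of SD `noise_sd` to the model fractions, truncated to $[0,1]$. No
densitometry error model is available to calibrate against, so the
default `noise_sd = 0.05` (5 percentage points per lane pair) is a
judgement call representative of band quantification on clean native
gels; the truncation mildly biases extreme fractions toward the interior,
which is why Monte-Carlo recovery is asserted on the *median* fitted
$K_d$ (within 15% over 200 replicates at $K_d = 0.14$ µM).

# Pausing index

For a unit with TSS $t$, the pausing index is the ratio of mean read
density in the promoter-proximal window $[t-100, t+200)$ to that in the
gene-body window $[t+400, t+800)$, both in transcript orientation
(windows flip on the minus strand). `pausing_index()` leaves the PI
*undefined* when the body density is zero — undefined units are excluded
from distribution comparisons and counted, never clamped to an arbitrary
large value, since a cumulative-distribution comparison is sensitive to
such imputation. PIs are invariant under any multiplicative rescaling of
the track (`scale_track()`), so all computations run on raw counts and
normalised display scales are purely cosmetic.

Distribution shifts between conditions or NELF-occupancy groups are
tested with the two-sample Kolmogorov–Smirnov test
(`compare_pi_distributions()`, via `stats::ks.test`), with the empirical
cumulative curves returned for plotting. NELF occupancy grouping
(`nelf_tiers()`) splits bound units at configurable score quantiles,
tertiles by default. The published high/mid/low group sizes do not
correspond to an exact tertile split and the underlying rule is not
documented, so the quantile rule is an explicit, reproducible surrogate.

The nascent-coverage generator places a gene's reads multinomially with
per-base weight `pausing_index_true` inside the promoter window and 1
elsewhere, which makes the *expected* promoter/body density ratio equal
the generating PI exactly; at $10^5$ reads per gene the measured median
is within 5% of targets 1–10. It emulates the density contrast only —
real nascent profiles have structured pause peaks ~30–60 bp downstream of
the TSS, termination signal, and mappability gaps, none of which matter
for a ratio of window means but all of which are absent here.

# TSS calling and enhancer assignment

`call_tss()` clusters 5'-end read positions per chromosome and strand by
single linkage with a maximum gap of `merge_gap` (default 25 nt), drops
clusters with fewer than `min_cluster_reads` total reads (default 5,
mirroring the tag threshold used by capped-RNA peak callers), and calls
the TSS at the cluster's maximum-count position, ties broken toward the
5'-most position in transcript orientation. The published pipeline used
an external TSS caller with "standard parameters" that are not specified,
so this simple, oracle-checkable clustering is the package's own
documented choice. Two further conventions:

* The `> 20 reads` high-confidence criterion is a **flag**
  (`well_defined`), not a filter, matching its two-tier published usage;
  whether it counts the called position or the whole cluster is
  ambiguous in prose, so it defaults to the called position with a
  `well_defined_on = "cluster"` switch.
* Extragenic filtering (`filter_extragenic()`) removes calls within any
  gene ±2 kb, strand-agnostically, with the extension kept half-open so a
  call exactly at `gene_end + flank` survives.

`assign_enhancer_tss()` picks exactly one TSS per enhancer transcript
unit among calls on the unit's strand within the unit ±200 nt: highest
read count first, then smallest absolute distance to the unit's 5' end,
then the most upstream position. A call inside two overlapping units may
be assigned to both (how the original analysis resolved this is
unstated; assigning to both is the conservative choice and is flagged).
Curation of pervasive/convergent transcription was done by visual
inspection in the original work; the package substitutes an explicit
rule — reject a unit whose antisense 5'-end signal within ±200 nt of the
assigned TSS exceeds half the sense signal — exposed as
`max_antisense_fraction`.

The 5'-end generator spikes Poisson-distributed read counts at true TSSs
with ±2 nt jitter (80% mass on the exact base) over a uniform background
of 0.01 reads/bp/strand; the caller recovers ≥95% of 100 spiked TSSs
within 2 nt under those conditions. Activity induction
(`classify_induction()`) is a strict `> 1.5`-fold rule on
expression versus baseline, with zero-baseline/nonzero-signal units
counted as induced.

# eCLIP crosslink distances

The crosslink site of a read pair is the first nucleotide of R2;
`extract_crosslink_sites()` tallies those per position (an optional
identical-record dedup stands in for upstream PCR-duplicate removal).
`assign_to_units()` maps sites into same-strand transcript units with
**1-based** distances from the unit 5' end — distance 1 *is* the 5'
nucleotide — so window labels read naturally as 1–200, 201–400, …;
internal genomic coordinates stay 0-based half-open with this one
documented conversion. `window_distribution()` bins distances into
half-open windows `(prev, edge]` (default edges
200/400/600/800/1000/2000) and `compare_window_distributions()` applies
Pearson's chi-squared on the 2×k count table without continuity
correction (k is 3 or 6 here, so Yates' correction would be both
unconventional and conservative); Benjamini–Hochberg adjustment is left
to report level since single comparisons are the norm.

`normalized_profile()` divides each unit's per-position crosslink counts
by that unit's nascent-expression density (reads/bp) before averaging
across units, so highly transcribed units do not dominate the
meta-profile. The published description of this normalisation is loose;
the per-unit-density formula is therefore explicit and a per-window
variant is switchable.

The crosslink generator draws distances from a two-component mixture:
with probability `crosslink_5prime_fraction` (default 0.7, matching the
reported ~70% of pre-mRNA crosslinks within the first 200 nt) uniform on
the first 200 nt, otherwise uniform on the *remainder* of the transcript.
With fraction 0, all mass therefore lies beyond 200 nt — the mixture
parameter is the first-window mass identically, which keeps the binomial
recovery oracle exact. Real profiles are steeper still near the TSS;
uniform-within-component suffices for window-proportion statistics and
keeps the null analytic, but passing tests say nothing about sub-window
shape.

# SHAPE-MaP reactivities

With a modified (1M7) and an untreated channel only — no denatured
control was probed, so no denominator channel exists —
`shape_reactivity()` computes per-position mutation rates
`count/depth`, the raw reactivity `rate_mod − rate_untreated`
(negatives retained by default, clamp switchable), masks positions below
`min_depth` in either channel (default 1000 — high enough that binomial
rate noise at the default simulation rates is negligible, low enough for
desk-scale fixtures; it is configurable for real libraries), and
normalises by the box-plot/percentile scale (`shape_norm_scale()`):
values more than 1.5 IQR above Q3 are excluded as outliers, capped at
10% of the data, and the scale is the mean of the surviving values
ranked between their 90th and 98th percentiles (drop the top 2%, average
the next 8%). The cap matters on bimodal profiles: without it, a mostly
paired RNA with a minority of genuinely reactive positions would discard
its entire reactive class as "outliers" and normalise to its noise
floor. A profile of identical raw values normalises to 1 by
construction.

`median_reactivity_class()` classifies an RNA by the median normalised
reactivity over unmasked positions: `structured` below 0.1,
`intermediate` below 0.15, `flexible` otherwise (strict `<`, cutoffs
configurable). Whether published medians were computed on raw or
normalised reactivities is not stated; normalised is the default and raw
is switchable.

`g_content_bins()` tabulates A/C/G/U frequencies in consecutive 200-nt
bins (5 bins over 1 kb by default), collapsing alternative TSSs closer
than 40 nt to a single representative and letting short sequences
contribute only complete bins (genomic extension to 1 kb requires genome
sequence, which may be supplied instead). `g_enrichment_test()` runs
paired two-sided t-tests of G against each other base's frequency per
bin, reporting raw and BH-adjusted p-values.

The mutation-count generator draws binomial counts at rates 0.05
(unpaired) / 0.005 (paired) / 0.002 (untreated background) at depth
$10^4$; under those conditions normalised reactivity ranks unpaired above
paired positions with AUC > 0.9, and an 80%-paired profile classifies as
structured. The generator models neither sequence-dependent adduct bias
nor read-level mutation co-occurrence, so passing tests validate the
arithmetic and normalisation, not ShapeMapper-grade mutation calling.

# Crosslinking-MS aggregation

`filter_xl()` applies the three post-search quality thresholds with `≥`
semantics — matched ions ≥ 7, TIC subscore ≥ 0.15, identification score
≥ 20, all configurable — keeping decoy records flagged so a decoy/target
FDR can be estimated among survivors. `aggregate_per_residue()` sums
redundant spectral counts (`nseen`) per (subunit, residue) over target
records, honouring an explicit per-analysis exclusion list (e.g.
`"NELF-E:1"` for an overrepresented initiator methionine treated as an
outlier in the published proportions; the exclusion is per-analysis
because it was described for one display only). `subunit_proportions()`
reports each subunit's share of the grand total and splits shares over
residue spans; the default spans put the NELF-E N-terminal region at
1–137 and the tentacle at 138–380 so that the two partitions are
disjoint and proportions add exactly (the quoted spans share residue
138; assigning the boundary residue to the tentacle is the package's
tie-break). An optional ppm mass-error column can be filtered on, with
no default since observed mass deviation is dataset-specific.

# Numerical conventions and degenerate inputs

* Coordinates: 0-based half-open everywhere internally (BED convention);
  1-based labels only in report columns (crosslink distances, residue
  numbers, window labels).
* Zero denominators are surfaced, not patched: zero-intensity lanes give
  `NA` fractions with a warning, zero body density gives undefined PI,
  zero-expression units are excluded from normalised profiles with a
  count, all-masked SHAPE profiles error.
* Ties: TSS calls break toward the 5'-most position; enhancer assignment
  breaks count ties by distance, then upstream position.
* All generators derive per-stage RNG substreams from one seed by fixed
  offsets, so stages are reproducible in isolation and in any order.

# Problem sizes

The shipped test suite and acceptance script run entirely on synthetic
data at sizes chosen to make sampling error comfortably smaller than the
asserted tolerances: 6 genes × $10^5$ reads for each pausing-index
target, 100 TSSs at mean 50 reads over a 1 Mb chromosome, $10^4$
crosslink reads, 200 Monte-Carlo binding curves, 200-nt SHAPE profiles at
depth $10^4$, and $10^4$-row crosslink-search tables. The complete run
takes well under a minute on one CPU.

# Known limitations

* The apparent $K_d$ is a comparative, model-dependent summary of a
  dissociation readout; it is not an equilibrium affinity.
* TSS clustering parameters are surrogates for an external caller whose
  settings are not published; absolute call sets on real data will
  differ even where recovery on synthetic spikes is exact.
* The NELF tier split is a quantile rule, not the unpublished original.
* Synthetic generators emulate the statistical features each estimator
  consumes (density ratios, mixture masses, spike positions, binomial
  rates), not sequencing realism: no mappability structure, no
  fragment-length or sequence bias, no read-level error model.
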