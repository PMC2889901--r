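---
title: "Design and analysis methods of the splicearray toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and analysis methods of the splicearray toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicearray)
```

# Overview

`splicearray` implements the three layers of a two-color splice-array
platform. A **designer** turns transcript models into exon, junction,
control and negative oligonucleotide probes under explicit thermodynamic
constraints. A **simulator** produces two-channel intensities from known
isoform mixtures, so that the statistical engine can be validated against
ground truth. An **analysis engine** normalizes, calibrates the no-change
variance from self-to-self hybridizations, and classifies every gene as
unchanged, differentially expressed, or a splice candidate, ranked by a
form-change score.

This vignette records the model assumptions, the tunable parameters and
their defaults, the numerical conventions, and the design decisions taken
where the problem was genuinely open.

# Thermodynamic layer

All probe selection is driven by three temperatures per sequence.

**Duplex Tm.** Nearest-neighbor enthalpy/entropy sums under the unified DNA
parameter set, with duplex-initiation terms per terminal base, a logarithmic
monovalent-salt entropy correction (`0.368 (L-1) ln[Na+]` e.u.) and the
strand-concentration term for a non-self-complementary duplex
(`R ln(C_T/4)`). The conditions record ([hyb_conditions()]) defaults to
**0.1 M Na+ and 1 µM strand**. The choice of sodium molarity deserves a
note: the platform's constraint set (target 75 °C, window 70--80 °C, limit
60 °C for cross-hybridization) stems from a proprietary Tm scale whose
parameterization is not public. Under the unified parameter set at 1 M Na+
a mid-GC 30--36-mer melts near 85--90 °C and the 70--80 °C window would be
reachable only by very AT-rich probes; at 0.1 M the same window is centered
on mid-GC probes of exactly this length class. We therefore fix 0.1 M as
the default so that the *printed* constraints are self-consistent, and keep
the conditions fully configurable. Absolute temperatures in this package
are consequently not comparable to the original platform's values; all
constraints are enforced on the package's own scale.

**Folding screen.** `compute_fold_tm()` is a deterministic hairpin scan,
not a partition-function fold: every perfectly Watson-Crick-paired stem of
at least 4 bp enclosing a loop of at least 3 nt is enumerated (including
inner-truncated sub-stems, since a GC-rich core can out-melt its full run),
and the stem's unimolecular melting temperature is computed from the
nearest-neighbor sums plus a fixed loop entropy penalty of −15 e.u. The
result is floored at 0 °C. The screen is used only to rank and to tag
(`fold_high` above 60 °C, the hybridization temperature); a heuristic that
can be verified by brute-force enumeration was deliberately preferred over
a thermodynamically complete fold.

**Cross-hybridization screen.** `compute_cross_tm()` performs a
seed-and-extend search (10-bp exact seeds, the shortest duplex the Tm model
accepts) for maximal perfectly matched regions between a probe and a
background of target sequences, and reports the best nearest-neighbor Tm
over all matched sub-regions of at least 10 bp, capped at the probe's own
duplex Tm. Matches below the seed length are ignored: a sub-10-bp duplex
cannot approach the 60 °C screening limit under these conditions. Inside
`build_design()` the background of a probe is **every target of every other
gene** in the design; same-gene targets are excluded because isoforms of
one gene share sequence by construction and the screen is meant to catch
off-gene binding. The design-wide search only examines k-mers that occur
more than once in the whole target set, which keeps it near-linear on
random sequence.

# Probe design

Targets are extracted in spliced-transcript coordinates (0-based half-open
internally; GTF/GFF3 I/O converts from 1-based inclusive):

* **Exon targets** are 36 bp: a centered window for exons ≥ 36 bp
  (centering maximizes the distance to neighboring-exon boundaries);
  shorter exons are padded from both neighbors with an even split, the odd
  remainder going to the 5′ side, and terminal exons padding only inward.
  A transcript shorter than 36 bp becomes a single whole-transcript target
  tagged `short_target`.
* **Junction targets** take up to 25 bp per side (50 bp total), recruited
  across multiple small exons where needed and truncated at transcript
  ends, with the realized flank lengths recorded.
* Identical target sequences arising from different isoforms of a gene are
  deduplicated by sequence; isoform exon unions are never merged.

**Exon probes** enumerate all windows of 30--36 bp. Among windows with Tm
in 70--80 °C and cross-Tm ≤ 60 °C, the window with Tm nearest 75 °C wins;
ties go to the smaller fold Tm, then the shorter window, then the leftmost.
If no window qualifies, the design still emits the best possible probe —
minimizing (cross Tm, fold Tm, |Tm − 75|) lexicographically — and tags the
violated constraints. **Junction probes** enumerate arm pairs anchored at
the junction, each arm between `min_arm = 10` bp and its flank length,
total length 25--42 bp. The primary objective is arm balance
(`min |Tm_left − Tm_right|`); within `balance_tol = 1 °C` of the best
balance, total Tm nearest 75 °C decides. The 10-bp arm floor reflects that
a shorter arm contributes no junction specificity; the 1 °C band
operationalizes a two-level objective ("as balanced as possible, then best
total Tm") that would otherwise be ill-posed. Junctions whose flanks cannot
host two minimum arms are recorded as design failures rather than silently
dropped.

All scores that feed a lexicographic comparison are rounded to 10⁻⁶ °C
first: windows with identical nearest-neighbor content then tie exactly and
fall through to the integer tie-breaks (length, then position), making the
design bit-reproducible across summation orders.

**Controls.** Each control transcript receives `n_control_positions = 12`
full-length optimum probes evenly spaced along its length, and per full
probe two half-oligonucleotides: the split point minimizes the |ΔTm| of the
two halves over all internal splits (each half ≥ 10 bp), and each half is
padded back to the parent length with an AT alternation (3′ pad for the 5′
half and vice versa). Control and negative probes are replicated 12 times
in the manifest so intra-array variability is measurable. **Negative
probes** are composition-matched shuffled sequences screened to cross-Tm
≤ 40 °C against every target.

# The hybridization simulator

The simulator exists to make the statistical engine falsifiable: every
analysis claim in the test suite is checked against its ground truth.

Signal model per probe and channel:

$$ I = \Big(\textstyle\sum_i c_i\, w_i\, b_i + B\Big)\, a_p\, 2^{\varepsilon}, $$

* `c_i` — isoform concentration (arbitrary units; per-gene concentrations
  are drawn log2-normal with mean 11 and SD 1 log2 units, i.e. around
  2000, well above background, emulating the "expressed in this tissue"
  gene selection of a real design);
* `w_i` — match weight: 1 when the full probe is contained in the isoform,
  `residual_fraction = 0.15` when **exactly one** junction arm (or one
  half-oligo half) is contained, 0 otherwise. The residual default encodes
  the observed behavior of half-matched probes: a sharp drop that does not
  reach zero. The exact fraction is unknown, so it is a parameter;
* `b_i` — optional positional-bias attenuation
  `exp(−rate × d₃′/kb)` with `positional_bias_rate = 0` by default
  (unbiased labeling); the knob emulates 3′-biased labeling protocols;
* `B` — per-spot background, truncated normal (mean 100, SD 10), **drawn
  once per spot and shared by both channels**. This makes "zero noise ⇒
  channels identical" hold exactly while keeping the negative-control
  detection cutoff meaningful; channel-specific background is deliberately
  not modeled;
* `a_p` — per-probe affinity, log2-normal with SD 0.3 (a free modeling
  choice; affinities cancel in ratios);
* `ε` — per-spot, per-channel Gaussian log2 noise. Gene-probe noise is
  multiplied by `gene_noise_mult = 1.1`, reflecting that gene-probe spread
  runs a little above control-probe spread on physical arrays.

`calibrate_noise()` finds by monotone root search the per-channel noise SD
for which a simulated self-to-self array has a log2 fold-change SD equal to
a requested value, default **0.093** — the platform's measured self-to-self
spread — and `simulate_cohort()` calibrates automatically when
`noise_sd_log2` is `NULL`.

What the generator does *not* emulate: dye-specific photobleaching,
scanner saturation, spatial artifacts, sequence-dependent affinity,
cross-hybridization of imperfect duplexes (probes bind only exact
containments or single arms), and biological between-pair heterogeneity
(an event has the same effect size in every pair). Passing tests therefore
demonstrate the correctness and calibration of the algorithms under a
clean two-color error model, not performance on clinical material.

Spike-in controls use three control transcripts at the kilobase lengths of
typical spike-ins (7.1/4.9/4.6 kb) assigned to three concentration tiers
(1000/8000/64000 units), identical in both channels.

# The analysis engine

**Preprocessing** has three stages. (1) *Detection*: per array and channel,
the cutoff is the mean + 3 SD of the negative-control spots; a spot is
detected only if both channels pass. Probes undetected in one channel are
excluded from gene statistics rather than floored — flooring is exactly the
mechanism by which expression changes of weakly expressed genes masquerade
as splice changes. (2) *Spot calibration*: within each replicated
control-probe family, spots deviating from the family median by more than
3 MAD are flagged. The MAD here is pooled across families: a per-family MAD
over ~12 replicates is noisy enough to flag a few percent of clean spots,
which measurably biased the downstream variance calibration; the pooled
scale keeps the false-flag rate at the nominal Gaussian level while still
catching gross (e.g. 10×) spot artifacts. (3) *Normalization*: per-array
median-centering of the log-ratios over detected gene probes, with an
optional intensity-dependent `lowess` centering.

**Variance calibration.** On each self-to-self array the spreads σ_g (gene
probes) and σ_c (control probes) are estimated with the Gaussian-consistent
robust scale (1.4826·MAD); the sample SD would inherit a small downward
bias from the spot-calibration truncation. `CF = mean(σ_g/σ_c)` transfers
the control spread to the gene-probe scale; on any test array
`σ* = CF·σ_c` uses that array's own controls, and the robust-change
threshold is `TH = ±kσ*` with `k = 3` (configurable; larger k is stricter).
A zero σ_c (noise-free input) is a named error — calibration is then
meaningless.

**Gene classification** (`analyze_gene`). Genes with fewer than
`min_probes = 4` detected probes are `not_detected`; low-coverage genes
are the main false-positive reservoir, so they are excluded rather than
scored. Otherwise with deviations `d_p = r_p − μ_G`:

* `E_expr = Σ d_p²` is the single-shift (pure expression) error;
* `E_iso` is the exact optimal two-group split of the sorted ratios —
  the minimal mixture alternative, solvable exactly in 1-D (the optimal
  2-means partition is an interval split of the sorted sample), so
  `E_iso ≤ E_expr` always;
* a gene is a `splice_candidate` when at least one probe exceeds
  `μ_G ± kσ*` **and** `E_iso ≤ α·E_expr` with `α = 0.5`: the mixture must
  explain at least half the variance the expression hypothesis leaves. The
  α margin is a package choice — requiring only `E_iso ≤ E_expr` would be
  vacuous since the two-group model nests the one-group model;
* otherwise `expression_change` when `|μ_G − center|` exceeds the
  threshold (center 0 for a single pair), else `no_change`;
* `form_change = Σ_p max(0, |d_p| − kσ*)/σ*`: the total deviation mass
  beyond the corridor in σ units. It is zero exactly when no probe leaves
  the corridor and grows with both the number and the magnitude of
  deviating probes, which is what a relative ranking of candidates needs.
  Whether the original platform's score also folded in the hypothesis
  errors is not documented; this definition is the package's own.

**Replicate analysis.** Probe ratios are averaged across all pairs with no
sample exclusion (outlier removal would distort prevalence); a probe
enters the mean profile only when detected in *every* pair, which
implements the "clearly above detection" rule without dropping samples.
The gene analysis is re-run on the mean profile with a pooled σ* (mean over
pair arrays) and the fold-change reference set to the array-wide mean
ratio. Candidates are ranked by form change with per-gene prevalence (the
fraction of pairs individually calling the gene) attached. Note the pooled
σ* is deliberately *not* rescaled by √n_pairs: the thresholds stay on the
single-array scale, so averaging mainly suppresses the noise, sharpening
rather than redefining the corridor.

**Positional-bias QC.** For each control transcript, the mean log2 signal
(both channels, averaged over arrays, one point per probe — replicate spots
share an affinity and must not be pseudo-replicated) is regressed on the
probe's distance from the 3′ end; 3′-biased labeling yields a negative
slope, flagged at p < 0.01. A constant channel imbalance shifts the
intercept only.

# Numerical conventions and degenerate inputs

* Tie-breaks are lexicographic and documented (scores rounded to 10⁻⁶ °C,
  then integer criteria), so designs are byte-identical across runs and
  platforms for a given seed.
* Every stochastic entry point takes an explicit integer seed; the
  designer's only randomness is negative-probe generation.
* Degenerate inputs are named errors, not warnings: missing chromosomes,
  zero-length exons, duplicate exon indices, absent negative controls,
  zero control-probe spread, missing σ*, fewer than 2 pairs in replicate
  analysis, fewer than 5 control positions in the bias QC.
* An empty cross-hybridization background returns 0 °C with a warning (a
  screen over nothing is not an error, but it should not pass silently).

# Problem sizes used by the test suite

The suite validates the designer against exhaustive-enumeration oracles on
100 seeded exon and 100 junction targets, the calibration statistics on
10,000-probe self-to-self arrays (robust-change rate against the analytic
Gaussian null, 2Φ(−3)), σ*/CF recovery across 10 seeds, and detection power
on a simulated cohort of 500 genes × 20 pairs with 50 exon-skip genes
(switch fraction 0.5) and 50 two-fold expression genes at noise calibrated
to the 0.093 self-to-self spread. These sizes give the statistical checks
enough resolution (binomial intervals of a few 10⁻³, SD estimates within a
couple of percent) while remaining single-CPU-friendly.

# Known limitations

* Absolute Tm values are tied to the package's parameterization and salt
  default; they are self-consistent, not comparable to proprietary scales.
* The folding screen is a stem heuristic; pseudoknots, bulges and
  mismatched stems are invisible to it.
* Cross-hybridization considers only perfectly matched local duplexes
  within the design's own targets — not a genome, and not imperfect
  duplexes.
* The simulator's match-weight rule assigns zero signal to a probe whose
  two arms both match an isoform non-contiguously; physically each arm
  could retain residual binding.
* Isoform-level concentration deconvolution is out of scope; the engine
  flags and ranks genes, it does not reconstruct isoform abundances.
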