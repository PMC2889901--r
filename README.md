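# splicearray

Desk-scale toolkit for two-color **exon/junction splice microarrays**: it
designs thermodynamically balanced oligonucleotide probes from transcript
models, simulates realistic two-channel hybridizations from known isoform
mixtures, and analyzes the resulting intensities to separate whole-gene
expression changes from changes in splice-form composition.

The package is aimed at people building or studying hybridization-based
splicing assays: the designer and the analysis engine are full
re-implementations of a splice-array platform, and the simulator makes the
whole pipeline testable on a laptop, without clinical samples, a scanner, or
any download.

## What it computes

**Probe design.** For every gene, 36-bp exon targets (short exons are padded
from their neighbors) and up to 50-bp junction targets (25 bp per side,
recruited across small exons) are extracted from the spliced transcripts.
Exon probes of 30–36 bp are chosen by enumerating every window and picking
the one with nearest-neighbor duplex Tm closest to 75 °C within the 70–80 °C
acceptance window, subject to a 60 °C cross-hybridization limit and a
secondary-structure screen. Junction probes (25–42 bp) straddle the junction
with two arms whose Tms are balanced (`min |Tm_left − Tm_right|`) before
optimizing total Tm. When no window complies, the best possible probe is
still emitted and tagged (`tm_out_of_range`, `cross_hyb_high`, `fold_high`,
`short_target`) so that quality enters the analysis instead of censoring the
design. Control transcripts get full-length probes spaced along their length
plus *half-oligonucleotides* — thermodynamically equal halves, AT-padded to
full length — which emulate 100% splicing at a boundary; shuffled negative
probes are screened to cross-Tm ≤ 40 °C.

**Analysis.** Let `r_p = log2(Cy5_p/Cy3_p)` be a probe's normalized
log-ratio. Self-to-self hybridizations calibrate the no-change variance: on
each, the gene-probe spread `σ_s,g` is related to the control-probe spread
`σ_c` by a calibration factor, `σ_s,g = CF·σ_c`. On a tumor-vs-normal array
the no-change SD is then estimated as `σ* = CF·σ_c` from that array's own
controls, and robust change is `|r| > TH = 3σ*`. For each gene `G` with mean
ratio `μ_G`, probes outside `μ_G ± 3σ*` signal potential splice-form
variation; the engine computes the error of the expression hypothesis
(`E_expr = Σ(r_p − μ_G)²`) and of the isoform-mixture hypothesis (`E_iso`,
the exact optimal two-group split), and ranks candidates by the **form
change** `Σ_p max(0, |r_p − μ_G| − 3σ*)/σ*`. Replicate analysis averages
each probe across all pairs (no sample exclusion) and re-runs the gene
analysis on the mean profile.

**Simulation.** Probe signals are concentration-weighted sums over isoforms
(full match = 1, exactly one junction arm matched = `residual_fraction`,
default 0.15), plus per-spot background and multiplicative lognormal noise
calibrated so a self-to-self array has fold-change SD 0.093. Spike-in
controls at three channel-balanced tiers and an optional 3'-labeling-bias
knob complete the model.

## Worked example

```r
library(splicearray)

co <- simulate_cohort(n_genes = 60, n_splice_genes = 6,
                      n_expression_genes = 6, n_pairs = 6, n_self = 3,
                      seed = 7)
prep   <- preprocess(co$intensities, co$design, k = 3)
varest <- estimate_variability(prep, k = 3)
res    <- replicate_analysis(prep, varest)
res
#> <candidate table: 6 splice candidates of 60 genes; pooled sigma* = 0.0898>
#>   gene_id form_change prevalence direction
#> 1   G0012   16.124509          1      down
#> 2   G0048   14.873371          1      down
#> 3   G0043   14.124160          1      down
#> 4   G0055   14.007950          1      down
#> 5   G0010    8.363687          1     mixed
#> 6   G0009    8.172414          1     mixed
co$truth$gene_id[co$truth$event == "exon_skip_switch"]
#> "G0009" "G0010" "G0012" "G0043" "G0048" "G0055"
```

All six simulated exon-skip genes (and none of the 2-fold expression-change
genes) are recovered as splice candidates. `form_change` is the total probe
deviation beyond the `±3σ*` corridor in `σ*` units — here each event leaves
2–4 probes about 1 log2 unit away from the gene mean against `σ* ≈ 0.09` —
and `prevalence = 1` means every one of the 6 pairs called the gene
individually. `varest$CF` (≈ 1.07 here) shows the gene-probe spread running
slightly above the control-probe spread, which is why the controls alone
would underestimate the experimental variation.

The same pipeline is scriptable from a shell via
`Rscript inst/cli/splicearray.R <design|simulate|analyze> --seed ... --out ...`.

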