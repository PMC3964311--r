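# reporternoise

Intrinsic/extrinsic decomposition of gene-expression noise for two-reporter
gene circuits with **non-identical** reporters.

## The problem

Fluctuations in a fluorescent reporter's level combine *extrinsic* noise —
cell-wide variation (polymerase and ribosome abundance, cell state) that
affects every gene in a cell — with *intrinsic* noise, the gene's own
stochastic synthesis and degradation. The classical two-reporter assay
separates the two by co-expressing two identically regulated reporters:
extrinsic noise correlates them, intrinsic noise does not. That assay
breaks down exactly where it is most interesting — when one reporter sits
inside a regulatory circuit (say, a LacI negative-feedback loop tunable by
IPTG) while the other is constitutive, because the two reporters then no
longer share the same sensitivity to the cell-wide state.

`reporternoise` is for experimentalists and modellers analysing such
circuits by flow cytometry. It implements a calibrated decomposition for
non-identical reporters, the associated cytometry preprocessing, a
stochastic circuit simulator to generate ground-truth data, and
delta-delta-Ct copy-number estimation for the clones.

## The statistic

Per cell, reporter levels are products of a shared extrinsic factor and
independent gene-specific intrinsic factors; on the log scale, for an
inducer titration indexed `i = 1..N` with well `N` fully induced,

    total_i      = Var(log X_i)                  (per reporter)
    alpha_i      = Cov_i / Cov_N                 (regulated reporter X)
    ext_X,i      = alpha_i * Cov_i
    ext_Y,i      = Cov_N                         (constitutive reporter Y)
    int          = total - ext                   (per reporter)

where `Cov_i = Cov(log X_i, log Y_i)`. The sensitivity coefficient
`alpha_i` rescales the regulated reporter's response to the shared
extrinsic variable; it is calibrated so the constitutive reporter's
extrinsic noise is the same in every well as in the fully induced well,
where both reporters behave constitutively and `alpha_N = 1` exactly. The
classical raw-moment estimators (`elowitz_decompose()`) are included as an
independent cross-check for the identical-reporter limit.

## Worked example

Simulate the default negative-feedback titration (7 IPTG points from
0.0625 to 25 uM at Dox 5000 ng/ml, 3 replicates, 20,000 cells per well),
preprocess (scatter gate, positive gate on the constitutive dsRed channel
against an uninduced control, 2.5-s.d. trim) and decompose:

```r
library(reporternoise)
cfg <- default_pipeline_config("negative_feedback", seed = 1)
run_dir <- tempfile("nf_run")
run_simulate(cfg, run_dir)
bd <- run_decompose(cfg, run_dir)
s <- summary(bd)   # replicate means +/- s.d. per well and reporter
s[s$reporter == "X", c("iptg_uM", "cv2_total_mean", "cv2_ext_mean",
                       "cv2_int_mean", "alpha_mean", "mean_mean")]
```

```
 iptg_uM cv2_total_mean cv2_ext_mean cv2_int_mean alpha_mean mean_mean
  0.0625         0.0279      0.00271       0.0252      0.350      71.3
  0.1697         0.0276      0.00283       0.0248      0.358      72.4
  0.4605         0.0258      0.00273       0.0230      0.351      79.4
  1.2500         0.0198      0.00367       0.0161      0.407     121.4
  3.3930         0.0187      0.00829       0.0105      0.612     263.4
  9.2100         0.0344      0.02039       0.0140      0.960     380.1
 25.0000         0.0368      0.02212       0.0147      1.000     388.4
```

Reading the table: at low IPTG the feedback is strong (LacI fully active),
and the regulated zsGreen1 channel shows *lower* extrinsic (0.0027 vs
0.0221) and total (0.0279 vs 0.0368) noise than at full induction, at the
cost of slightly *higher* intrinsic noise (0.0252 vs 0.0147, expression
having dropped ~5.4-fold) — negative feedback suppresses cell-wide
fluctuations but cannot remove, and slightly amplifies, gene-local ones.
`alpha` falls from 1 at full induction to ~0.35 under strong feedback: the
loop roughly third-fold attenuates the reporter's response to the shared
extrinsic state. `plot(bd, reporter = "X")` draws the components against
IPTG (total: green squares, extrinsic: red triangles, intrinsic: blue
diamonds), and `run_validate(cfg)` reruns the ground-truth checks
(pure-extrinsic / pure-intrinsic / mixture scenarios, small-gate filtering,
classical-estimator agreement).

Copy-number estimation from a qPCR Ct table (here the shipped synthetic
two-copy example):

```r
qpcr_copy_number(system.file("extdata", "qpcr_synthetic_2copy.csv",
                             package = "reporternoise"))
```

```
qPCR copy-number estimate (delta-delta-Ct)
  efficiencies: transgene 1.060, reference 0.981
  ratios: 1.886, 1.849, 2.173
  mean 1.969 +/- 0.178  ->  call: 2 copies
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/reporternoise.R` (subcommands `simulate`, `decompose`,
`validate`, `qpcr`).

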