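# pulsekin

Genome-wide RNA synthesis, processing and decay rates from a single
4-thiouridine (4sU) pulse.

## The problem

Metabolic labeling with 4sU marks RNA made during a short pulse. After
purifying the labeled fraction and sequencing it alongside total RNA from
the same sample, per-gene kinetic rates can be estimated from one time
point under the steady-state assumption — a design suited to small, intact
tissue samples (a larval brain, an organoid) where pulse–chase time courses
are impractical. `pulsekin` implements that estimator together with the
downstream analyses such a study needs: expression filtering and TPM
recomputation from intron/exon count tables, spike-in scaling between the
pull-down and total libraries, half-life capping derived from purification
specificity, gene-feature annotation (transcription factors, cell-type
specificity, H3K27me3 peak categories), stability percentiles and rank
tests, a winsorized interaction regression of log decay rates with a
stratified bootstrap, and a nascent-versus-total derepression test. A
ground-truthed synthetic-data generator makes every stage testable by
parameter recovery.

## The model

Each gene follows first-order kinetics,

    dP/dt = alpha - k_p * P        (premature RNA, synthesis alpha in TPM/min)
    dM/dt = k_p * P - k_d * M      (mature RNA, processing k_p, decay k_d in 1/min)

with steady state P* = alpha/k_p and M* = alpha/k_d. Intronic signal
measures P, exonic signal measures P + M, so mature RNA is
"total − pre-mRNA". A pulse of length t labels

    P_L(t) = P* (1 − e^{−k_p t})
    M_L(t) = M* [1 − (k_d e^{−k_p t} − k_p e^{−k_d t}) / (k_d − k_p)]

and the estimator inverts this: synthesis from the scaled labeled signal
(`alpha = s·L/t` in the short-pulse mode, or exact inversion), then

    decay rate  k_d = alpha / (total − pre-mRNA),    half-life = ln2 / k_d.

Unlabeled RNA carried through the pull-down at a ratio r (e.g. 1:100)
bounds the longest resolvable half-life at `ln2·t/r` — 1386 min for r =
0.01 at t = 20 min — so reported half-lives are capped (default 1000 min).

## Worked example

```r
library(pulsekin)

cfg <- simulation_config(n_genes = 2000, seed = 101)  # 20-min pulse defaults
sim <- simulate_experiment(cfg)                       # truth + count tables
fit <- fit_kinetics(sim$counts, t_label = 20, spike_ins = cfg$spike_in_spec)
fit
#> Steady-state 4sU labeling kinetic fit
#>   genes: 1986 (of 1986 expressed; 0 degenerate dropped)
#>   pulse: 20 min; pull-down scale s = 0.1309 (spike_in); linear synthesis
#>   median half-life: 79.5 min (0.0% at the 1000-min cap)

summary(fit)
#> kinetic fit over 1986 genes (pulse 20 min, scale 0.1309)
#>                  Q1    median       Q3
#> half_life 41.010000 79.480000 143.9000
#> synthesis  0.136600  0.489200   1.6320
#> decay      0.004817  0.008721   0.0169
#> sd(log10 synthesis) = 0.779, sd(log10 decay) = 0.392
#> 0.0% of genes at the half-life cap

head(coef(fit), 3)
#>            synthesis processing       decay
#> gene_00001 0.1840855 0.11923284 0.023851290
#> gene_00002 1.3507870 0.11152581 0.005379940
#> gene_00003 0.1333455 0.06080047 0.008189747
```

The generator drew half-lives with median 82 min and log10 spreads
0.79/0.44; the fit recovers them from the noisy count tables (the small
shortfalls in the medians and spreads reflect spike-in scale noise and the
short-pulse approximation — see the methods vignette). `plot(fit)` draws
the half-life histogram with the cap marked; `predict(fit)` pushes the
estimated rates back through the labeling equations.

Downstream, `stability_percentile()`, `group_stability_test()`,
`classify_h3k27me3()`, `classify_cts()`, `fit_decay_model()` and
`bootstrap_model()` reproduce the feature-level statistics, and
`run_pipeline(run_config(...), outdir)` chains every stage over files on
disk into TSV outputs plus a JSON summary.

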