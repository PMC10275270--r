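---
title: "Steady-state RNA kinetics from a single 4sU pulse: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state RNA kinetics from a single 4sU pulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsekin)
```

# The kinetic model and its assumptions

`pulsekin` treats every gene as a two-compartment first-order system:
premature RNA is produced at rate $\alpha$ (TPM/min), processed to mature
RNA at rate $k_p$ (1/min), and mature RNA decays at rate $k_d$ (1/min).
Three assumptions make a single labeling time point sufficient:

1. **Steady state.** Total RNA levels do not change over the assay, so
   $P^* = \alpha/k_p$ and $M^* = \alpha/k_d$. `steady_state_check()`
   quantifies this by the $r^2$ of log abundances between two profiles
   (e.g. before/after the incubation interval).
2. **Intronic signal measures pre-mRNA.** The exonic quantification of a
   gene covers both premature and mature molecules, the intronic
   quantification only premature ones, so mature = total − pre-mRNA
   (clipped at zero; see *Degenerate genes* below).
3. **Uniform labeling.** Every molecule initiated or elongating during the
   pulse acquires label (an incorporation-efficiency parameter below 1 is
   exposed in the generator but defaults to complete incorporation).

With zero labeled material at pulse start, the labeled pools follow

$$P_L(t) = P^*(1 - e^{-k_p t}), \qquad
  M_L(t) = M^*\left[1 - \frac{k_d e^{-k_p t} - k_p e^{-k_d t}}{k_d - k_p}\right],$$

which saturate at the steady-state pools and accrue as $\alpha t$ for
short pulses.

# The estimator

`fit_kinetics()` runs five steps on a count table holding paired total and
pull-down libraries:

1. **Expression filter**: a gene is kept when at least one library group
   (condition × fraction) shows ≥ 10 exonic counts in at least
   ceiling(2/3 × group size) libraries — for three replicates, two must
   pass. Exonic-only filtering is the default because intronic counts are
   absent for intronless genes; the region is configurable.
2. **TPM recomputation** after removing spike-in (and any other excluded,
   e.g. rRNA) rows, so each library's TPM sums to $10^6$ over retained
   rows.
3. **Premature/mature split** per gene and library.
4. **Pull-down scaling.** TPM is relative within a library, so labeled
   abundances need a factor $s$ mapping them onto the total-RNA TPM scale.
   The default uses thiolated spike-ins present at known equal amounts in
   both fractions: each spike-in's signal per unit mass is expressed
   relative to the gene content of its library, and $s$ is the geometric
   mean over spike-ins of the total/pull-down ratio. The geometric mean
   (rather than a median) is the natural pooling for multiplicative
   ratios and has noticeably lower sampling error with a ten-spike set.
   Alternatives: a fixed factor, or an anchor mode that chooses $s$ so the
   resulting median half-life matches a supplied value.
5. **Rates.** Linear (default) synthesis $\alpha = s\,L/t$ from the total
   labeled signal $L$; then $k_d = \alpha/(\text{total} - \text{pre})$,
   $k_p = \alpha/\text{pre}$ (missing for intronless genes), half-life
   $\ln 2/k_d$, and delta-method CVs assuming independent errors:
   $\mathrm{cv}_{k_d}^2 = \mathrm{cv}_\alpha^2 +
   (\mathrm{var}_{\text{tot}} + \mathrm{var}_{\text{pre}})/
   (\text{total}-\text{pre})^2$, with replicate sample variances.

The **exact** synthesis mode inverts the labeled-pool solution with
$k_p = \alpha/P$, $k_d = \alpha/M$ tied to the observed pools, by a
fixed-point iteration $\alpha \leftarrow \alpha \cdot L_{obs}/L(\alpha)$
initialized at the linear estimate. It removes the downward bias the
linear mode incurs when an appreciable share of labeled molecules decays
within the pulse. Genes whose labeled signal reaches the steady-state pool
(unresolvably fast decay) or that fail to converge in 100 iterations keep
the linear estimate and are flagged `converged = FALSE`.

The linear mode remains the default because it embodies the same
short-pulse logic as the specificity cap (below) and because exact
inversion treats all pull-down signal as labeled — in the presence of
carryover contamination it converts contamination directly into synthesis,
while the linear mode's two biases (labeled decay within the pulse,
contamination inflation) partially offset.

## Purification specificity and the half-life cap

If the pull-down carries unlabeled RNA at ratio $r$ relative to labeled
signal, a gene with labeled fraction below $r$ is indistinguishable from
contamination. Under the short-pulse approximation the labeled fraction of
the mature pool is $k_d t$, so the longest resolvable half-life is
$\ln 2 \cdot t / r$: 1386 min for $r = 0.01$ and $t = 20$, conventionally
rounded down to a 1000-min reporting cap. `apply_cap()` rewrites reported
half-lives only; decay rates are untouched, and the regression stage
bounds the tail by winsorization instead.

A consequence worth stating explicitly: carryover does not push genes
*over* the cap, it pulls them *under* it. Contamination adds
$r \cdot \text{total}$ to the pull-down signal, which places a floor
$\approx r/t$ under the estimated decay rate and hence a ceiling near
$\ln 2\, t/r$ on estimated half-lives. In simulations the capped fraction
is therefore *smaller* with 1:100 carryover than without it — the same
resolvability argument that motivates the cap, seen from the other side.

## Degenerate genes

With replicate noise, intronic TPM occasionally exceeds exonic TPM in a
single library even when the gene's mean premature pool is well below its
total. Rates are computed from condition means, so exclusion from rate
estimation applies only to genes degenerate at the mean level
(mean total ≤ mean premature); the per-library excursions remain flagged
in the expression profile. Dropping per-library-degenerate genes instead
would truncate the unstable tail (their premature/mature ratio
$k_d/k_p$ is high) and visibly bias the recovered median half-life.

# Feature annotation

* **Transcription factors** and other list-based features are plain id
  lists matched against the rate table's universe.
* **Cell-type specificity**: a gene is CTS when any cell type in a
  single-cell enrichment table shows $p < 0.05$ and linear fold change
  ≥ 2. Fold change is taken on the linear scale ("at least twofold").
* **H3K27me3 categories**: peaks within ±1 kb of the TSS set flag A,
  within ±1 kb of the TES flag C, overlapping the gene span flag B;
  the category is the exact flag combination (8 values including "none"),
  and the "extended" genes (category ABC) are the me3 feature used in the
  regression. Windows are symmetric around the TSS/TES points — the
  conservative reading of "within 1 kb" — and configurable; upstream of a
  minus-strand gene lies at higher coordinates. GTF input is 1-based
  closed, BED 0-based half-open; both are normalized on import, and
  overlap means non-empty intersection, so splitting a peak into abutting
  fragments changes nothing. Multi-isoform genes are collapsed to their
  outermost span. The AC category is computed and retained; it is
  typically too scarce to display and can be excluded at that stage.

# Stability statistics and the feature regression

Stability percentiles are the rank transform of −decay (ties averaged), so
the most stable gene sits at 100. Group tests are two-sided Mann–Whitney U
against all other genes, exact for groups under 20 without ties, normal
approximation with tie correction otherwise; stars follow the display
thresholds $p < 0.05$, $p < 10^{-9}$, $p < 10^{-39}$. Composition
enrichment combines the within-group feature fraction with a two-sided
Fisher exact p; odds ratios carry Woolf (log-normal) intervals with the
Haldane 0.5 correction when a cell is zero.

For the regression, decay rates are log10-transformed and winsorized at
the top and bottom 1% (linear-interpolation quantiles; the convention is a
package choice since several exist), then fit by OLS on the three binary
features, additive or with all interactions. The interaction model is
saturated over the $2^3$ cells: its coefficients are computed in closed
form from the cell means, so fitted values equal cell means exactly and
the intercept is the (0,0,0) mean. Uncapped (winsorized) rates enter the
regression: winsorization already bounds the tail, and capping would
discretize it.

The stratified bootstrap resamples each of the eight nonoverlapping
feature groups with replacement at the smallest group's size (10,000
iterations by default), giving every group equal weight. With equal
per-group depth the OLS coefficients depend on the data only through the
eight resampled cell means, which is how the refits are computed — the
per-iteration cost is a pair of 8-row solves, and the draw means converge
to the equal-weight (balanced) fit rather than the raw-data fit. Reported
alongside the draws is the fraction of positive draws per coefficient, a
sign-stability summary complementing the normal-theory p-values of the
full-data fit.

`group_mean_changes()` gives the assumption-free counterpart: for each
feature and each setting of the other two, the difference of group mean
log decay rates, with empty pairs reported as missing rather than zero.

# The derepression ratio test

Given nascent and total abundances in control and knockdown conditions,
$\Delta = \log_2(\text{total}_{kd}/\text{total}_{ctrl}) -
\log_2(\text{nascent}_{kd}/\text{nascent}_{ctrl})$ per gene. A purely
transcriptional response leaves $\Delta$ near zero; a stability change
moves total RNA more than nascent RNA. $\Delta$ is invariant to
gene-independent scaling of any library and antisymmetric under swapping
the conditions; the target set is compared with the background by
Mann–Whitney. The pseudocount is the minimum positive abundance across
the four columns, reusing the global min-value rule applied before all
log transforms in the package.

# The synthetic-data generator

The generator is the package's test surface: it draws kinetic truth,
forms pools, labels them, and emits negative-binomial count tables, so
every estimator can be checked by parameter recovery. Defaults encode the
reference conditions the estimator targets:

| parameter | default | why |
|---|---|---|
| median half-life | 82 min | calibration of the decay distribution |
| sd log10 synthesis / decay | 0.79 / 0.44 | observed genome-wide spreads |
| pulse length | 20 min | labeling duration |
| contamination | 0.01 | 1:100 pull-down specificity |
| replicates | 3 | standard RNA-seq design choice |
| NB dispersion | 0.05 | typical bulk RNA-seq overdispersion |
| median synthesis | 0.2 TPM/min | puts mean totals near 200 TPM; rates are scale-free |
| processing law | log-normal, median 10 × median $k_d$, sd 0.25 | premature pools ~10% of mature, matching pull-down intron enrichment |
| intronless fraction | 0.15 | approximate share of intronless genes in a compact metazoan genome |
| library depth | 2 × 10⁷ | mid-size RNA-seq library |
| spike-ins | 10 transcripts, 2× amount ladder | a small thiolated ERCC-like set |

Rates are log-normal on the log10 scale with synthesis, processing and
decay drawn independently; feature flags (TF 10%, CTS 12%, me3 peaks on
8% of eligible genes) are planted independently of kinetics unless
`feature_effects` shifts log10 decay for carriers. Counts are NB with a
shared dispersion around depth-scaled expectations (dispersion 0 returns
real-valued expectations, deliberately unrounded); pull-down expectations
are labeled + contamination × unlabeled; spike-ins are appended at known
amounts in both fractions. Everything is a deterministic function of the
seed, and `write_fixture()` emits a byte-stable on-disk experiment
(counts, metadata, truth tables, GTF/TSV gene models, peak BED, gene
lists, a cell-type enrichment table, a YAML config echo).

What the generator does **not** emulate — and what recovery tests
therefore cannot certify on real data: read-level effects (mappability,
positional coverage bias, intron/exon ambiguity in short reads), isoform
structure, cell-type mixtures within a tissue, correlated
synthesis–decay programs, batch effects between fractions, or 4sU
toxicity. It validates estimator logic, not upstream quantification.

# Numerical choices

* The labeled-mature fraction cancels catastrophically near $k_p = k_d$ in
  its textbook form. It is evaluated as
  $1 - e^{-k_p t}\,(1 + k_p t\, \varphi(\delta t))$ with
  $\delta = k_d - k_p$ and $\varphi(x) = -\mathrm{expm1}(-x)/x$ whenever
  $|\delta|t < 10^{-4}$, which degrades smoothly to the repeated-root
  limit $1-(1+kt)e^{-kt}$ and agrees with adaptive ODE integration to
  better than $10^{-8}$ across the parameter space including
  $|k_p-k_d|/k_p < 10^{-6}$.
* Exact-mode inversion: fixed point with relative tolerance $10^{-10}$,
  100-iteration limit, linear initializer; saturation guard when the
  observed labeled signal reaches the total pool.
* Filter ceiling rule: ceiling(2/3 × n) so a 3-library group needs 2.
* Quantiles everywhere are R type 7 (linear interpolation).
* Ties in rank tests: average ranks; exact Mann–Whitney only for small
  tie-free groups.
* Empty design cells: the additive model drops non-estimable columns
  (e.g. a feature with no carriers); the interaction model refuses to fit
  and names the empty cell.

# Problem sizes and limitations

The test suite and the acceptance script run recovery at 5,000 genes ×
6 libraries with 2,000-iteration bootstraps — sizes chosen so the full
check cycle completes in seconds while leaving Monte-Carlo error well
inside the asserted tolerances; the package itself has no size-dependent
logic and the bootstrap's cell-mean formulation keeps 10,000 iterations
cheap at genome scale.

Known limitations: the linear synthesis mode compresses the decay-rate
spread slightly (its bias grows with $k_d t$) and the spike-in scale
estimate carries a few-percent multiplicative uncertainty with a ten-spike
set at realistic overdispersion — both visible as small shortfalls in
recovered medians and sigmas; the CV propagation assumes independent
errors although TPM normalization induces weak correlations; processing
rates are undefined for intronless genes; and single-timepoint estimation
cannot resolve half-lives shorter than a few minutes (labeled pools
saturate) or longer than the specificity bound.
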