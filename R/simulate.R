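#' Configuration for a synthetic 4sU pulse-labeling experiment
#'
#' Collects every parameter of the ground-truthed generator: the per-gene
#' first-order kinetic model (synthesis -> processing -> decay), the pulse
#' duration, the pull-down contamination level, spike-ins, and the count
#' noise model. The defaults reproduce the reference conditions the estimator
#' targets: a 20-minute 4sU pulse on tissue whose transcriptome has a median
#' RNA half-life of 82 min, log10 rate spreads of 0.79 (synthesis) and 0.44
#' (decay), a pull-down carrying over roughly 1 unlabeled molecule per 100,
#' and three replicate libraries per fraction.
#'
#' @param n_genes number of genes to simulate.
#' @param median_half_life median RNA half-life in minutes; sets the median
#'   of the decay-rate distribution to `log(2) / median_half_life`.
#' @param sigma_log10_synthesis standard deviation of log10 synthesis rates.
#' @param sigma_log10_decay standard deviation of log10 decay rates.
#' @param median_synthesis median synthesis rate in TPM/min. Only the overall
#'   abundance scale depends on this; all rate estimates are scale-free.
#' @param processing_rate_law list with entries `median_ratio` (median
#'   processing rate as a multiple of the median decay rate) and
#'   `sigma_log10`; processing rates are drawn log-normally and
#'   independently of decay.
#' @param intronless_frac fraction of genes without introns (no premature
#'   pool is observable for these; processing is treated as instantaneous).
#' @param t_label labeling pulse duration in minutes.
#' @param contamination_frac unlabeled:labeled carryover ratio in the
#'   pull-down fraction (1:100 purification specificity by default).
#' @param labeling_efficiency fraction of newly synthesised molecules that
#'   acquire label during the pulse (1 = complete incorporation).
#' @param n_replicates replicate libraries per fraction.
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); 0 gives noise-free expectations.
#' @param library_depth expected read count per library.
#' @param spike_in_spec data frame with columns `id` and `amount`: thiolated
#'   spike-in transcripts added at known equal amounts to both fractions.
#' @param feature_effects named numeric vector of log10 decay-rate shifts
#'   applied to genes carrying the planted `tf`, `me3` and `cts` features;
#'   all zero by default so kinetic rates are independent of features.
#' @param n_conditions number of biological conditions (each gets its own
#'   set of replicate libraries drawn from the same expectations).
#' @param seed integer seed; fully determines the generated experiment.
#'
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              median_half_life = 82,
                              sigma_log10_synthesis = 0.79,
                              sigma_log10_decay = 0.44,
                              median_synthesis = 0.2,
                              processing_rate_law = list(median_ratio = 10,
                                                         sigma_log10 = 0.25),
                              intronless_frac = 0.15,
                              t_label = 20,
                              contamination_frac = 0.01,
                              labeling_efficiency = 1,
                              n_replicates = 3,
                              nb_dispersion = 0.05,
                              library_depth = 2e7,
                              spike_in_spec = default_spike_ins(),
                              feature_effects = c(tf = 0, me3 = 0, cts = 0),
                              n_conditions = 1,
                              seed = 1L) {
  stopifnot(n_genes >= 2, n_replicates >= 1, n_conditions >= 1)
  if (median_half_life <= 0 || sigma_log10_synthesis < 0 ||
      sigma_log10_decay < 0 || median_synthesis <= 0)
    stop("kinetic distribution parameters must be positive (sigmas >= 0)")
  if (t_label <= 0) stop("t_label must be > 0")
  if (contamination_frac < 0 || contamination_frac >= 1)
    stop("contamination_frac must lie in [0, 1)")
  if (labeling_efficiency <= 0 || labeling_efficiency > 1)
    stop("labeling_efficiency must lie in (0, 1]")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (library_depth <= 0) stop("library_depth must be > 0")
  cfg <- list(n_genes = as.integer(n_genes),
              median_half_life = median_half_life,
              sigma_log10_synthesis = sigma_log10_synthesis,
              sigma_log10_decay = sigma_log10_decay,
              median_synthesis = median_synthesis,
              processing_rate_law = processing_rate_law,
              intronless_frac = intronless_frac,
              t_label = t_label,
              contamination_frac = contamination_frac,
              labeling_efficiency = labeling_efficiency,
              n_replicates = as.integer(n_replicates),
              nb_dispersion = nb_dispersion,
              library_depth = library_depth,
              spike_in_spec = spike_in_spec,
              feature_effects = feature_effects,
              n_conditions = as.integer(n_conditions),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default thiolated spike-in set
#'
#' Ten synthetic transcripts at known amounts spanning two orders of
#' magnitude, mixed into both the total and the pull-down fraction. Amounts
#' are in the same arbitrary abundance units as the gene pools.
#'
#' @return data frame with columns `id` and `amount`.
#' @export
default_spike_ins <- function() {
  data.frame(id = sprintf("spike_%02d", 1:10),
             amount = round(30 * 2^(0:9) / 3, 2),
             stringsAsFactors = FALSE)
}

#' Draw per-gene kinetic parameters
#'
#' Synthesis and decay rates are log-normal on the log10 scale: the decay
#' distribution is centred so the median half-life `log(2)/k_d` equals
#' `config$median_half_life`, with `sd(log10 k_d) = sigma_log10_decay`;
#' synthesis is centred on `median_synthesis` with its own sigma. Processing
#' rates are drawn independently per `processing_rate_law`; intronless genes
#' get `k_p = Inf` (no observable premature pool).
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `gene_id`, `alpha` (TPM/min), `k_p`
#'   (1/min, `Inf` for intronless genes), `k_d` (1/min), `half_life` (min),
#'   `intronless`.
#' @export
sample_kinetic_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("gene_%05d", seq_len(n))
  log10_alpha <- stats::rnorm(n, log10(config$median_synthesis),
                              config$sigma_log10_synthesis)
  kd_med <- log(2) / config$median_half_life
  log10_kd <- stats::rnorm(n, log10(kd_med), config$sigma_log10_decay)
  intronless <- stats::runif(n) < config$intronless_frac
  law <- config$processing_rate_law
  log10_kp <- stats::rnorm(n, log10(kd_med * law$median_ratio), law$sigma_log10)
  k_p <- 10^log10_kp
  k_p[intronless] <- Inf
  params <- data.frame(gene_id = gene_id,
                       alpha = 10^log10_alpha,
                       k_p = k_p,
                       k_d = 10^log10_kd,
                       stringsAsFactors = FALSE)
  params$half_life <- log(2) / params$k_d
  params$intronless <- intronless
  params
}

#' Steady-state premature and mature RNA pools
#'
#' Under constant first-order kinetics, the premature pool settles at
#' `alpha / k_p` and the mature pool at `alpha / k_d`. The ratio
#' premature/mature therefore equals `k_d / k_p` exactly.
#'
#' @param params data frame as from [sample_kinetic_params()].
#' @return data frame with columns `gene_id`, `premature`, `mature` (TPM).
#' @export
steady_state_pools <- function(params) {
  if (any(params$alpha <= 0) || any(params$k_p <= 0) || any(params$k_d <= 0))
    stop("all rates must be > 0")
  data.frame(gene_id = params$gene_id,
             premature = params$alpha / params$k_p,
             mature = params$alpha / params$k_d,
             stringsAsFactors = FALSE)
}

#' Labeled premature and mature pools after a pulse of length t
#'
#' Closed-form solution of the two-compartment system
#' `dP/dt = alpha - k_p P`, `dM/dt = k_p P - k_d M` with zero initial
#' labeled pools:
#' `P_L(t) = P* (1 - exp(-k_p t))` and
#' `M_L(t) = M* [1 - (k_d e^{-k_p t} - k_p e^{-k_d t}) / (k_d - k_p)]`,
#' evaluated in a cancellation-safe form so that the repeated-root limit
#' `M* [1 - (1 + k t) e^{-k t}]` at `k_p = k_d = k` is approached smoothly.
#' `k_p = Inf` gives instantaneous processing:
#' `P_L = 0`, `M_L = M* (1 - exp(-k_d t))`.
#'
#' @param params data frame as from [sample_kinetic_params()].
#' @param t pulse duration in minutes (scalar, >= 0).
#' @param efficiency labeling incorporation efficiency in (0, 1]; scales
#'   both labeled pools.
#' @return data frame with columns `gene_id`, `labeled_premature`,
#'   `labeled_mature` (TPM).
#' @export
labeled_pools <- function(params, t, efficiency = 1) {
  if (length(t) != 1 || t < 0) stop("t must be a single value >= 0")
  alpha <- params$alpha; k_p <- params$k_p; k_d <- params$k_d
  if (any(alpha <= 0) || any(k_p <= 0) || any(k_d <= 0))
    stop("all rates must be > 0")
  p_star <- alpha / k_p
  m_star <- alpha / k_d
  lp <- p_star * (1 - exp(-k_p * t))
  lm <- m_star * labeled_mature_frac(k_p, k_d, t)
  inst <- !is.finite(k_p)
  if (any(inst)) {
    lp[inst] <- 0
    lm[inst] <- m_star[inst] * (1 - exp(-k_d[inst] * t))
  }
  data.frame(gene_id = params$gene_id,
             labeled_premature = efficiency * lp,
             labeled_mature = efficiency * lm,
             stringsAsFactors = FALSE)
}

# Labeled fraction of the mature pool after a pulse of length t.
# Algebraically 1 - (k_d e^{-k_p t} - k_p e^{-k_d t})/(k_d - k_p), but that
# form cancels catastrophically as k_p -> k_d. Writing delta = k_d - k_p and
# phi(x) = (1 - e^{-x})/x, it equals 1 - e^{-k_p t} (1 + k_p t phi(delta t)),
# which is evaluated with expm1 when |delta| t is small and degrades
# gracefully to the textbook repeated-root limit 1 - (1 + k t) e^{-k t} at
# delta = 0.
labeled_mature_frac <- function(k_p, k_d, t) {
  delta <- k_d - k_p
  x <- delta * t
  small <- is.finite(k_p) & abs(x) < 1e-4
  out <- numeric(length(k_p))
  g <- is.finite(k_p) & !small
  if (any(g))
    out[g] <- 1 - (k_d[g] * exp(-k_p[g] * t) - k_p[g] * exp(-k_d[g] * t)) /
      delta[g]
  if (any(small)) {
    xs <- x[small]
    phi <- ifelse(xs == 0, 1, -expm1(-xs) / xs)
    out[small] <- 1 - exp(-k_p[small] * t) * (1 + k_p[small] * t * phi)
  }
  out[!is.finite(k_p)] <- 1 - exp(-k_d[!is.finite(k_p)] * t)
  pmin(pmax(out, 0), 1)
}

# Gene structures: lengths, intronless status, genomic placement and planted
# feature memberships. Deterministic given config$seed (offset stream).
simulate_genes <- function(config, params) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  exonic_length <- pmax(200, round(10^stats::rnorm(n, log10(1500), 0.25)))
  intronic_length <- ifelse(params$intronless, 0,
                            pmax(100, round(10^stats::rnorm(n, log10(2000), 0.4))))
  span <- exonic_length + intronic_length
  chroms <- c("2L", "2R", "3L", "3R", "X")
  chrom <- sample(chroms, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- integer(n)
  for (ch in chroms) {
    idx <- which(chrom == ch)
    if (!length(idx)) next
    # sequential placement with 5 kb gaps keeps neighbouring genes' peak
    # windows from overlapping
    start[idx] <- cumsum(c(1L, span[idx][-length(idx)] + 5000L))
  }
  end <- start + span - 1L
  tf <- stats::runif(n) < 0.10
  cts <- stats::runif(n) < 0.12
  # H3K27me3 peaks need room for a gene-body peak clear of both 1 kb windows
  eligible <- span >= 3000
  me3_category <- rep("none", n)
  cats <- c("A", "B", "C", "AB", "BC", "ABC", "AC")
  prob <- c(0.20, 0.25, 0.10, 0.15, 0.10, 0.18, 0.02)
  planted <- which(eligible & stats::runif(n) < 0.08 / mean(eligible))
  me3_category[planted] <- sample(cats, length(planted), replace = TRUE,
                                  prob = prob)
  data.frame(gene_id = params$gene_id, chrom = chrom, strand = strand,
             start = start, end = end,
             exonic_length = exonic_length, intronic_length = intronic_length,
             tf = tf, cts = cts, me3_category = me3_category,
             stringsAsFactors = FALSE)
}

# Peak intervals (0-based half-open) realising each gene's planted me3
# category: one small peak per region so that the combination of overlap
# flags recovers the category exactly.
simulate_peaks <- function(genes) {
  rows <- list()
  for (i in which(genes$me3_category != "none")) {
    g <- genes[i, ]
    tss <- if (g$strand == "+") g$start else g$end
    tes <- if (g$strand == "+") g$end else g$start
    up <- g$strand == "+"
    cat_chr <- strsplit(g$me3_category, "")[[1]]
    if ("A" %in% cat_chr) {   # upstream of the TSS, within 1 kb, off the body
      s <- if (up) tss - 700 else tss + 300
      rows[[length(rows) + 1L]] <- c(g$chrom, s, s + 400)
    }
    if ("B" %in% cat_chr) {   # mid-body, > 1 kb from both ends
      mid <- floor((g$start + g$end) / 2)
      rows[[length(rows) + 1L]] <- c(g$chrom, mid - 150, mid + 150)
    }
    if ("C" %in% cat_chr) {   # downstream of the TES, within 1 kb
      s <- if (up) tes + 300 else tes - 700
      rows[[length(rows) + 1L]] <- c(g$chrom, s, s + 400)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  m <- do.call(rbind, rows)
  # stored 1-based here; converted to BED 0-based half-open on write
  data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]), stringsAsFactors = FALSE)
}

# Cell-type enrichment table realising the planted CTS flags: CTS genes get
# one cell type passing (p < 0.05, fold change >= 2), all other entries fail
# at least one threshold.
simulate_cts_table <- function(config, genes) {
  set.seed(config$seed + 2L)
  cell_types <- c("neuroblast", "immature_neuron", "cholinergic_neuron",
                  "gabaergic_neuron", "glia", "hemocyte", "neuroepithelium",
                  "ring_gland")
  n <- nrow(genes)
  tab <- expand.grid(gene_id = genes$gene_id, cell_type = cell_types,
                     stringsAsFactors = FALSE)
  tab$fold_change <- round(pmin(1.9, 10^stats::rnorm(nrow(tab), 0, 0.12)), 3)
  tab$p_value <- round(stats::runif(nrow(tab), 0.06, 1), 4)
  hit_ct <- sample(cell_types, n, replace = TRUE)
  hit <- which(genes$cts)
  idx <- match(paste(genes$gene_id[hit], hit_ct[hit]),
               paste(tab$gene_id, tab$cell_type))
  tab$fold_change[idx] <- round(2 + stats::rexp(length(idx), 1), 3)
  tab$p_value[idx] <- signif(stats::runif(length(idx), 1e-6, 0.04), 3)
  tab[order(tab$gene_id, tab$cell_type), ]
}

#' Simulate total and pull-down RNA-seq count tables
#'
#' Expected pull-down signal per pool is
#' `labeled + contamination_frac * unlabeled`; the exonic signal of a gene
#' is its premature + mature pool and the intronic signal the premature pool
#' alone. Expected counts scale each region's signal x length to the library
#' depth; counts are drawn negative-binomially with the configured shared
#' dispersion (dispersion 0 returns the real-valued expectations unrounded).
#' Thiolated spike-ins are appended at their known amounts in both
#' fractions.
#'
#' @param pools data frame joining [steady_state_pools()] and
#'   [labeled_pools()] by `gene_id`.
#' @param config a [simulation_config()].
#' @param genes gene structure table (internal layout); generated from the
#'   config when omitted.
#' @return a `count_table` (see [load_tables()]) with
#'   `2 * n_replicates * n_conditions` libraries.
#' @export
simulate_libraries <- function(pools, config, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$library_depth <= 0) stop("library depth must be > 0")
  if (is.null(genes)) {
    # intronless genes are recognisable by an exactly-zero premature pool
    genes <- simulate_genes(config, data.frame(
      gene_id = pools$gene_id, intronless = pools$premature == 0))
  }
  stopifnot(identical(genes$gene_id, pools$gene_id))
  c_frac <- config$contamination_frac
  tot_ex <- pools$premature + pools$mature
  tot_in <- pools$premature
  lab_ex <- pools$labeled_premature + pools$labeled_mature
  lab_in <- pools$labeled_premature
  pd_ex <- lab_ex + c_frac * (tot_ex - lab_ex)
  pd_in <- lab_in + c_frac * (tot_in - lab_in)

  has_intron <- genes$intronic_length > 0
  spikes <- config$spike_in_spec
  rowdata <- data.frame(
    gene_id = c(pools$gene_id, pools$gene_id[has_intron], spikes$id),
    region = c(rep("exonic", nrow(pools)),
               rep("intronic", sum(has_intron)),
               rep("exonic", nrow(spikes))),
    length = c(genes$exonic_length, genes$intronic_length[has_intron],
               rep(1000L, nrow(spikes))),
    stringsAsFactors = FALSE)

  signal_total <- c(tot_ex, tot_in[has_intron], spikes$amount)
  signal_pd <- c(pd_ex, pd_in[has_intron], spikes$amount)

  libs <- expand.grid(replicate = seq_len(config$n_replicates),
                      fraction = c("total", "pulldown"),
                      condition = sprintf("cond%d", seq_len(config$n_conditions)),
                      stringsAsFactors = FALSE)
  libs$library_id <- sprintf("%s_%s_rep%d", libs$fraction, libs$condition,
                             libs$replicate)
  libs <- libs[, c("library_id", "fraction", "condition", "replicate")]

  set.seed(config$seed + 3L)
  counts <- matrix(0, nrow(rowdata), nrow(libs),
                   dimnames = list(NULL, libs$library_id))
  for (j in seq_len(nrow(libs))) {
    sig <- if (libs$fraction[j] == "total") signal_total else signal_pd
    w <- sig * rowdata$length
    mu <- config$library_depth * w / sum(w)
    counts[, j] <- if (config$nb_dispersion == 0) mu else
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  }
  structure(list(counts = counts, rowdata = rowdata, libraries = libs,
                 mode = "counts"),
            class = "count_table")
}

#' Write a complete runnable fixture to disk
#'
#' Generates a full synthetic experiment from a config and writes every
#' input the pipeline consumes: the count table and library metadata, the
#' kinetic truth table, gene models (GTF and minimal TSV), an H3K27me3 peak
#' BED, a transcription-factor gene list, a cell-type enrichment table, the
#' spike-in sheet, a planted-feature truth table, and a YAML echo of the
#' config. Output is byte-identical across runs with the same config.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if absent).
#' @return invisibly, a named list of the written file paths.
#' @export
write_fixture <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config)
  p <- function(f) file.path(outdir, f)
  tsv <- function(d, f) utils::write.table(
    d, p(f), sep = "\t", quote = FALSE, row.names = FALSE)

  cnt <- data.frame(sim$counts$rowdata, sim$counts$counts,
                    check.names = FALSE)
  tsv(cnt, "counts.tsv")
  tsv(sim$counts$libraries, "libraries.tsv")
  truth <- sim$params
  truth$k_p[!is.finite(truth$k_p)] <- NA
  tsv(truth, "truth_rates.tsv")
  tsv(sim$genes[, c("gene_id", "chrom", "strand", "start", "end")],
      "genes.tsv")
  gtf <- sprintf(
    '%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    sim$genes$chrom, sim$genes$start, sim$genes$end, sim$genes$strand,
    sim$genes$gene_id)
  writeLines(gtf, p("genes.gtf"))
  bed <- sprintf("%s\t%d\t%d", sim$peaks$chrom, sim$peaks$start - 1L,
                 sim$peaks$end)
  writeLines(bed, p("peaks.bed"))
  writeLines(sim$genes$gene_id[sim$genes$tf], p("tf_genes.txt"))
  tsv(sim$cts_table, "cts_enrichment.tsv")
  tsv(config$spike_in_spec, "spike_ins.tsv")
  tsv(sim$genes[, c("gene_id", "tf", "cts", "me3_category")],
      "truth_features.tsv")
  cfg <- config
  cfg$spike_in_spec <- NULL
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(list(counts = p("counts.tsv"), libraries = p("libraries.tsv"),
                 truth = p("truth_rates.tsv"), genes_tsv = p("genes.tsv"),
                 gtf = p("genes.gtf"), peaks = p("peaks.bed"),
                 tf = p("tf_genes.txt"), cts = p("cts_enrichment.tsv"),
                 spikes = p("spike_ins.tsv"),
                 features = p("truth_features.tsv"),
                 config = p("config.yaml")))
}

#' Run the full generator in memory
#'
#' Convenience wrapper chaining [sample_kinetic_params()],
#' [steady_state_pools()], [labeled_pools()] and [simulate_libraries()],
#' together with the gene structures, peaks and cell-type table.
#'
#' @param config a [simulation_config()].
#' @return list with elements `params`, `pools`, `genes`, `peaks`,
#'   `cts_table`, `counts`.
#' @export
simulate_experiment <- function(config) {
  params <- sample_kinetic_params(config)
  if (any(config$feature_effects != 0)) {
    genes0 <- simulate_genes(config, params)
    eff <- config$feature_effects
    shift <- eff["tf"] * genes0$tf + eff["cts"] * genes0$cts +
      eff["me3"] * (genes0$me3_category == "ABC")
    params$k_d <- params$k_d * 10^shift
    params$half_life <- log(2) / params$k_d
  }
  genes <- simulate_genes(config, params)
  pools <- steady_state_pools(params)
  lab <- labeled_pools(params, config$t_label, config$labeling_efficiency)
  pools <- cbind(pools, lab[, c("labeled_premature", "labeled_mature")])
  counts <- simulate_libraries(pools, config, genes)
  list(params = params, pools = pools, genes = genes,
       peaks = simulate_peaks(genes),
       cts_table = simulate_cts_table(config, genes),
       counts = counts)
}
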