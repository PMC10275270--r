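#' Run configuration for the full pipeline
#'
#' Bundles all input paths and analysis parameters. The defaults reproduce
#' the study settings: a 20-min pulse, 1:100 pull-down specificity (1000-min
#' reporting cap), the 10-count/2-of-3 expression filter, CTS thresholds
#' p < 0.05 and fold change >= 2, 1-kb H3K27me3 windows, 1% winsorization,
#' and a 10,000-iteration stratified bootstrap at the minimum group size.
#'
#' @param counts,libraries paths to the quantification and library TSVs.
#' @param gene_models path to a GTF or minimal gene-model TSV (optional;
#'   needed for H3K27me3 classification).
#' @param peaks path to an H3K27me3 peak BED (optional).
#' @param tf_list path to a transcription-factor id list (optional).
#' @param cts_table path to a cell-type enrichment TSV (optional).
#' @param spike_ins path to the spike-in sheet (`id`, `amount`).
#' @param derepression path to a nascent/total knockdown TSV (optional).
#' @param derepression_targets path to the target id list for the
#'   derepression test.
#' @param t_label pulse duration, minutes.
#' @param specificity_ratio pull-down carryover ratio (sets the resolvable
#'   half-life; reported alongside the cap).
#' @param cap half-life reporting cap, minutes.
#' @param min_count,min_frac expression-filter thresholds.
#' @param cts_p_max,cts_min_fc CTS classification thresholds.
#' @param me3_window TSS/TES window half-width, nucleotides.
#' @param winsorize_tail winsorized fraction at each end.
#' @param n_boot bootstrap iterations.
#' @param per_group_n bootstrap per-group depth (`"min"` or an integer).
#' @param synthesis_mode `"linear"` or `"exact"`.
#' @param seed integer seed for the bootstrap.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts, libraries, gene_models = NULL, peaks = NULL,
                       tf_list = NULL, cts_table = NULL, spike_ins = NULL,
                       derepression = NULL, derepression_targets = NULL,
                       t_label = 20, specificity_ratio = 0.01, cap = 1000,
                       min_count = 10, min_frac = 2 / 3,
                       cts_p_max = 0.05, cts_min_fc = 2,
                       me3_window = 1000, winsorize_tail = 0.01,
                       n_boot = 10000, per_group_n = "min",
                       synthesis_mode = "linear", seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes quantification loading, rate estimation, feature annotation and
#' the stability/regression statistics (plus the derepression test when its
#' inputs are given), writing every stage's table and a JSON summary into a
#' run directory. With a fixed config and seed the outputs are reproducible
#' bit for bit.
#'
#' @param config a [run_config()] or the path to a YAML file of its fields.
#' @param outdir output directory (created).
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  # validate declared inputs before any computation starts
  paths <- Filter(Negate(is.null),
                  config[c("counts", "libraries", "gene_models", "peaks",
                           "tf_list", "cts_table", "spike_ins",
                           "derepression", "derepression_targets")])
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", names(missing), unlist(missing)),
               collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  ct <- load_tables(config$counts, config$libraries)
  spikes <- if (!is.null(config$spike_ins))
    utils::read.delim(config$spike_ins, stringsAsFactors = FALSE) else NULL
  pol <- if (is.null(spikes)) scale_policy("fixed_factor", 1) else
    scale_policy("spike_in")
  fit <- fit_kinetics(ct, t_label = config$t_label, scale = pol,
                      spike_ins = spikes,
                      synthesis = config$synthesis_mode,
                      cap = config$cap, min_count = config$min_count,
                      min_frac = config$min_frac)
  tsv(fit$rates, "rates.tsv")
  universe <- fit$rates$gene_id

  summary <- list(
    n_genes = nrow(fit$rates),
    scale = fit$scale,
    median_half_life = stats::median(fit$rates$half_life, na.rm = TRUE),
    sd_log10_synthesis = stats::sd(log10(fit$rates$synthesis[fit$rates$synthesis > 0])),
    sd_log10_decay = stats::sd(log10(fit$rates$decay), na.rm = TRUE),
    pct_capped = 100 * mean(fit$rates$capped),
    max_resolvable_half_life = cap_from_specificity(config$specificity_ratio,
                                                    config$t_label),
    unspliced_pct = stats::setNames(
      as.list(library_unspliced_fraction(fit$profile)$pct_unspliced),
      library_unspliced_fraction(fit$profile)$library_id))

  prof <- stability_percentile(fit$rates$decay, universe)
  tsv(prof, "stability_percentiles.tsv")

  tf_ids <- if (!is.null(config$tf_list)) {
    ids <- unique(readLines(config$tf_list)); ids[nzchar(ids)]
  } else character()
  cts <- if (!is.null(config$cts_table)) {
    classify_cts(utils::read.delim(config$cts_table, stringsAsFactors = FALSE),
                 config$cts_p_max, config$cts_min_fc)
  } else list(flags = data.frame(gene_id = character(), cts = logical()),
              sets = list())
  me3 <- if (!is.null(config$peaks)) {
    if (is.null(config$gene_models))
      stop("H3K27me3 classification needs gene_models alongside peaks")
    classify_h3k27me3(read_gene_models(config$gene_models),
                      read_peaks(config$peaks), config$me3_window)
  } else data.frame(gene_id = character(), me3_category = character(),
                    extended_me3 = logical())

  ann <- build_annotation(universe, tf_ids, cts$flags, me3)
  tsv(ann, "annotation.tsv")

  tests <- list()
  for (nm in c("tf", "cts", "me3")) {
    ids <- ann$gene_id[ann[[nm]]]
    if (length(ids) && length(ids) < length(universe)) {
      gt <- group_stability_test(prof, ids)
      tests[[nm]] <- data.frame(group = nm, n = gt$n,
                                median_percentile = gt$median_percentile,
                                U = gt$U, p = gt$p, stars = gt$stars)
    }
  }
  if (length(tests)) tsv(do.call(rbind, tests), "group_tests.tsv")
  summary$group_tests <- lapply(tests, function(d)
    list(n = d$n, median_percentile = d$median_percentile, p = d$p))

  if (any(ann$tf) && any(ann$me3) && any(ann$cts)) {
    y <- winsorize_log(fit$rates$decay, config$winsorize_tail)
    groups <- nonoverlapping_groups(ann)
    tsv(data.frame(group = names(groups$sizes),
                   n = as.integer(groups$sizes)), "group_sizes.tsv")
    reg_rows <- list()
    for (interactions in c(FALSE, TRUE)) {
      ok <- !interactions || all(groups$sizes > 0)
      if (!ok) next
      m <- fit_decay_model(y, ann$tf, ann$me3, ann$cts, interactions)
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        model = if (interactions) "interaction" else "additive",
        coefficient = names(m$coefficients),
        estimate = unname(m$coefficients), se = unname(m$se),
        p = unname(m$p_values), stringsAsFactors = FALSE)
    }
    reg <- do.call(rbind, reg_rows)
    if (all(groups$sizes > 0)) {
      bt <- bootstrap_model(y, ann$tf, ann$me3, ann$cts,
                            n_iter = config$n_boot,
                            per_group_n = config$per_group_n,
                            seed = config$seed)
      qs <- apply(bt$draws_interaction, 2, stats::quantile,
                  c(0.025, 0.5, 0.975))
      idx <- match(reg$coefficient[reg$model == "interaction"],
                   colnames(bt$draws_interaction))
      reg[reg$model == "interaction", c("boot_q025", "boot_q50", "boot_q975")] <-
        t(qs)[idx, ]
      summary$bootstrap_positive_frac <-
        as.list(bt$positive_frac$interaction)
    }
    tsv(reg, "regression.tsv")
    tsv(group_mean_changes(y, ann$tf, ann$me3, ann$cts), "mean_changes.tsv")
    summary$regression <- stats::setNames(
      as.list(reg$estimate[reg$model == "interaction"]),
      reg$coefficient[reg$model == "interaction"])
  }

  if (!is.null(config$derepression)) {
    if (is.null(config$derepression_targets))
      stop("derepression test needs derepression_targets")
    din <- utils::read.delim(config$derepression, stringsAsFactors = FALSE)
    targets <- readLines(config$derepression_targets)
    rs <- ratio_shift(din, targets[nzchar(targets)])
    tsv(rs$delta, "derepression.tsv")
    summary$derepression <- list(median_target = rs$median_target,
                                 median_background = rs$median_background,
                                 p = rs$p)
  }

  cfg_echo <- unclass(config)
  yaml::write_yaml(cfg_echo[!vapply(cfg_echo, is.null, TRUE)],
                   file.path(outdir, "config.yaml"))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
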