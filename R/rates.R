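#' Scaling policy between pull-down and total libraries
#'
#' TPM is a within-library relative measure, so labeled abundances from the
#' pull-down fraction must be rescaled onto the total-RNA TPM scale before
#' synthesis rates can be computed. Three policies are supported:
#' `spike_in` (default; uses thiolated spike-ins present at known equal
#' amounts in both fractions), `fixed_factor` (a user-supplied factor), and
#' `median_half_life_anchor` (chooses the factor so the post-hoc median
#' half-life equals an anchor value).
#'
#' @param mode one of `"spike_in"`, `"fixed_factor"`,
#'   `"median_half_life_anchor"`.
#' @param value the fixed factor, or the anchor half-life in minutes.
#' @return list of class `scale_policy`.
#' @export
scale_policy <- function(mode = c("spike_in", "fixed_factor",
                                  "median_half_life_anchor"),
                         value = NULL) {
  mode <- match.arg(mode)
  if (mode != "spike_in" && (is.null(value) || value <= 0))
    stop("policy '", mode, "' needs a positive value")
  structure(list(mode = mode, value = value), class = "scale_policy")
}

#' Estimate the pull-down to total scale factor
#'
#' In `spike_in` mode the factor is the geometric mean, over spike-ins, of
#' the total-library signal per unit mass divided by the pull-down signal
#' per unit mass, with each spike-in's signal expressed relative to the
#' gene (non-spike) content of its library. Multiplying pull-down TPM by the
#' returned `s` puts it on the total-RNA TPM scale.
#'
#' @param ct a count-mode `count_table` still containing the spike-in rows.
#' @param spike_ins data frame with columns `id` and `amount`.
#' @param policy a [scale_policy()].
#' @param condition restrict to one condition (default: all libraries).
#' @return scalar scale factor `s > 0`.
#' @export
estimate_scale <- function(ct, spike_ins = NULL,
                           policy = scale_policy("spike_in"),
                           condition = NULL) {
  if (policy$mode == "fixed_factor") return(policy$value)
  if (policy$mode == "median_half_life_anchor")
    stop("anchor mode is resolved inside fit_kinetics(), not standalone")
  stop_if_not_counts(ct)
  if (is.null(spike_ins) || !nrow(spike_ins))
    stop("spike_in policy requires a spike-in table")
  hit <- ct$rowdata$gene_id %in% spike_ins$id
  if (!any(hit)) stop("no spike-in rows found in the count table")
  libs <- ct$libraries
  sel <- rep(TRUE, nrow(libs))
  if (!is.null(condition)) sel <- libs$condition == condition
  rate <- ct$counts / ct$rowdata$length
  gene_content <- colSums(rate[!hit, , drop = FALSE])
  rel <- sweep(rate[hit, , drop = FALSE], 2, gene_content, "/")
  per_mass <- rel / spike_ins$amount[match(ct$rowdata$gene_id[hit],
                                           spike_ins$id)]
  tot_cols <- libs$library_id[sel & libs$fraction == "total"]
  pd_cols <- libs$library_id[sel & libs$fraction == "pulldown"]
  if (!length(tot_cols) || !length(pd_cols))
    stop("need both total and pulldown libraries to estimate the scale")
  # ratios are multiplicative: pool spike-ins on the log scale
  ratios <- rowMeans(per_mass[, tot_cols, drop = FALSE]) /
    rowMeans(per_mass[, pd_cols, drop = FALSE])
  s <- exp(mean(log(ratios[is.finite(ratios) & ratios > 0])))
  if (!is.finite(s) || s <= 0) stop("scale estimation failed")
  s
}

#' Estimate per-gene synthesis rates
#'
#' Linear mode uses the short-pulse approximation
#' `alpha = s * (labeled premature + labeled mature) / t`: total labeled
#' signal accrues at rate `alpha` early in the pulse. Exact mode inverts
#' the closed-form labeled-pool solution, with processing and decay rates
#' tied to the observed premature/mature pools (`k_p = alpha/P`,
#' `k_d = alpha/M`), by a fixed-point iteration initialised at the linear
#' estimate; it removes the downward bias the linear mode incurs for
#' fast-decaying genes.
#'
#' @param labeled_total per-gene labeled signal: pull-down exonic TPM
#'   (premature + mature), condition means.
#' @param t_label pulse duration (min).
#' @param s scale factor from [estimate_scale()].
#' @param mode `"linear"` or `"exact"`.
#' @param total,premature total-library exonic and intronic TPM means
#'   (required for exact mode).
#' @param max_iter,tol fixed-point controls for exact mode.
#' @return list with `synthesis` (TPM/min) and logical `converged` (always
#'   `TRUE` in linear mode; non-converged genes keep the linear estimate).
#' @export
estimate_synthesis <- function(labeled_total, t_label, s,
                               mode = c("linear", "exact"),
                               total = NULL, premature = NULL,
                               max_iter = 100, tol = 1e-10) {
  mode <- match.arg(mode)
  if (t_label <= 0) stop("t_label must be > 0")
  if (s <= 0) stop("scale factor must be > 0")
  obs <- s * labeled_total
  alpha <- obs / t_label
  converged <- rep(TRUE, length(alpha))
  if (mode == "exact") {
    if (is.null(total) || is.null(premature))
      stop("exact mode needs total and premature abundances")
    mat <- pmax(total - premature, 0)
    predict_labeled <- function(a, P, M) {
      lp <- if (P > 0) P * (1 - exp(-(a / P) * t_label)) else 0
      if (M <= 0) return(lp)
      kd <- a / M
      kp <- if (P > 0) a / P else Inf
      lp + M * labeled_mature_frac(kp, kd, t_label)
    }
    for (i in seq_along(alpha)) {
      P <- premature[i]; M <- mat[i]
      if (!is.finite(obs[i]) || obs[i] <= 0 || P + M <= 0) next
      if (obs[i] >= P + M * (1 - 1e-12)) { converged[i] <- FALSE; next }
      a <- alpha[i]
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        pred <- predict_labeled(a, P, M)
        if (pred <= 0) break
        a_new <- a * obs[i] / pred
        if (abs(a_new - a) <= tol * a) { ok <- TRUE; a <- a_new; break }
        a <- a_new
      }
      if (ok) alpha[i] <- a else converged[i] <- FALSE
    }
  }
  list(synthesis = pmax(alpha, 0), converged = converged)
}

#' Steady-state decay rates from synthesis and total RNA
#'
#' The steady-state balance gives
#' `decay = synthesis / (total RNA - pre-mRNA)`, i.e. synthesis divided by
#' the mature pool; half-life is `log(2) / decay`. Genes with
#' `total <= premature` are flagged and get no rate.
#'
#' @param synthesis per-gene synthesis rates (TPM/min).
#' @param total,premature total-library exonic and intronic TPM means.
#' @return list with `decay` (1/min, `NA` where degenerate), `half_life`
#'   (min) and logical `degenerate`.
#' @export
estimate_decay <- function(synthesis, total, premature) {
  mature <- total - premature
  degenerate <- !(mature > 0)
  decay <- ifelse(degenerate, NA_real_, synthesis / mature)
  decay[!degenerate & decay <= 0] <- NA_real_
  list(decay = decay, half_life = log(2) / decay, degenerate = degenerate)
}

#' Steady-state processing rates
#'
#' `k_p = synthesis / premature`; genes without intronic signal (intronless)
#' get a missing value rather than an error.
#'
#' @param synthesis per-gene synthesis rates (TPM/min).
#' @param premature total-library intronic TPM means.
#' @return numeric vector of processing rates (1/min), `NA` where
#'   premature is 0.
#' @export
estimate_processing <- function(synthesis, premature) {
  ifelse(premature > 0, synthesis / premature, NA_real_)
}

#' Longest resolvable half-life from pull-down specificity
#'
#' If the purification carries over unlabeled RNA at a ratio `ratio`
#' relative to the labeled signal (e.g. 0.01 for a 1:100 specificity), a
#' gene whose true labeled signal after a pulse of `t_label` minutes falls
#' below that carryover cannot be distinguished from contamination. Under
#' the short-pulse approximation the labeled fraction of the mature pool is
#' `k_d * t`, so the longest resolvable half-life is
#' `log(2) * t_label / ratio` minutes: 1386.29 min for ratio 0.01 at
#' t = 20, conventionally rounded down to a 1000-min reporting cap.
#'
#' @param ratio carryover ratio of unlabeled to labeled signal, in (0, 1].
#' @param t_label pulse duration (min).
#' @return maximum resolvable half-life in minutes.
#' @export
cap_from_specificity <- function(ratio, t_label = 20) {
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  log(2) * t_label / ratio
}

#' Cap reported half-lives
#'
#' Half-lives above the cap are reported at the cap with `capped = TRUE`;
#' the underlying decay rate is left untouched (downstream regression
#' handles the tail by winsorization instead).
#'
#' @param rates a rates data frame with `half_life` column.
#' @param cap reporting cap in minutes.
#' @return the data frame with `half_life` capped and a `capped` flag.
#' @export
apply_cap <- function(rates, cap = 1000) {
  rates$capped <- !is.na(rates$half_life) & rates$half_life > cap
  rates$half_life[rates$capped] <- cap
  rates
}

#' Delta-method coefficient of variation for decay rates
#'
#' Assuming independent errors in synthesis and in the (total - premature)
#' denominator,
#' `cv_decay = sqrt(cv_synthesis^2 +
#'                  (var_total + var_premature) / (total - premature)^2)`.
#'
#' @param cv_synthesis CV of the synthesis estimate.
#' @param var_total,var_premature replicate variances of the total and
#'   premature abundances.
#' @param total,premature the point estimates.
#' @return numeric vector of decay-rate CVs (`NA` where the denominator is
#'   degenerate).
#' @export
propagate_cv <- function(cv_synthesis, var_total, var_premature,
                         total, premature) {
  if (any(var_total < 0, na.rm = TRUE) || any(var_premature < 0, na.rm = TRUE))
    stop("variances must be >= 0")
  mature <- total - premature
  out <- sqrt(cv_synthesis^2 + (var_total + var_premature) / mature^2)
  out[!(mature > 0)] <- NA_real_
  out
}

#' Degradation/processing rate ratio proxy
#'
#' At steady state the premature/mature abundance ratio in total RNA equals
#' `k_d / k_p`, giving a labeling-free readout of relative RNA dynamics.
#'
#' @param profile an `expression_profile` (total-fraction means are used).
#' @param condition optional condition restriction.
#' @return data frame with `gene_id` and `ratio` (`NA` where mature is 0).
#' @export
deg_proc_ratio <- function(profile, condition = NULL) {
  st <- profile_stats(profile, "total", condition)
  m <- st$mature$mean
  data.frame(gene_id = profile$gene_id,
             ratio = ifelse(m > 0, st$premature$mean / m, NA_real_),
             stringsAsFactors = FALSE)
}

#' Steady-state check: correlation of RNA levels between two profiles
#'
#' Squared Pearson correlation of log10 total abundances (condition means)
#' between two expression profiles, after adding a pseudocount equal to the
#' minimum positive value across both inputs. An r-squared near 1 supports
#' the steady-state assumption over the compared interval.
#'
#' @param profile_a,profile_b `expression_profile` objects sharing genes.
#' @return list with `r_squared`, `n` genes compared and the `pseudocount`.
#' @export
steady_state_check <- function(profile_a, profile_b) {
  shared <- intersect(profile_a$gene_id, profile_b$gene_id)
  if (length(shared) < 3) stop("need at least 3 shared genes")
  xa <- profile_stats(profile_a, "total")$total$mean[match(shared, profile_a$gene_id)]
  xb <- profile_stats(profile_b, "total")$total$mean[match(shared, profile_b$gene_id)]
  pos <- c(xa[xa > 0], xb[xb > 0])
  if (!length(pos)) stop("no positive values")
  pc <- min(pos)
  r <- stats::cor(log10(xa + pc), log10(xb + pc))
  list(r_squared = r^2, n = length(shared), pseudocount = pc)
}

#' Fit the steady-state kinetic model to a labeling experiment
#'
#' The central estimator: from a count-mode table holding paired total and
#' pull-down libraries, it (1) applies the expression filter, (2) recomputes
#' TPM after removing spike-ins and other excluded ids, (3) splits
#' intron/exon signal into premature/mature/total abundances, (4) scales the
#' pull-down onto the total-RNA TPM scale, and (5) estimates per-gene
#' synthesis (TPM/min), processing and decay rates (1/min), half-lives with
#' a specificity-derived reporting cap, and delta-method CVs.
#'
#' @param ct a count-mode `count_table` (e.g. from [load_tables()] or
#'   [simulate_libraries()]).
#' @param t_label pulse duration in minutes.
#' @param scale a [scale_policy()].
#' @param spike_ins spike-in table (`id`, `amount`) for spike-in scaling.
#' @param synthesis `"linear"` (default) or `"exact"` estimation mode.
#' @param cap reporting cap for half-lives, minutes.
#' @param min_count,min_frac expression-filter thresholds.
#' @param exclude_ids extra gene ids (e.g. rRNA) removed before TPM
#'   recomputation; spike-in ids are always removed.
#' @param condition condition to fit (default: the single condition
#'   present; an error if ambiguous).
#' @return object of class `kinetic_fit` with elements `rates` (data frame:
#'   `gene_id`, `synthesis`, `processing`, `decay`, `half_life`, `capped`,
#'   `cv_synthesis`, `cv_total`, `cv_decay`), `scale`, `profile_total`,
#'   `profile_pulldown`, `t_label`, `cap`, `n_filtered`, `call`.
#' @export
fit_kinetics <- function(ct, t_label = 20,
                         scale = scale_policy("spike_in"),
                         spike_ins = NULL,
                         synthesis = c("linear", "exact"),
                         cap = 1000, min_count = 10, min_frac = 2 / 3,
                         exclude_ids = character(),
                         condition = NULL) {
  synthesis <- match.arg(synthesis)
  stop_if_not_counts(ct)
  conds <- unique(ct$libraries$condition)
  if (is.null(condition)) {
    if (length(conds) > 1)
      stop("multiple conditions present; pick one via `condition`")
    condition <- conds
  }
  spike_ids <- if (!is.null(spike_ins)) spike_ins$id else character()
  keep_genes <- setdiff(filter_expressed(ct, min_count, min_frac),
                        c(spike_ids, exclude_ids))

  if (scale$mode == "spike_in") {
    s <- estimate_scale(ct, spike_ins, scale, condition)
  } else if (scale$mode == "fixed_factor") {
    s <- scale$value
  } else {
    s <- 1  # anchor mode: provisional, rescaled below
  }

  tpm <- recompute_tpm(ct, c(spike_ids, exclude_ids))
  tpm <- subset_genes(tpm, keep_genes)
  profile <- split_premature_mature(tpm)
  st_tot <- profile_stats(profile, "total", condition)
  st_pd <- profile_stats(profile, "pulldown", condition)

  total <- st_tot$total$mean
  premature <- st_tot$premature$mean
  labeled_total <- st_pd$total$mean

  if (scale$mode == "median_half_life_anchor") {
    # closed form in linear mode: half-life ~ log(2) t M / (s L)
    hl1 <- log(2) * t_label * pmax(total - premature, 0) / labeled_total
    hl1 <- hl1[is.finite(hl1) & hl1 > 0]
    s <- stats::median(hl1) / scale$value
  }

  syn <- estimate_synthesis(labeled_total, t_label, s, synthesis,
                            total = total, premature = premature)
  dec <- estimate_decay(syn$synthesis, total, premature)
  proc <- estimate_processing(syn$synthesis, premature)

  cv_synthesis <- sqrt(st_pd$total$var) / labeled_total
  cv_total <- sqrt(st_tot$total$var) / total
  cv_decay <- propagate_cv(cv_synthesis, st_tot$total$var,
                           st_tot$premature$var, total, premature)

  rates <- data.frame(gene_id = profile$gene_id,
                      synthesis = syn$synthesis,
                      processing = proc,
                      decay = dec$decay,
                      half_life = dec$half_life,
                      cv_synthesis = cv_synthesis,
                      cv_total = cv_total,
                      cv_decay = cv_decay,
                      converged = syn$converged,
                      stringsAsFactors = FALSE)
  # degeneracy is judged on the condition means the rates are computed
  # from: single-library excursions of intronic above exonic signal are
  # replicate noise, not evidence that the gene has no mature pool
  drop <- dec$degenerate
  rates <- rates[!drop, ]
  rates <- apply_cap(rates, cap)
  rates <- rates[, c("gene_id", "synthesis", "processing", "decay",
                     "half_life", "capped", "cv_synthesis", "cv_total",
                     "cv_decay", "converged")]
  structure(list(rates = rates, scale = s, scale_policy = scale,
                 profile = profile, t_label = t_label, cap = cap,
                 condition = condition,
                 n_filtered = length(keep_genes),
                 n_degenerate = sum(drop),
                 synthesis_mode = synthesis,
                 call = match.call()),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Steady-state 4sU labeling kinetic fit\n")
  cat(sprintf("  genes: %d (of %d expressed; %d degenerate dropped)\n",
              nrow(x$rates), x$n_filtered, x$n_degenerate))
  cat(sprintf("  pulse: %g min; pull-down scale s = %.4g (%s); %s synthesis\n",
              x$t_label, x$scale, x$scale_policy$mode, x$synthesis_mode))
  cat(sprintf("  median half-life: %.1f min (%.1f%% at the %g-min cap)\n",
              stats::median(x$rates$half_life, na.rm = TRUE),
              100 * mean(x$rates$capped), x$cap))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  r <- object$rates
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
  out <- list(n = nrow(r),
              half_life = qs(r$half_life),
              synthesis = qs(r$synthesis),
              decay = qs(r$decay),
              sd_log10_synthesis = stats::sd(log10(r$synthesis[r$synthesis > 0])),
              sd_log10_decay = stats::sd(log10(r$decay), na.rm = TRUE),
              pct_capped = 100 * mean(r$capped),
              scale = object$scale, t_label = object$t_label)
  class(out) <- "summary.kinetic_fit"
  out
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic fit over %d genes (pulse %g min, scale %.4g)\n",
              x$n, x$t_label, x$scale))
  m <- rbind(half_life = x$half_life, synthesis = x$synthesis,
             decay = x$decay)
  colnames(m) <- c("Q1", "median", "Q3")
  print(signif(m, 4))
  cat(sprintf("sd(log10 synthesis) = %.3f, sd(log10 decay) = %.3f\n",
              x$sd_log10_synthesis, x$sd_log10_decay))
  cat(sprintf("%.1f%% of genes at the half-life cap\n", x$pct_capped))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  m <- as.matrix(object$rates[, c("synthesis", "processing", "decay")])
  rownames(m) <- object$rates$gene_id
  m
}

#' @export
plot.kinetic_fit <- function(x, breaks = 50, ...) {
  hl <- x$rates$half_life
  graphics::hist(hl[!x$rates$capped], breaks = breaks, col = "grey70",
                 border = NA, xlab = "half-life (min)",
                 main = sprintf("RNA half-lives (%.1f%% at ≥%g min cap)",
                                100 * mean(x$rates$capped), x$cap), ...)
  graphics::abline(v = x$cap, lty = 2)
  invisible(x)
}

#' Predicted labeled pools from a fitted model
#'
#' Pushes the estimated rates back through the closed-form labeled-pool
#' solution, giving expected labeled premature/mature abundances (total-RNA
#' TPM scale) for a pulse of length `t`.
#'
#' @param object a `kinetic_fit`.
#' @param t pulse duration (min); defaults to the fitted pulse.
#' @param ... unused.
#' @return data frame `gene_id`, `labeled_premature`, `labeled_mature`.
#' @export
predict.kinetic_fit <- function(object, t = object$t_label, ...) {
  r <- object$rates
  ok <- !is.na(r$decay)
  params <- data.frame(gene_id = r$gene_id[ok],
                       alpha = r$synthesis[ok],
                       k_p = ifelse(is.na(r$processing[ok]), Inf,
                                    r$processing[ok]),
                       k_d = r$decay[ok], stringsAsFactors = FALSE)
  labeled_pools(params, t)
}
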