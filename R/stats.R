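#' Stability percentiles from decay rates
#'
#' Rank transform of stability: the most stable gene (lowest decay rate)
#' gets percentile 100, the least stable the lowest percentile. Ties get
#' average ranks; percentile = 100 * rank(-decay) / n.
#'
#' @param decay per-gene decay rates (1/min).
#' @param gene_id optional ids.
#' @return data frame `gene_id`, `decay`, `stability_percentile`.
#' @export
stability_percentile <- function(decay, gene_id = NULL) {
  if (length(decay) < 2) stop("need at least 2 genes")
  if (is.null(gene_id)) gene_id <- as.character(seq_along(decay))
  data.frame(gene_id = gene_id, decay = decay,
             stability_percentile = 100 * rank(-decay, ties.method = "average") /
               length(decay),
             stringsAsFactors = FALSE)
}

star_string <- function(p) {
  # display thresholds: * p < 0.05, ** p < 1e-9, *** p < 1e-39
  if (is.na(p)) "" else if (p < 1e-39) "***" else if (p < 1e-9) "**" else
    if (p < 0.05) "*" else ""
}

#' Rank-based stability test of a gene group against the rest
#'
#' Two-sided Mann-Whitney U test of the group's decay rates against all
#' other genes, with the group's median stability percentile attached. The
#' exact distribution is used for small groups (< 20) without ties; the
#' normal approximation with tie correction otherwise.
#'
#' @param profile data frame from [stability_percentile()].
#' @param group_ids ids of the group.
#' @return list with `n`, `median_percentile`, `U`, `p`, `stars`.
#' @export
group_stability_test <- function(profile, group_ids) {
  ing <- profile$gene_id %in% group_ids
  if (!any(ing) || all(ing))
    stop("group must be a nonempty strict subset of the universe")
  x <- profile$decay[ing]; y <- profile$decay[!ing]
  exact <- min(length(x), length(y)) < 20 && !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)
  list(n = length(x),
       median_percentile = stats::median(profile$stability_percentile[ing]),
       U = unname(wt$statistic), p = wt$p.value, stars = star_string(wt$p.value))
}

#' Feature composition of a gene group, with enrichment test
#'
#' The fraction of the group carrying a feature, and a two-sided Fisher
#' exact p-value for enrichment of the feature in the group against the
#' rest of the universe.
#'
#' @param group_ids ids of the group.
#' @param feature_ids ids carrying the feature.
#' @param universe all gene ids.
#' @return list with `fraction`, `p`, `n_group`.
#' @export
composition_enrichment <- function(group_ids, feature_ids, universe) {
  group_ids <- intersect(group_ids, universe)
  if (!length(group_ids)) stop("empty group")
  feature_ids <- intersect(feature_ids, universe)
  a <- sum(group_ids %in% feature_ids)
  tab <- matrix(c(a, length(group_ids) - a,
                  length(setdiff(feature_ids, group_ids)),
                  length(universe) - length(union(group_ids, feature_ids))),
                nrow = 2)
  list(fraction = a / length(group_ids),
       p = stats::fisher.test(tab)$p.value,
       n_group = length(group_ids))
}

#' Odds ratio with Woolf confidence interval
#'
#' Sample odds ratio `ad/bc` of a 2x2 table, a normal-approximation
#' confidence interval on the log odds ratio (Woolf), applying the Haldane
#' 0.5 continuity correction to all cells when any cell is zero, and a
#' two-sided Fisher exact p-value on the original table.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param conf confidence level (default 0.95).
#' @return list with `or`, `ci_low`, `ci_high`, `p`.
#' @export
odds_ratio_ci <- function(tab, conf = 0.95) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("odds ratio undefined: a margin of the table is zero")
  p <- stats::fisher.test(tab)$p.value
  if (any(tab == 0)) tab <- tab + 0.5
  or <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se), p = p)
}

#' Log-transform and winsorize decay rates
#'
#' `y = log10(decay)`, then values below the lower-tail quantile are set to
#' it and values above the upper-tail quantile to it (linear-interpolation
#' quantiles), limiting outlier influence on the regression.
#'
#' @param decay decay rates, all > 0.
#' @param tail winsorized fraction at each end (default 0.01 = top and
#'   bottom 1%).
#' @return numeric vector, same length and order as the input.
#' @export
winsorize_log <- function(decay, tail = 0.01) {
  if (any(!is.finite(decay)) || any(decay <= 0))
    stop("decay rates must be finite and > 0")
  y <- log10(decay)
  q <- stats::quantile(y, c(tail, 1 - tail), type = 7, names = FALSE)
  pmin(pmax(y, q[1]), q[2])
}

# design matrices over the 8 feature cells, columns in coefficient order
# beta0..beta7: 1, TF, me3, CTS, TF:me3, TF:CTS, me3:CTS, TF:me3:CTS
cell_grid <- function() {
  g <- expand.grid(tf = 0:1, me3 = 0:1, cts = 0:1)
  g[order(g$tf, g$me3, g$cts), c("tf", "me3", "cts")]
}

design_matrix <- function(tf, me3, cts, interactions) {
  X <- cbind(`(Intercept)` = 1, TF = tf, me3 = me3, CTS = cts)
  if (interactions)
    X <- cbind(X, `TF:me3` = tf * me3, `TF:CTS` = tf * cts,
               `me3:CTS` = me3 * cts, `TF:me3:CTS` = tf * me3 * cts)
  X
}

#' Linear model of log decay rates on gene features
#'
#' Ordinary least squares of (winsorized log10) decay rates on the three
#' binary features TF, me3 (extended H3K27me3) and CTS, either additive
#' (coefficients beta0..beta3) or with all pairwise and the three-way
#' interaction (beta0..beta7). The interaction model is saturated over the
#' 8 feature cells: its fitted values equal the cell means exactly, and
#' beta0 equals the (0,0,0) group mean.
#'
#' @param y response (winsorized log10 decay rates).
#' @param tf,me3,cts logical or 0/1 feature vectors.
#' @param interactions include interaction terms (default TRUE).
#' @return object of class `decay_lm`: list with `coefficients`,
#'   `p_values`, `interactions`, `cell_means`, `cell_sizes`, and the
#'   underlying `lm` fit.
#' @export
fit_decay_model <- function(y, tf, me3, cts, interactions = TRUE) {
  tf <- as.integer(tf); me3 <- as.integer(me3); cts <- as.integer(cts)
  stopifnot(length(tf) == length(y), length(me3) == length(y),
            length(cts) == length(y))
  grid <- cell_grid()
  cell <- interaction(tf, me3, cts)
  sizes <- as.integer(table(factor(cell, levels = interaction(grid$tf,
                                                              grid$me3,
                                                              grid$cts))))
  names(sizes) <- sprintf("(%d,%d,%d)", grid$tf, grid$me3, grid$cts)
  if (interactions && any(sizes == 0))
    stop("empty feature cell(s) make the interaction model rank-deficient: ",
         paste(names(sizes)[sizes == 0], collapse = ", "))
  X <- design_matrix(tf, me3, cts, interactions)
  # features with no carriers are not estimable; drop their columns so the
  # remaining coefficients (e.g. the grand-mean intercept) are still exact
  keep <- c(TRUE, colSums(abs(X[, -1, drop = FALSE])) > 0)
  X <- X[, keep, drop = FALSE]
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  fitted <- fit$fitted.values
  means <- tapply(y, factor(cell, levels = interaction(grid$tf, grid$me3,
                                                       grid$cts)), mean)
  names(means) <- names(sizes)
  if (interactions) {
    # the saturated model has closed-form coefficients in the cell means;
    # using them makes the fitted values equal the cell means exactly
    m <- stats::setNames(means, sprintf("m%d%d%d", grid$tf, grid$me3,
                                        grid$cts))
    coefs[] <- c(m["m000"],
                 m["m100"] - m["m000"],
                 m["m010"] - m["m000"],
                 m["m001"] - m["m000"],
                 m["m110"] - m["m100"] - m["m010"] + m["m000"],
                 m["m101"] - m["m100"] - m["m001"] + m["m000"],
                 m["m011"] - m["m010"] - m["m001"] + m["m000"],
                 m["m111"] - m["m110"] - m["m101"] - m["m011"] +
                   m["m100"] + m["m010"] + m["m001"] - m["m000"])
    cellidx <- sprintf("(%d,%d,%d)", tf, me3, cts)
    fitted <- unname(means[cellidx])
  }
  residuals <- y - fitted
  # normal-theory two-sided p-values
  rss <- sum(residuals^2)
  df <- length(y) - fit$rank
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- coefs / se
  pvals <- 2 * stats::pt(-abs(tval), df)
  structure(list(coefficients = coefs, p_values = pvals, se = se,
                 interactions = interactions, cell_means = means,
                 cell_sizes = sizes, sigma = sqrt(sigma2), df = df,
                 fitted = fitted, residuals = residuals),
            class = "decay_lm")
}

#' @export
print.decay_lm <- function(x, ...) {
  cat(sprintf("OLS model of log10 decay rate (%s interactions), n = %d\n",
              if (x$interactions) "with" else "without", sum(x$cell_sizes)))
  tab <- cbind(estimate = x$coefficients, se = x$se, p = x$p_values)
  print(signif(tab, 4))
  invisible(x)
}

#' @export
coef.decay_lm <- function(object, ...) object$coefficients

#' @export
summary.decay_lm <- function(object, ...) {
  cat(sprintf("feature-cell means (log10 decay), sizes in parentheses:\n"))
  for (nm in names(object$cell_means))
    cat(sprintf("  %s: %8.4f (%d)\n", nm, object$cell_means[nm],
                object$cell_sizes[nm]))
  print(object)
  invisible(object)
}

#' Stratified bootstrap of the feature regression
#'
#' Resamples each of the eight nonoverlapping feature groups with
#' replacement at a common depth (by default the smallest group's size) and
#' refits both the additive and the interaction model, giving each group
#' equal weight regardless of its frequency in the data. With equal
#' per-group depth, the OLS coefficients depend on the data only through
#' the eight resampled cell means, which is how the refits are computed.
#'
#' @param y response (winsorized log10 decay rates).
#' @param tf,me3,cts feature vectors.
#' @param n_iter bootstrap iterations (default 10000).
#' @param per_group_n genes sampled per group per iteration; `"min"`
#'   (default) uses the smallest group size.
#' @param seed integer seed for reproducible draws.
#' @return object of class `decay_boot`: list with matrices
#'   `draws_additive` (n_iter x 4) and `draws_interaction` (n_iter x 8),
#'   `positive_frac` per coefficient, `per_group_n`, `group_sizes`.
#' @export
bootstrap_model <- function(y, tf, me3, cts, n_iter = 10000,
                            per_group_n = "min", seed = NULL) {
  tf <- as.integer(tf); me3 <- as.integer(me3); cts <- as.integer(cts)
  grid <- cell_grid()
  cell <- factor(interaction(tf, me3, cts),
                 levels = interaction(grid$tf, grid$me3, grid$cts))
  groups <- split(y, cell)
  sizes <- vapply(groups, length, 0L)
  names(sizes) <- sprintf("(%d,%d,%d)", grid$tf, grid$me3, grid$cts)
  if (any(sizes == 0))
    stop("empty feature group(s): ",
         paste(names(sizes)[sizes == 0], collapse = ", "))
  n_g <- if (identical(per_group_n, "min")) min(sizes) else
    as.integer(per_group_n)
  if (n_g < 1) stop("per_group_n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  means <- matrix(0, n_iter, 8)
  for (g in seq_len(8)) {
    draws <- matrix(sample(groups[[g]], n_g * n_iter, replace = TRUE),
                    n_g, n_iter)
    means[, g] <- colMeans(draws)
  }
  Xc_int <- design_matrix(grid$tf, grid$me3, grid$cts, TRUE)
  Xc_add <- design_matrix(grid$tf, grid$me3, grid$cts, FALSE)
  # equal group weights: full-data OLS reduces to OLS on the 8 cell means
  B_int <- solve(Xc_int)
  B_add <- solve(crossprod(Xc_add), t(Xc_add))
  draws_int <- means %*% t(B_int)
  draws_add <- means %*% t(B_add)
  colnames(draws_int) <- colnames(Xc_int)
  colnames(draws_add) <- colnames(Xc_add)
  structure(list(draws_additive = draws_add, draws_interaction = draws_int,
                 positive_frac = list(
                   additive = colMeans(draws_add > 0),
                   interaction = colMeans(draws_int > 0)),
                 per_group_n = n_g, group_sizes = sizes, n_iter = n_iter),
            class = "decay_boot")
}

#' @export
print.decay_boot <- function(x, ...) {
  cat(sprintf("stratified bootstrap: %d iterations, %d genes per group (min group %d)\n",
              x$n_iter, x$per_group_n, min(x$group_sizes)))
  q <- function(m) t(apply(m, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  cat("interaction model coefficient quantiles:\n")
  print(signif(q(x$draws_interaction), 3))
  cat("fraction of positive draws (interaction model):\n")
  print(round(x$positive_frac$interaction, 3))
  invisible(x)
}

#' Mean decay-rate change per feature at fixed context
#'
#' For each feature, compares the mean response of the group positive for
#' the feature with the group negative for it but identical in the other
#' two features, across all four contexts. Pairs with an empty cell are
#' reported as `NA`, not 0.
#'
#' @param y response (winsorized log10 decay rates).
#' @param tf,me3,cts feature vectors.
#' @return data frame with `feature`, `context` (setting of the other two
#'   features), `delta` (mean difference, positive = feature raises decay),
#'   `n_pos`, `n_neg`.
#' @export
group_mean_changes <- function(y, tf, me3, cts) {
  flags <- data.frame(tf = as.integer(tf), me3 = as.integer(me3),
                      cts = as.integer(cts))
  out <- list()
  for (f in c("tf", "me3", "cts")) {
    others <- setdiff(c("tf", "me3", "cts"), f)
    ctx <- expand.grid(a = 0:1, b = 0:1)
    for (i in seq_len(4)) {
      in_ctx <- flags[[others[1]]] == ctx$a[i] & flags[[others[2]]] == ctx$b[i]
      pos <- in_ctx & flags[[f]] == 1
      neg <- in_ctx & flags[[f]] == 0
      out[[length(out) + 1L]] <- data.frame(
        feature = f,
        context = sprintf("%s=%d,%s=%d", others[1], ctx$a[i],
                          others[2], ctx$b[i]),
        delta = if (any(pos) && any(neg)) mean(y[pos]) - mean(y[neg]) else
          NA_real_,
        n_pos = sum(pos), n_neg = sum(neg), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Squared correlation on the log scale with pseudocounts
#'
#' Pearson r-squared of `log10(x + pc_x)` versus `log10(y + pc_y)`, where
#' each pseudocount is the smallest positive value of its vector (so zero
#' entries can be log-transformed).
#'
#' @param x,y paired nonnegative values.
#' @param log apply the log10 + pseudocount transform (default TRUE).
#' @return squared Pearson correlation.
#' @export
correlation_r2 <- function(x, y, log = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (log) {
    px <- min(x[x > 0]); py <- min(y[y > 0])
    x <- log10(x + px); y <- log10(y + py)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  stats::cor(x, y)^2
}
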