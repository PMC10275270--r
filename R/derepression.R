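#' Total-versus-nascent ratio shift after a perturbation
#'
#' For each gene, the difference between the total-RNA and the nascent-RNA
#' log2 fold changes of a knockdown against its control:
#' `delta = log2(total_kd / total_ctrl) - log2(nascent_kd / nascent_ctrl)`.
#' A purely transcriptional perturbation moves total RNA in step with
#' nascent RNA (delta near 0); a stability effect makes total respond more
#' than nascent (positive median delta for stabilised genes). A two-sided
#' Mann-Whitney test compares the target set's deltas against all other
#' genes. A pseudocount equal to the minimum positive abundance across the
#' four columns is added before the ratios, and delta is invariant to any
#' gene-independent global scaling of each library.
#'
#' @param input data frame with columns `gene_id`, `nascent_ctrl`,
#'   `nascent_kd`, `total_ctrl`, `total_kd` (normalised abundances).
#' @param target_ids ids of the putative target set (e.g. Polycomb-domain
#'   genes).
#' @param pseudocount override for the automatic minimum-positive rule.
#' @return list with `delta` (data frame `gene_id`, `delta`, `target`),
#'   `median_target`, `median_background`, `U`, `p`, `stars`.
#' @export
ratio_shift <- function(input, target_ids, pseudocount = NULL) {
  need <- c("gene_id", "nascent_ctrl", "nascent_kd", "total_ctrl", "total_kd")
  if (!all(need %in% names(input)))
    stop("input needs columns: ", paste(need, collapse = ", "))
  if (nrow(input) < 2) stop("need at least 2 genes")
  target_ids <- intersect(target_ids, input$gene_id)
  if (!length(target_ids)) stop("empty target set")
  vals <- as.matrix(input[, need[-1]])
  if (any(vals < 0)) stop("abundances must be >= 0")
  if (is.null(pseudocount)) {
    pos <- vals[vals > 0]
    if (!length(pos)) stop("no positive abundances")
    pseudocount <- min(pos)
  }
  v <- vals + pseudocount
  delta <- (log2(v[, "total_kd"]) - log2(v[, "total_ctrl"])) -
    (log2(v[, "nascent_kd"]) - log2(v[, "nascent_ctrl"]))
  target <- input$gene_id %in% target_ids
  dd <- data.frame(gene_id = input$gene_id, delta = delta, target = target,
                   stringsAsFactors = FALSE)
  if (all(target)) {
    wt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    wt <- stats::wilcox.test(delta[target], delta[!target],
                             alternative = "two.sided",
                             exact = sum(target) < 20 && !anyDuplicated(delta))
  }
  list(delta = dd,
       median_target = stats::median(delta[target]),
       median_background = if (all(target)) NA_real_ else
         stats::median(delta[!target]),
       U = unname(wt$statistic), p = wt$p.value,
       stars = star_string(wt$p.value),
       pseudocount = pseudocount)
}
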