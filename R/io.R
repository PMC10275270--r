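#' Load count/TPM tables with library metadata
#'
#' Reads a tab-separated quantification table (columns: `gene_id`, `region`
#' in {exonic, intronic}, optionally `length`, then one column per library)
#' and a library metadata table (`library_id`, `fraction` in
#' {total, pulldown}, `condition`, `replicate`). A `length` column marks a
#' count-mode table; without it the values are taken as TPM and operations
#' that need raw counts refuse the table.
#'
#' @param counts_path path to the quantification TSV.
#' @param libraries_path path to the library metadata TSV.
#' @return an object of class `count_table`: list with `counts` (numeric
#'   matrix, one column per library), `rowdata` (`gene_id`, `region`,
#'   `length`), `libraries` (metadata data frame) and `mode`
#'   (`"counts"` or `"tpm"`).
#' @export
load_tables <- function(counts_path, libraries_path) {
  for (f in c(counts_path, libraries_path))
    if (!file.exists(f)) stop("file not found: ", f)
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  libs <- utils::read.delim(libraries_path, stringsAsFactors = FALSE)
  need <- c("library_id", "fraction", "condition", "replicate")
  if (!all(need %in% names(libs)))
    stop("library metadata must have columns: ", paste(need, collapse = ", "))
  if (!all(libs$fraction %in% c("total", "pulldown")))
    stop("library fraction must be 'total' or 'pulldown'")
  if (!all(c("gene_id", "region") %in% names(raw)))
    stop("quantification table must have gene_id and region columns")
  has_len <- "length" %in% names(raw)
  meta_cols <- c("gene_id", "region", if (has_len) "length")
  lib_cols <- setdiff(names(raw), meta_cols)
  unknown <- setdiff(lib_cols, libs$library_id)
  if (length(unknown))
    stop("libraries missing from metadata: ", paste(unknown, collapse = ", "))
  libs <- libs[libs$library_id %in% lib_cols, ]
  key <- paste(raw$gene_id, raw$region)
  if (anyDuplicated(key))
    stop("duplicated gene_id+region rows: ",
         paste(unique(raw$gene_id[duplicated(key)]), collapse = ", "))
  if (!all(raw$region %in% c("exonic", "intronic")))
    stop("region must be 'exonic' or 'intronic'")
  counts <- as.matrix(raw[, libs$library_id, drop = FALSE])
  if (any(counts < 0)) stop("negative quantification values")
  rowdata <- data.frame(gene_id = raw$gene_id, region = raw$region,
                        length = if (has_len) raw$length else NA_real_,
                        stringsAsFactors = FALSE)
  if (has_len && any(rowdata$length <= 0)) stop("lengths must be > 0")
  orphan <- setdiff(rowdata$gene_id[rowdata$region == "intronic"],
                    rowdata$gene_id[rowdata$region == "exonic"])
  if (length(orphan))
    stop("intronic rows without exonic rows: ", paste(orphan, collapse = ", "))
  structure(list(counts = counts, rowdata = rowdata, libraries = libs,
                 mode = if (has_len) "counts" else "tpm"),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table (%s mode): %d rows (%d genes), %d libraries\n",
              x$mode, nrow(x$rowdata), length(unique(x$rowdata$gene_id)),
              nrow(x$libraries)))
  cat("fractions:", paste(sprintf("%s=%d", names(table(x$libraries$fraction)),
                                  table(x$libraries$fraction)),
                          collapse = ", "), "\n")
  invisible(x)
}

stop_if_not_counts <- function(ct) {
  if (!inherits(ct, "count_table")) stop("expected a count_table")
  if (ct$mode != "counts")
    stop("operation requires a count-mode table with lengths; got TPM mode")
}

#' Recompute TPM after excluding rRNA/spike-in rows
#'
#' Removes all rows belonging to the excluded gene ids (e.g. ribosomal RNAs
#' and spike-ins), then renormalises per library:
#' `TPM = (count/length) / sum(count/length) * 1e6`, so every library's TPM
#' column sums to one million over the retained rows.
#'
#' @param ct a count-mode `count_table`.
#' @param exclude_ids character vector of gene ids to drop before
#'   normalisation (default none).
#' @return a TPM-mode `count_table` over the retained rows.
#' @export
recompute_tpm <- function(ct, exclude_ids = character()) {
  stop_if_not_counts(ct)
  keep <- !(ct$rowdata$gene_id %in% exclude_ids)
  counts <- ct$counts[keep, , drop = FALSE]
  len <- ct$rowdata$length[keep]
  rate <- counts / len
  denom <- colSums(rate)
  if (any(denom == 0)) stop("all-zero library after exclusion: ",
                            paste(colnames(counts)[denom == 0], collapse = ", "))
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  structure(list(counts = tpm, rowdata = ct$rowdata[keep, ],
                 libraries = ct$libraries, mode = "tpm"),
            class = "count_table")
}

#' Expression filter: minimum counts in a fraction of libraries
#'
#' A gene is kept if, in at least one condition (condition x fraction
#' library group), its exonic count reaches `min_count` in at least
#' `ceiling(frac * n_libraries)` of the group's libraries. With the default
#' 10 counts in 2/3 of libraries, a 3-library group needs 2 passing
#' libraries.
#'
#' @param ct a count-mode `count_table`.
#' @param min_count minimum count per library.
#' @param frac required fraction of a group's libraries (ceiling rule).
#' @param region which region's counts to filter on (default exonic).
#' @return character vector of surviving gene ids.
#' @export
filter_expressed <- function(ct, min_count = 10, frac = 2 / 3,
                             region = "exonic") {
  stop_if_not_counts(ct)
  rows <- ct$rowdata$region == region
  if (!any(rows)) stop("no rows with region ", region)
  counts <- ct$counts[rows, , drop = FALSE]
  ids <- ct$rowdata$gene_id[rows]
  grp <- interaction(ct$libraries$condition, ct$libraries$fraction, drop = TRUE)
  keep <- rep(FALSE, length(ids))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    need <- ceiling(frac * length(cols))
    pass <- rowSums(counts[, cols, drop = FALSE] >= min_count) >= need
    keep <- keep | pass
  }
  ids[keep]
}

#' Split TPM signal into premature, mature and total abundances
#'
#' Treats the exonic TPM of a gene as its total signal (pre-mRNA contains
#' exons too) and the intronic TPM as the premature signal; mature signal is
#' `max(total - premature, 0)`. Genes whose premature signal exceeds their
#' total in any library are flagged degenerate (retained in the profile but
#' excluded from rate estimation downstream). Intronless genes get premature
#' 0.
#'
#' @param ct a TPM-mode `count_table`.
#' @return an object of class `expression_profile`: list with `gene_id`,
#'   matrices `premature`, `mature`, `total` (gene x library), logical
#'   `degenerate`, logical `intronless`, and the library metadata.
#' @export
split_premature_mature <- function(ct) {
  if (!inherits(ct, "count_table")) stop("expected a count_table")
  if (ct$mode != "tpm") stop("expected a TPM-mode table; run recompute_tpm()")
  ex <- ct$rowdata$region == "exonic"
  genes <- ct$rowdata$gene_id[ex]
  total <- ct$counts[ex, , drop = FALSE]
  rownames(total) <- genes
  premature <- matrix(0, nrow(total), ncol(total), dimnames = dimnames(total))
  intr <- which(ct$rowdata$region == "intronic")
  premature[ct$rowdata$gene_id[intr], ] <- ct$counts[intr, , drop = FALSE]
  degenerate <- apply(premature > total, 1, any)
  mature <- pmax(total - premature, 0)
  structure(list(gene_id = genes, premature = premature, mature = mature,
                 total = total, degenerate = unname(degenerate),
                 intronless = !(genes %in% ct$rowdata$gene_id[intr]),
                 libraries = ct$libraries),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile: %d genes x %d libraries (%d degenerate, %d intronless)\n",
              length(x$gene_id), ncol(x$total), sum(x$degenerate),
              sum(x$intronless)))
  invisible(x)
}

# Per-gene mean and replicate sample variance over the libraries of one
# fraction (optionally one condition).
profile_stats <- function(profile, fraction, condition = NULL) {
  sel <- profile$libraries$fraction == fraction
  if (!is.null(condition)) sel <- sel & profile$libraries$condition == condition
  if (!any(sel)) stop("no libraries for fraction ", fraction)
  cols <- profile$libraries$library_id[sel]
  f <- function(m) list(mean = rowMeans(m[, cols, drop = FALSE]),
                        var = apply(m[, cols, drop = FALSE], 1, stats::var))
  list(premature = f(profile$premature), mature = f(profile$mature),
       total = f(profile$total), n = length(cols))
}

#' Per-library percentage of unspliced signal
#'
#' `100 * sum(premature) / sum(total)` per library. Pull-down libraries are
#' expected to show a substantially higher unspliced percentage than total
#' libraries, since labeled RNA is recent and enriched for unprocessed
#' transcripts.
#'
#' @param profile an `expression_profile`.
#' @return data frame with `library_id`, `fraction`, `pct_unspliced`.
#' @export
library_unspliced_fraction <- function(profile) {
  if (!length(profile$gene_id)) stop("empty profile")
  tot <- colSums(profile$total)
  if (any(tot == 0)) stop("library with zero total signal")
  data.frame(library_id = profile$libraries$library_id,
             fraction = profile$libraries$fraction,
             pct_unspliced = 100 * colSums(profile$premature) / tot,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subset a count table to a set of genes
#'
#' @param ct a `count_table`.
#' @param gene_ids ids to keep (spike-in/extra rows not listed are dropped).
#' @return the subsetted `count_table`.
#' @export
subset_genes <- function(ct, gene_ids) {
  keep <- ct$rowdata$gene_id %in% gene_ids
  structure(list(counts = ct$counts[keep, , drop = FALSE],
                 rowdata = ct$rowdata[keep, ], libraries = ct$libraries,
                 mode = ct$mode),
            class = "count_table")
}
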