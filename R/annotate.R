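#' Read gene models from GTF or a minimal TSV
#'
#' GTF is read (via rtracklayer, 1-based closed coordinates) and collapsed
#' to one span per `gene_id`; a minimal TSV needs columns `gene_id`,
#' `chrom`, `strand`, `start`, `end`. The TSS is the start on the + strand
#' and the end on the - strand; the TES is the opposite end.
#'
#' @param path GTF (`.gtf`/`.gff`) or TSV file.
#' @return data frame `gene_id`, `chrom`, `strand`, `start`, `end` (1-based
#'   closed).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gtf$|\\.gff[23]?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    df <- data.frame(gene_id = S4Vectors::mcols(gr)$gene_id,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    # outermost span per gene (multi-isoform records collapse to gene level)
    sp <- split(df, df$gene_id)
    df <- do.call(rbind, lapply(sp, function(d)
      data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                 strand = d$strand[1], start = min(d$start),
                 end = max(d$end), stringsAsFactors = FALSE)))
    rownames(df) <- NULL
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end")
    if (!all(need %in% names(df)))
      stop("gene model TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$start > df$end)) stop("gene models with start > end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df
}

#' Read peak intervals from BED
#'
#' BED files are 0-based half-open on disk; rtracklayer converts them to
#' 1-based closed GRanges on import, which is the internal convention here.
#'
#' @param path BED file.
#' @return a `GRanges` of peaks.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rtracklayer::import(path, format = "BED")
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         strand = genes$strand)
}

#' Classify genes by H3K27me3 peak location
#'
#' A gene is flagged `A` if any peak overlaps the window within 1 kb of its
#' transcription start site (both sides of the TSS point), `C` analogously
#' at the transcription end site, and `B` if any peak overlaps the gene
#' body (the full span including introns and exons). Windows are
#' strand-aware: upstream of a minus-strand gene lies at higher
#' coordinates. Every gene gets exactly one category: the concatenation of
#' its flags (`"none"`, `"A"`, `"B"`, `"C"`, `"AB"`, `"AC"`, `"BC"`,
#' `"ABC"`). Genes carrying all three (`"ABC"`) are the "extended" targets
#' used as the me3 feature in the regression.
#'
#' @param genes gene models from [read_gene_models()].
#' @param peaks a `GRanges` of peaks (or data frame `chrom`, `start`, `end`
#'   in 1-based closed coordinates).
#' @param window half-width of the TSS/TES windows, nucleotides.
#' @return data frame `gene_id`, `me3_category`, `extended_me3`.
#' @export
classify_h3k27me3 <- function(genes, peaks, window = 1000) {
  if (is.data.frame(peaks))
    peaks <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(peaks$start, peaks$end))
  gr <- genes_to_granges(genes)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  tes <- ifelse(plus, genes$end, genes$start)
  win <- function(center) GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(center - window, 1), center + window))
  # genes on chromosomes without peaks simply see an empty peak set
  lv <- unique(c(GenomeInfoDb::seqlevels(peaks), genes$chrom))
  GenomeInfoDb::seqlevels(peaks) <- lv
  hits <- function(q) {
    GenomeInfoDb::seqlevels(q) <- lv
    GenomicRanges::countOverlaps(q, peaks, ignore.strand = TRUE) > 0
  }
  a <- hits(win(tss))
  b <- hits(gr)
  c_ <- hits(win(tes))
  cat_str <- paste0(ifelse(a, "A", ""), ifelse(b, "B", ""), ifelse(c_, "C", ""))
  cat_str[cat_str == ""] <- "none"
  data.frame(gene_id = genes$gene_id, me3_category = cat_str,
             extended_me3 = cat_str == "ABC", stringsAsFactors = FALSE)
}

#' Classify cell-type-specific genes from a single-cell enrichment table
#'
#' A gene is cell-type specific (CTS) if at least one cell type shows
#' statistical enrichment (`p_value < p_max`) together with a fold-change
#' of at least `min_fc` (linear scale). Per-cell-type gene sets are
#' returned for composition analyses.
#'
#' @param enrichment data frame with columns `gene_id`, `cell_type`,
#'   `fold_change`, `p_value`.
#' @param p_max p-value threshold (default 0.05).
#' @param min_fc minimum linear fold change (default 2).
#' @return list with `flags` (data frame `gene_id`, `cts`) and `sets`
#'   (named list of gene-id vectors per cell type).
#' @export
classify_cts <- function(enrichment, p_max = 0.05, min_fc = 2) {
  need <- c("gene_id", "cell_type", "fold_change", "p_value")
  if (!all(need %in% names(enrichment)))
    stop("enrichment table needs columns: ", paste(need, collapse = ", "))
  hit <- enrichment$p_value < p_max & enrichment$fold_change >= min_fc
  sets <- lapply(split(enrichment$gene_id[hit], enrichment$cell_type[hit]),
                 unique)
  genes <- unique(enrichment$gene_id)
  list(flags = data.frame(gene_id = genes,
                          cts = genes %in% unique(enrichment$gene_id[hit]),
                          stringsAsFactors = FALSE),
       sets = sets)
}

#' Load plain-text gene lists as membership flags
#'
#' Each file holds one gene id per line; duplicates are dropped. Ids absent
#' from the reference universe are reported via a message and excluded.
#'
#' @param paths named character vector of list files; names become flag
#'   columns.
#' @param universe character vector of known gene ids (e.g. the rate
#'   table's genes).
#' @return data frame with `gene_id` and one logical column per list.
#' @export
load_gene_lists <- function(paths, universe) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("paths must be named (name becomes the flag column)")
  out <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (nm in names(paths)) {
    ids <- unique(readLines(paths[[nm]]))
    ids <- ids[nzchar(ids)]
    if (!length(ids)) stop("empty gene list: ", paths[[nm]])
    missing <- setdiff(ids, universe)
    if (length(missing))
      message(length(missing), " ids in '", nm,
              "' absent from the universe; dropped")
    out[[nm]] <- universe %in% ids
  }
  out
}

#' Partition genes into the eight (TF, me3, CTS) groups
#'
#' Every gene falls in exactly one of the 2^3 combinations of the three
#' binary features, written as a vector string like `"(1,0,1)"` in the
#' order (TF, me3, CTS).
#'
#' @param annotation data frame with logical columns `tf`, `me3`, `cts`.
#' @return list with `group` (character vector, one entry per gene, ordered
#'   as the input) and `sizes` (named table over all 8 groups).
#' @export
nonoverlapping_groups <- function(annotation) {
  stopifnot(all(c("tf", "me3", "cts") %in% names(annotation)))
  grp <- sprintf("(%d,%d,%d)", as.integer(annotation$tf),
                 as.integer(annotation$me3), as.integer(annotation$cts))
  lv <- as.vector(outer(0:1, outer(0:1, 0:1, paste, sep = ","),
                        paste, sep = ","))
  lv <- sprintf("(%s)", sort(lv))
  sizes <- table(factor(grp, levels = lv))
  list(group = grp, sizes = sizes)
}

#' Assemble the full feature annotation
#'
#' Joins TF membership, CTS classification, and the H3K27me3 category into
#' one table over a gene universe, ready for the regression stage (the
#' regression's `me3` feature is the extended, ABC-category flag).
#'
#' @param universe gene ids with measured rates.
#' @param tf_ids transcription-factor gene ids.
#' @param cts_flags data frame from [classify_cts()]`$flags`.
#' @param me3 data frame from [classify_h3k27me3()].
#' @param extra named list of extra id vectors to add as flags.
#' @return data frame `gene_id`, `tf`, `cts`, `me3_category`, `me3`
#'   (extended), plus extra flags.
#' @export
build_annotation <- function(universe, tf_ids, cts_flags, me3,
                             extra = list()) {
  out <- data.frame(gene_id = universe,
                    tf = universe %in% tf_ids,
                    cts = universe %in% cts_flags$gene_id[cts_flags$cts],
                    stringsAsFactors = FALSE)
  idx <- match(universe, me3$gene_id)
  out$me3_category <- ifelse(is.na(idx), "none", me3$me3_category[idx])
  out$me3 <- out$me3_category == "ABC"
  for (nm in names(extra)) out[[nm]] <- universe %in% extra[[nm]]
  out
}
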