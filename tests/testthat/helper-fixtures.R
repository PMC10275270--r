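# shared fixture builders; everything is generated in code at test time

# hand-built count_table without going through files
make_ct <- function(counts, gene_id, region, length = NULL, libs) {
  counts <- as.matrix(counts)
  colnames(counts) <- libs$library_id
  structure(list(counts = counts,
                 rowdata = data.frame(gene_id = gene_id, region = region,
                                      length = if (is.null(length))
                                        NA_real_ else length,
                                      stringsAsFactors = FALSE),
                 libraries = libs,
                 mode = if (is.null(length)) "tpm" else "counts"),
            class = "count_table")
}

lib_meta <- function(n_rep = 3, fractions = c("total", "pulldown"),
                     condition = "cond1") {
  libs <- expand.grid(replicate = seq_len(n_rep), fraction = fractions,
                      condition = condition, stringsAsFactors = FALSE)
  libs$library_id <- sprintf("%s_%s_rep%d", libs$fraction, libs$condition,
                             libs$replicate)
  libs[, c("library_id", "fraction", "condition", "replicate")]
}

# independent oracle: fourth-order numerical integration of the labeling ODEs
ode_labeled <- function(alpha, k_p, k_d, t) {
  deriv <- function(t, y, parms)
    list(c(alpha - k_p * y[1], k_p * y[1] - k_d * y[2]))
  out <- deSolve::ode(y = c(P = 0, M = 0), times = c(0, t), func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 1e-12, atol = 1e-14)
  c(labeled_premature = unname(out[2, "P"]),
    labeled_mature = unname(out[2, "M"]))
}

# response fixture over the 8 (TF, me3, CTS) cells; residuals can be centred
# within each cell so the sample cell means equal the model exactly
make_group_fixture <- function(sizes, effects = c(tf = 0, me3 = 0, cts = 0),
                               sd = 0.3, base = -2, center = FALSE,
                               seed = 1) {
  set.seed(seed)
  grid <- expand.grid(tf = 0:1, me3 = 0:1, cts = 0:1)
  grid <- grid[order(grid$tf, grid$me3, grid$cts), ]
  stopifnot(length(sizes) == 8)
  rows <- lapply(seq_len(8), function(i) {
    mu <- base + effects["tf"] * grid$tf[i] + effects["me3"] * grid$me3[i] +
      effects["cts"] * grid$cts[i]
    eps <- stats::rnorm(sizes[i], 0, sd)
    if (center) eps <- eps - mean(eps)
    data.frame(tf = grid$tf[i], me3 = grid$me3[i], cts = grid$cts[i],
               y = mu + eps)
  })
  do.call(rbind, rows)
}
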