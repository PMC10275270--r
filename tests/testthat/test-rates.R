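test_that("scale policies validate and fixed factors pass through", {
  expect_error(scale_policy("fixed_factor"), "needs a positive value")
  expect_equal(estimate_scale(NULL, policy = scale_policy("fixed_factor", 2.5)),
               2.5)
})

test_that("identical spike signal in both fractions gives scale 1", {
  libs <- lib_meta(n_rep = 1)
  counts <- rbind(c(100, 100), c(50, 50), c(10, 10))
  ct <- make_ct(counts, c("g1", "g2", "spike_a"), rep("exonic", 3),
                length = c(1000, 1000, 1000), libs = libs)
  spikes <- data.frame(id = "spike_a", amount = 5)
  expect_equal(estimate_scale(ct, spikes), 1)
})

test_that("spike scaling recovers the generative scale", {
  # noise-free: exact; the generative scale is the ratio of pull-down to
  # total library signal over gene rows (exonic + intronic)
  cfg <- simulation_config(n_genes = 500, nb_dispersion = 0, seed = 8)
  sim <- simulate_experiment(cfg)
  has_intron <- is.finite(sim$params$k_p)
  tot <- sim$pools$premature + sim$pools$mature
  lab <- sim$pools$labeled_premature + sim$pools$labeled_mature
  cfr <- cfg$contamination_frac
  pd_ex <- lab + cfr * (tot - lab)
  pd_in <- sim$pools$labeled_premature +
    cfr * (sim$pools$premature - sim$pools$labeled_premature)
  s_true <- (sum(pd_ex) + sum(pd_in[has_intron])) /
    (sum(tot) + sum(sim$pools$premature[has_intron]))
  s_est <- estimate_scale(sim$counts, cfg$spike_in_spec)
  expect_equal(s_est, s_true, tolerance = 1e-9)
  # with replicate count noise at the default dispersion: within 5%
  cfg2 <- simulation_config(n_genes = 5000, seed = 1)
  sim2 <- simulate_experiment(cfg2)
  s_est2 <- estimate_scale(sim2$counts, cfg2$spike_in_spec)
  has_intron <- is.finite(sim2$params$k_p)
  tot <- sim2$pools$premature + sim2$pools$mature
  lab <- sim2$pools$labeled_premature + sim2$pools$labeled_mature
  pd_ex <- lab + 0.01 * (tot - lab)
  pd_in <- sim2$pools$labeled_premature +
    0.01 * (sim2$pools$premature - sim2$pools$labeled_premature)
  s_true2 <- (sum(pd_ex) + sum(pd_in[has_intron])) /
    (sum(tot) + sum(sim2$pools$premature[has_intron]))
  expect_lt(abs(s_est2 / s_true2 - 1), 0.05)
})

test_that("linear synthesis is scaled labeled signal over pulse time", {
  got <- estimate_synthesis(10, t_label = 20, s = 1)
  expect_equal(got$synthesis, 0.5)
  expect_error(estimate_synthesis(10, t_label = 0, s = 1), "t_label")
  expect_error(estimate_synthesis(10, t_label = 20, s = -1), "scale")
})

test_that("exact synthesis inverts the labeled-pool solution", {
  set.seed(23)
  n <- 50
  params <- data.frame(gene_id = sprintf("g%d", 1:n),
                       alpha = 10^runif(n, -2, 1),
                       k_p = 10^runif(n, -2, 0),
                       k_d = log(2) / 10^runif(n, log10(5), 3.5))
  pools <- steady_state_pools(params)
  lab <- labeled_pools(params, 20)
  got <- estimate_synthesis(lab$labeled_premature + lab$labeled_mature,
                            t_label = 20, s = 1, mode = "exact",
                            total = pools$premature + pools$mature,
                            premature = pools$premature)
  expect_true(all(got$converged))
  expect_equal(got$synthesis, params$alpha, tolerance = 1e-6)
  # linear mode underestimates, more severely for faster decay (monotone in
  # k_d at fixed processing rate)
  lin <- estimate_synthesis(lab$labeled_premature + lab$labeled_mature,
                            t_label = 20, s = 1)
  expect_true(all(lin$synthesis <= params$alpha * (1 + 1e-12)))
  pm <- data.frame(gene_id = sprintf("m%d", 1:20), alpha = 1, k_p = 0.1,
                   k_d = 10^seq(-4, -1, length.out = 20))
  labm <- labeled_pools(pm, 20)
  ratio <- estimate_synthesis(labm$labeled_premature + labm$labeled_mature,
                              t_label = 20, s = 1)$synthesis / pm$alpha
  expect_true(all(diff(ratio) < 0))
})

test_that("decay follows synthesis over mature abundance", {
  d <- estimate_decay(1, total = 100, premature = 20)
  expect_equal(d$decay, 0.0125)
  expect_equal(d$half_life, log(2) / 0.0125)
  expect_equal(round(log(2) / 0.0125, 2), 55.45)
  dg <- estimate_decay(1, total = 10, premature = 10)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$decay))
})

test_that("processing is synthesis over premature, missing when intronless", {
  expect_equal(estimate_processing(1, 10), 0.1)
  expect_true(is.na(estimate_processing(1, 0)))
})

test_that("noise-free fixture rates match the generative truth", {
  cfg <- simulation_config(n_genes = 400, nb_dispersion = 0,
                           contamination_frac = 0, seed = 19)
  sim <- simulate_experiment(cfg)
  fit <- fit_kinetics(sim$counts, spike_ins = cfg$spike_in_spec,
                      synthesis = "exact")
  m <- match(fit$rates$gene_id, sim$params$gene_id)
  ok <- fit$rates$converged & !fit$rates$capped
  expect_gt(mean(ok), 0.95)
  expect_equal(fit$rates$decay[ok], sim$params$k_d[m][ok], tolerance = 1e-6)
  fin <- ok & is.finite(sim$params$k_p[m])
  expect_equal(fit$rates$processing[fin], sim$params$k_p[m][fin],
               tolerance = 1e-6)
  # intronless genes: processing missing, decay still estimated
  intronless <- ok & !is.finite(sim$params$k_p[m])
  expect_true(all(is.na(fit$rates$processing[intronless])))
  expect_true(all(is.finite(fit$rates$decay[intronless])))
})

test_that("doubling library depth leaves TPM-based rates unchanged", {
  cfg1 <- simulation_config(n_genes = 150, nb_dispersion = 0, seed = 6)
  cfg2 <- simulation_config(n_genes = 150, nb_dispersion = 0, seed = 6,
                            library_depth = 4e7)
  f1 <- fit_kinetics(simulate_experiment(cfg1)$counts,
                     spike_ins = cfg1$spike_in_spec)
  f2 <- fit_kinetics(simulate_experiment(cfg2)$counts,
                     spike_ins = cfg2$spike_in_spec)
  expect_equal(f1$rates$decay, f2$rates$decay, tolerance = 1e-9)
})

test_that("specificity cap follows the short-pulse closed form", {
  expect_equal(cap_from_specificity(0.01, 20), log(2) * 2000)
  expect_equal(round(cap_from_specificity(0.01, 20), 2), 1386.29)
  expect_equal(cap_from_specificity(1, 20), log(2) * 20)
  expect_equal(round(cap_from_specificity(1, 20), 2), 13.86)
  expect_equal(round(cap_from_specificity(0.01, 10), 2), 693.15)
  expect_error(cap_from_specificity(0, 20), "ratio")
})

test_that("capping rewrites half-lives but not decay rates", {
  r <- data.frame(half_life = c(1500, 82), decay = log(2) / c(1500, 82))
  capped <- apply_cap(r, 1000)
  expect_equal(capped$half_life, c(1000, 82))
  expect_equal(capped$capped, c(TRUE, FALSE))
  expect_equal(capped$decay, r$decay)
})

test_that("delta-method CV reduces correctly in limiting cases", {
  expect_equal(propagate_cv(0, 0, 0, 100, 20), 0)
  expect_equal(propagate_cv(0.1, 0, 0, 100, 20), 0.1)
  expect_true(is.na(propagate_cv(0.1, 1, 1, 10, 10)))
  expect_error(propagate_cv(0.1, -1, 0, 100, 20), "variances")
})

test_that("propagated decay CV tracks empirical replicate variability", {
  cfg <- simulation_config(n_genes = 800, seed = 29)
  sim <- simulate_experiment(cfg)
  fit <- fit_kinetics(sim$counts, spike_ins = cfg$spike_in_spec)
  # empirical check: per-gene CV from per-replicate decay estimates
  tpm <- recompute_tpm(sim$counts, cfg$spike_in_spec$id)
  tpm <- subset_genes(tpm, fit$rates$gene_id)
  prof <- split_premature_mature(tpm)
  libs <- prof$libraries
  per_rep <- sapply(1:3, function(r) {
    tot <- prof$total[, libs$library_id[libs$fraction == "total" &
                                          libs$replicate == r]]
    pre <- prof$premature[, libs$library_id[libs$fraction == "total" &
                                              libs$replicate == r]]
    lab <- prof$total[, libs$library_id[libs$fraction == "pulldown" &
                                          libs$replicate == r]]
    (fit$scale * lab / fit$t_label) / (tot - pre)
  })
  emp_cv <- apply(per_rep, 1, sd) / rowMeans(per_rep)
  m <- match(fit$rates$gene_id, prof$gene_id)
  ok <- is.finite(emp_cv[m]) & is.finite(fit$rates$cv_decay)
  ratio <- fit$rates$cv_decay[ok] / emp_cv[m][ok]
  # same scale for the bulk of genes
  expect_gt(mean(ratio > 0.5 & ratio < 2), 0.85)
})

test_that("premature/mature ratio equals decay/processing at steady state", {
  cfg <- simulation_config(n_genes = 150, nb_dispersion = 0,
                           contamination_frac = 0, seed = 27)
  sim <- simulate_experiment(cfg)
  tpm <- recompute_tpm(sim$counts, cfg$spike_in_spec$id)
  prof <- split_premature_mature(tpm)
  dp <- deg_proc_ratio(prof)
  m <- match(dp$gene_id, sim$params$gene_id)
  fin <- is.finite(sim$params$k_p[m])
  expect_equal(dp$ratio[fin], (sim$params$k_d / sim$params$k_p)[m][fin],
               tolerance = 1e-9)
  # intronless genes report 0/mature = 0 premature signal -> ratio 0
  expect_true(all(dp$ratio[!fin] == 0))
})

test_that("steady-state check returns r2 of log-level agreement", {
  cfg <- simulation_config(n_genes = 300, seed = 15)
  sim <- simulate_experiment(cfg)
  tpm <- recompute_tpm(sim$counts, cfg$spike_in_spec$id)
  prof <- split_premature_mature(tpm)
  same <- steady_state_check(prof, prof)
  expect_equal(same$r_squared, 1)
  # two independent replicates of the same truth stay highly correlated
  cfg2 <- simulation_config(n_genes = 300, seed = 15)
  cfg2$seed <- 16L
  sim2 <- simulate_experiment(cfg2)
  # same kinetic truth requires same seed for params; emulate a second
  # timepoint by resimulating libraries from the same pools
  ct2 <- simulate_libraries(sim$pools, cfg2, sim$genes)
  prof2 <- split_premature_mature(recompute_tpm(ct2, cfg2$spike_in_spec$id))
  r2 <- steady_state_check(prof, prof2)$r_squared
  expect_gt(r2, 0.9)
})

test_that("median-anchor scaling reproduces the requested median", {
  cfg <- simulation_config(n_genes = 1000, seed = 33)
  sim <- simulate_experiment(cfg)
  fit <- fit_kinetics(sim$counts,
                      scale = scale_policy("median_half_life_anchor", 82),
                      spike_ins = cfg$spike_in_spec)
  expect_lt(abs(median(fit$rates$half_life) - 82), 3)
})
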