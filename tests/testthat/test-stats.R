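test_that("stability percentiles rank genes by stability", {
  # four distinct rates: brute-force ranking gives 25/50/75/100
  prof <- stability_percentile(c(0.4, 0.01, 0.1, 0.02), letters[1:4])
  expect_equal(prof$stability_percentile, c(25, 100, 50, 75))
  # the fastest-decaying gene sits lowest
  expect_equal(which.min(prof$stability_percentile), which.max(prof$decay))
  # ties share a percentile
  tied <- stability_percentile(c(1, 1, 2))
  expect_equal(tied$stability_percentile[1], tied$stability_percentile[2])
  # uniformity: mean percentile is 50 + O(1/n)
  big <- stability_percentile(rlnorm(2001))
  expect_equal(mean(big$stability_percentile), 50, tolerance = 0.1)
})

test_that("group stability test reduces to U = n1*n2/2 under identity", {
  prof <- data.frame(gene_id = sprintf("g%d", 1:40),
                     decay = rep(1:20, 2),
                     stability_percentile = rep(50, 40))
  got <- group_stability_test(prof, sprintf("g%d", 1:20))
  expect_equal(got$U, 20 * 20 / 2)
  expect_gt(got$p, 0.9)
  expect_equal(got$stars, "")
})

test_that("a strongly shifted group is detected with the right stars", {
  set.seed(55)
  n <- 2000
  decay <- 10^rnorm(n, -2, 0.4)
  ids <- sprintf("g%04d", 1:n)
  grp <- ids[1:200]
  decay[1:200] <- decay[1:200] * 10^(3 * 0.4)  # +3 sigma shift
  prof <- stability_percentile(decay, ids)
  got <- group_stability_test(prof, grp)
  expect_lt(got$p, 1e-10)
  expect_true(got$stars %in% c("**", "***"))
  expect_lt(got$median_percentile, 25)
  # singleton group still computes, with a wide p
  single <- group_stability_test(prof, ids[5])
  expect_gt(single$p, 0.01)
})

test_that("composition enrichment combines fraction with Fisher tail", {
  universe <- sprintf("g%d", 1:100)
  group <- universe[1:20]
  feature <- universe[1:13]
  got <- composition_enrichment(group, feature, universe)
  expect_equal(got$fraction, 13 / 20)
  # independent hypergeometric tail for full containment of a rare feature
  expect_lt(composition_enrichment(universe[1:10], universe[1:10],
                                   universe)$p, 1e-10)
  # background-rate feature: no signal
  set.seed(9)
  feat_bg <- sample(universe, 50)
  grp_bg <- sample(universe, 40)
  expect_gt(composition_enrichment(grp_bg, feat_bg, universe)$p, 0.001)
})

test_that("odds ratio and Woolf interval match hand computation", {
  even <- odds_ratio_ci(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$or, 1)
  tab <- matrix(c(20, 5, 5, 20), 2)
  got <- odds_ratio_ci(tab)
  expect_equal(got$or, 16)
  se <- sqrt(1 / 20 + 1 / 5 + 1 / 5 + 1 / 20)
  z <- qnorm(0.975)
  expect_equal(got$ci_low, 16 * exp(-z * se))
  expect_equal(got$ci_high, 16 * exp(z * se))
  expect_equal(got$p, fisher.test(tab)$p.value)
  # zero cell: Haldane correction keeps the estimate finite
  hald <- odds_ratio_ci(matrix(c(10, 0, 5, 10), 2))
  expect_true(is.finite(hald$or) && hald$or > 1)
  expect_error(odds_ratio_ci(matrix(c(0, 0, 5, 10), 2)), "margin")
})

test_that("winsorization matches a brute-force sort oracle", {
  set.seed(77)
  x <- 10^rnorm(200, -2, 0.5)
  got <- winsorize_log(x, tail = 0.01)
  # oracle: replace values beyond the type-7 percentile bounds after sorting
  y <- log10(x)
  o <- sort(y)
  lo <- quantile(y, 0.01, type = 7, names = FALSE)
  hi <- quantile(y, 0.99, type = 7, names = FALSE)
  want <- pmin(pmax(y, lo), hi)
  expect_equal(got, want)
  # exactly the bottom 2 and top 2 of 200 distinct values are replaced
  expect_equal(sum(got != y), 4)
  expect_equal(sort(got)[1:2], rep(lo, 2))
  expect_equal(min(got), lo)
  expect_equal(max(got), hi)
  # all-equal input unchanged; order weakly preserved
  expect_equal(winsorize_log(rep(2, 10)), rep(log10(2), 10))
  expect_true(all(diff(got[order(y)]) >= 0))
  expect_error(winsorize_log(c(1, 0)), "> 0")
})

test_that("the interaction model is saturated over the 8 cells", {
  d <- make_group_fixture(sizes = c(50, 30, 40, 25, 35, 20, 30, 15),
                          effects = c(tf = 0.4, me3 = 0.3, cts = -0.2),
                          seed = 10)
  m <- fit_decay_model(d$y, d$tf, d$me3, d$cts, interactions = TRUE)
  b <- m$coefficients
  mu <- m$cell_means
  expect_equal(unname(b["(Intercept)"]), unname(mu["(0,0,0)"]),
               tolerance = 1e-12)
  expect_equal(unname(b["(Intercept)"] + b["TF"]), unname(mu["(1,0,0)"]),
               tolerance = 1e-10)
  expect_equal(unname(b["(Intercept)"] + b["TF"] + b["me3"] + b["TF:me3"]),
               unname(mu["(1,1,0)"]), tolerance = 1e-10)
  # fitted values equal cell means everywhere
  cellidx <- paste0("(", d$tf, ",", d$me3, ",", d$cts, ")")
  expect_equal(unname(m$fitted), unname(mu[cellidx]), tolerance = 1e-10)
  # an empty cell is an error naming the cell
  d2 <- d[!(d$tf == 1 & d$me3 == 1 & d$cts == 1), ]
  expect_error(fit_decay_model(d2$y, d2$tf, d2$me3, d2$cts, TRUE), "\\(1,1,1\\)")
})

test_that("additive OLS matches the independent normal-equation solution", {
  d <- make_group_fixture(sizes = rep(40, 8),
                          effects = c(tf = 0.25, me3 = 0.1, cts = -0.15),
                          seed = 20)
  m <- fit_decay_model(d$y, d$tf, d$me3, d$cts, interactions = FALSE)
  X <- cbind(1, d$tf, d$me3, d$cts)
  beta <- solve(t(X) %*% X) %*% t(X) %*% d$y
  expect_equal(unname(m$coefficients), as.vector(beta), tolerance = 1e-10)
  # flags all zero: intercept recovers the grand mean, no other terms
  m0 <- fit_decay_model(d$y, rep(0, nrow(d)), rep(0, nrow(d)),
                        rep(0, nrow(d)), interactions = FALSE)
  expect_equal(unname(m0$coefficients["(Intercept)"]), mean(d$y))
  expect_equal(length(m0$coefficients), 1L)
})

test_that("regression p-values agree with lm's t-tests", {
  d <- make_group_fixture(sizes = c(60, 35, 45, 30, 40, 25, 35, 20),
                          effects = c(tf = 0.3, me3 = 0.2, cts = 0),
                          seed = 30)
  m <- fit_decay_model(d$y, d$tf, d$me3, d$cts, interactions = FALSE)
  ref <- summary(lm(y ~ tf + me3 + cts, data = d))$coefficients
  expect_equal(unname(m$p_values), unname(ref[, 4]), tolerance = 1e-10)
})

test_that("bootstrap draws are deterministic and group-balanced", {
  d <- make_group_fixture(sizes = c(300, 80, 60, 50, 45, 42, 40, 39),
                          effects = c(tf = 0.2, me3 = 0.3, cts = -0.1),
                          seed = 40)
  b1 <- bootstrap_model(d$y, d$tf, d$me3, d$cts, n_iter = 200, seed = 101)
  b2 <- bootstrap_model(d$y, d$tf, d$me3, d$cts, n_iter = 200, seed = 101)
  expect_identical(b1$draws_interaction, b2$draws_interaction)
  expect_identical(b1$draws_additive, b2$draws_additive)
  expect_equal(b1$per_group_n, 39)
  # equal-weight refit equals full OLS when group sizes are equal: validate
  # the cell-mean shortcut against lm on an expanded balanced sample
  db <- make_group_fixture(sizes = rep(25, 8),
                           effects = c(tf = 0.2, me3 = 0.3, cts = -0.1),
                           seed = 41)
  ref <- lm(y ~ tf * me3 * cts, data = db)
  mu <- tapply(db$y, interaction(db$tf, db$me3, db$cts), mean)
  grid <- expand.grid(tf = 0:1, me3 = 0:1, cts = 0:1)
  grid <- grid[order(grid$tf, grid$me3, grid$cts), ]
  mu <- mu[paste(grid$tf, grid$me3, grid$cts, sep = ".")]
  bsolve <- bootstrap_model(db$y, db$tf, db$me3, db$cts, n_iter = 2, seed = 1)
  # reconstruct coefficients from the cell means with the same design
  Xc <- cbind(1, grid$tf, grid$me3, grid$cts, grid$tf * grid$me3,
              grid$tf * grid$cts, grid$me3 * grid$cts,
              grid$tf * grid$me3 * grid$cts)
  expect_equal(as.vector(solve(Xc, mu)),
               unname(coef(ref)[c("(Intercept)", "tf", "me3", "cts",
                                  "tf:me3", "tf:cts", "me3:cts",
                                  "tf:me3:cts")]),
               tolerance = 1e-9)
})

test_that("bootstrap means converge to the balanced fit, not the raw fit", {
  # heavily unbalanced groups with non-additive means: the two fits differ
  d <- make_group_fixture(sizes = c(1000, 60, 60, 60, 60, 60, 60, 39),
                          effects = c(tf = 0.3, me3 = 0.2, cts = 0),
                          seed = 50)
  d$y[d$tf == 1 & d$me3 == 1] <- d$y[d$tf == 1 & d$me3 == 1] + 0.4
  bt <- bootstrap_model(d$y, d$tf, d$me3, d$cts, n_iter = 4000, seed = 7)
  raw <- fit_decay_model(d$y, d$tf, d$me3, d$cts, interactions = FALSE)
  mu <- tapply(d$y, interaction(d$tf, d$me3, d$cts), mean)
  grid <- expand.grid(tf = 0:1, me3 = 0:1, cts = 0:1)
  grid <- grid[order(grid$tf, grid$me3, grid$cts), ]
  mu <- mu[paste(grid$tf, grid$me3, grid$cts, sep = ".")]
  Xa <- cbind(1, grid$tf, grid$me3, grid$cts)
  balanced <- solve(crossprod(Xa), crossprod(Xa, mu))
  boot_mean <- colMeans(bt$draws_additive)
  expect_equal(unname(boot_mean), as.vector(balanced), tolerance = 0.02)
  # and the raw fit is genuinely different on this fixture
  expect_gt(max(abs(raw$coefficients - as.vector(balanced))), 0.05)
})

test_that("winsorized regression ignores inflation of the extreme gene", {
  set.seed(66)
  decay <- 10^rnorm(500, -2, 0.4)
  flags <- data.frame(tf = runif(500) < 0.5, me3 = runif(500) < 0.5,
                      cts = runif(500) < 0.5)
  fit1 <- fit_decay_model(winsorize_log(decay), flags$tf, flags$me3,
                          flags$cts, interactions = FALSE)
  decay2 <- decay
  decay2[which.max(decay2)] <- decay2[which.max(decay2)] * 1e6
  fit2 <- fit_decay_model(winsorize_log(decay2), flags$tf, flags$me3,
                          flags$cts, interactions = FALSE)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-12)
})

test_that("mean changes recover planted shifts per context", {
  d <- make_group_fixture(sizes = rep(60, 8),
                          effects = c(tf = 0, me3 = 0.3, cts = 0),
                          sd = 0.05, center = TRUE, seed = 60)
  mc <- group_mean_changes(d$y, d$tf, d$me3, d$cts)
  me3_rows <- mc[mc$feature == "me3", ]
  expect_equal(me3_rows$delta, rep(0.3, 4), tolerance = 1e-10)
  tf_rows <- mc[mc$feature == "tf", ]
  expect_equal(tf_rows$delta, rep(0, 4), tolerance = 1e-10)
  # an empty pair is reported as NA, not 0
  d2 <- d[!(d$tf == 1 & d$me3 == 1 & d$cts == 1), ]
  mc2 <- group_mean_changes(d2$y, d2$tf, d2$me3, d2$cts)
  expect_true(any(is.na(mc2$delta)))
  expect_equal(mc2$n_pos[mc2$feature == "tf" &
                           mc2$context == "me3=1,cts=1"], 0)
})

test_that("log-scale r2 behaves at its limits", {
  x <- 10^rnorm(100)
  expect_equal(correlation_r2(x, x), 1)
  set.seed(88)
  a <- 10^rnorm(10000); b <- 10^rnorm(10000)
  expect_lt(correlation_r2(a, b), 0.01)
  expect_error(correlation_r2(rep(1, 10), x[1:10]), "variance")
})
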