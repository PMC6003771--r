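test_that("branch shift posterior probabilities are counting fractions with flags", {
  trace <- c(rep(list(2L), 7), rep(list(integer(0)), 3))
  pp <- branch_shift_pp(trace, n_branches = 4)
  expect_equal(pp$pp, c(0, 0.7, 0, 0))
  expect_true(pp$pp_ge_0.2[2] && pp$pp_ge_0.5[2] && !pp$pp_ge_0.8[2])
  all_b <- rep(list(3L), 5)
  expect_equal(branch_shift_pp(all_b, n_branches = 3)$pp[3], 1)
  none <- rep(list(integer(0)), 5)
  expect_equal(branch_shift_pp(none, n_branches = 3)$pp, rep(0, 3))
  expect_error(branch_shift_pp(list(), n_branches = 3), "empty")
})

test_that("signal-to-noise decomposes as separation / stationary SD * discount", {
  tr <- simulate_tree(20, 10, seed = 2)
  tbar <- mean(ape::node.depth.edgelength(tr)[1:20])
  # hand evaluation: theta {0, 3}, alpha 2, sigma2 1
  es <- signal_to_noise(list(alpha = 2, sigma2 = 1, theta = c(0, 3)), tr)
  expect_equal(es$eta_phi,
               3 / sqrt(1 / 4) * (1 - exp(-2 * tbar)), tolerance = 1e-12)
  # equal optima: zero effect
  es0 <- signal_to_noise(list(alpha = 2, sigma2 = 1, theta = c(1, 1)), tr)
  expect_equal(es0$eta_phi, 0)
  # stationary SD 1 and full adaptation: eta_phi -> |dtheta|
  es1 <- signal_to_noise(list(alpha = 50, sigma2 = 100, theta = c(0, 1)), tr)
  expect_equal(es1$eta_phi, 1, tolerance = 1e-6)
  # monotone in the minimum separation
  es2 <- signal_to_noise(list(alpha = 2, sigma2 = 1, theta = c(0, 4)), tr)
  expect_gt(es2$eta_phi, es$eta_phi)
  # single regime: explicit undefined result
  s1 <- signal_to_noise(list(alpha = 1, sigma2 = 1, theta = 0.5), tr)
  expect_true(is.na(s1$eta_phi))
  expect_identical(s1$note, "single-regime")
})

test_that("with a constant likelihood the sampler reproduces the shift-count prior", {
  tr <- simulate_tree(20, 100, seed = 8)
  y <- stats::setNames(rep(0, 20), tr$tip.label)
  fit <- run_rjmcmc(y, tr, iterations = 4e5, thin = 50, seed = 99,
                    prior_only = TRUE)
  k <- fit$trace$k
  kmax <- fit$prior$k_max
  expected <- stats::dpois(0:kmax, fit$prior$k_mean)
  expected <- expected / sum(expected)
  obs <- tabulate(k + 1L, nbins = kmax + 1L)
  # pool tail bins with small expected counts for a valid chi-square
  keep <- expected * length(k) >= 5
  cut <- max(which(keep))
  obs2 <- c(obs[1:cut], sum(obs[-(1:cut)]))
  exp2 <- c(expected[1:cut], sum(expected[-(1:cut)]))
  gof <- suppressWarnings(stats::chisq.test(obs2, p = exp2))
  expect_gt(gof$p.value, 0.01)
})

test_that("the sampler flags invalid chain settings", {
  tr <- simulate_tree(10, 10, seed = 1)
  y <- stats::setNames(stats::rnorm(10), tr$tip.label)
  expect_error(run_rjmcmc(y, tr, iterations = 1000, thin = 200, seed = 1),
               "too short")
  expect_error(run_rjmcmc(y, tr, iterations = 1000, thin = 10),
               "seed")
})

test_that("a strongly planted shift is recovered with high PP on or next to its branch", {
  # one shift with eta_phi ~ 10 by construction
  tr <- simulate_tree(50, 100, seed = 501)
  bt <- branch_table(tr)
  # a clade of moderate size: pick the planted branch deterministically
  clade <- gradeshift:::pick_clade(tr, 12)
  e <- bt$edge[bt$child == clade$node]
  p <- regime_painting(tr, e)
  alpha <- 0.05; sigma2 <- 0.004
  dtheta <- 10 * sqrt(sigma2 / (2 * alpha)) /
    (1 - exp(-alpha * 100))             # eta_phi = 10 exactly
  y <- simulate_ou(tr, alpha, sigma2, theta = c(0, dtheta), painting = p,
                   seed = 77)
  neighborhood <- c(e, which(tr$edge[, 2] == tr$edge[e, 1]),
                    which(tr$edge[, 1] == tr$edge[e, 2]))
  argmaxes <- integer(0)
  for (s in 1:2) {
    fit <- run_rjmcmc(y, tr, iterations = 5e4, thin = 25, seed = 600 + s)
    top <- as.integer(names(which.max(fit$pp)))
    argmaxes <- c(argmaxes, top)
    expect_gt(max(fit$pp), 0.8)
    expect_true(top %in% neighborhood)
  }
  # two seeds agree on the argmax branch
  expect_equal(argmaxes[1], argmaxes[2])
})

test_that("single-regime data yield no confident shift calls", {
  tr <- simulate_tree(50, 100, seed = 502)
  y <- simulate_ou(tr, 0.05, 0.004, theta = 0, seed = 21)
  for (s in 1:2) {
    fit <- run_rjmcmc(y, tr, iterations = 2e4, thin = 20, seed = 700 + s)
    expect_lt(max(fit$pp), 0.8)
  }
})

test_that("posterior optima on the modal configuration match GLS under the OU weights", {
  tr <- simulate_tree(40, 100, seed = 503)
  bt <- branch_table(tr)
  clade <- gradeshift:::pick_clade(tr, 10)
  e <- bt$edge[bt$child == clade$node]
  p <- regime_painting(tr, e)
  y <- simulate_ou(tr, 0.05, 0.004, theta = c(0, 1.5), painting = p,
                   seed = 31)
  fit <- run_rjmcmc(y, tr, iterations = 3e4, thin = 30, seed = 41)
  expect_equal(fit$modal$shifts, e)
  # GLS estimate of the optima at the posterior-mean alpha
  W <- ou_design_weights(tr, p, fit$modal$alpha)
  V <- ou_covariance(tr, fit$modal$alpha, fit$modal$sigma2,
                     root = "stationary")
  L <- chol(V)
  Ww <- backsolve(L, W, transpose = TRUE)
  yw <- backsolve(L, y[rownames(W)], transpose = TRUE)
  b <- qr.coef(qr(Ww), yw)
  sig <- vapply(fit$samples$shifts, function(s)
    identical(sort(s), e), logical(1))
  th <- t(vapply(fit$samples$thetas[sig], identity, numeric(2)))
  for (j in 1:2) {
    expect_lt(abs(mean(th[, j]) - b[j]), 2 * stats::sd(th[, j]))
  }
})
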