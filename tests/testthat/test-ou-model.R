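test_that("regime paintings cover every branch and count regimes correctly", {
  tr <- simulate_tree(10, 50, seed = 7)
  p0 <- regime_painting(tr)
  expect_equal(p0$n_regimes, 1L)
  expect_true(all(p0$regime == 1L))
  p2 <- regime_painting(tr, shift_edges = c(3L, 9L))
  expect_equal(p2$n_regimes, 3L)
  expect_equal(length(p2$regime), nrow(tr$edge))
  expect_error(regime_painting(tr, 999L), "out of range")
})

test_that("OU design weights: rows sum to 1, concentrate at large alpha, and match hand integration", {
  tr <- tree_abc()                       # ((A:1,B:1):1,C:2)
  p1 <- regime_painting(tr)
  for (a in c(0.1, 1, 5)) {
    W <- ou_design_weights(tr, p1, a)
    expect_equal(unname(rowSums(W)), rep(1, 3), tolerance = 1e-12)
  }
  # shift on A's terminal branch (cladewise edge 2), alpha = 1, depth 2.
  # Hand integration for tip A: root term e^-2; segment on edge 1 (t 0..1,
  # regime 1): e^-(2-1) - e^-(2-0); segment on edge 2 (t 1..2, regime 2):
  # e^0 - e^-1.
  p2 <- regime_painting(tr, shift_edges = 2L)
  W <- ou_design_weights(tr, p2, alpha = 1)
  expect_equal(W["A", 1], exp(-2) + (exp(-1) - exp(-2)), tolerance = 1e-12)
  expect_equal(W["A", 2], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(W["B", 2], 0)
  expect_equal(W["C", 1], 1)
  # alpha * terminal-branch length = 20: the tip loads almost entirely on
  # its terminal branch's regime
  W20 <- ou_design_weights(tr, p2, alpha = 20)
  expect_lt(W20["A", 1], 1e-6)
})

test_that("OU covariance has the closed-form diagonal and the BM limit", {
  tr <- simulate_tree(6, 10, seed = 2)
  Td <- ape::node.depth.edgelength(tr)[1:6]
  V <- ou_covariance(tr, alpha = 0.5, sigma2 = 2)
  expect_equal(unname(diag(V)), 2 / (2 * 0.5) * (1 - exp(-2 * 0.5 * Td)),
               tolerance = 1e-12)
  Vsmall <- ou_covariance(tr, alpha = 1e-6, sigma2 = 2)
  Vbm <- 2 * ape::vcv(tr)
  expect_lt(max(abs(Vsmall - Vbm)) / max(Vbm), 1e-4)
  expect_error(ou_covariance(tr, -1, 1), "alpha")
  expect_error(ou_covariance(tr, 1, 0), "sigma2")
})

test_that("OU covariance matches a large simulation", {
  tr <- simulate_tree(4, 5, seed = 9)
  alpha <- 0.5; sigma2 <- 2
  p <- regime_painting(tr)
  nsim <- 50000
  set.seed(1)
  sims <- vapply(seq_len(nsim),
                 function(i) simulate_ou(tr, alpha, sigma2, theta = 0),
                 numeric(4))
  V_emp <- stats::cov(t(sims))
  # fixed-root simulation (x0 = theta): compare against the "fixed" form
  V_th <- ou_covariance(tr, alpha, sigma2, root = "fixed")
  # SE of a sample covariance entry: sqrt((Vii Vjj + Vij^2)/nsim) <= 0.013
  # at these parameters; allow 3 SE
  expect_lt(max(abs(V_emp - V_th)), 3 * 0.014)
})

test_that("OU log-likelihood equals brute-force multivariate normal densities", {
  for (s in 1:5) {
    n <- sample(3:6, 1)
    tr <- simulate_tree(n, 10, seed = 600 + s)
    e_shift <- sample(nrow(tr$edge), 1)
    p <- regime_painting(tr, e_shift)
    theta <- stats::rnorm(p$n_regimes)
    alpha <- stats::runif(1, 0.05, 1); sigma2 <- stats::runif(1, 0.2, 2)
    y <- simulate_ou(tr, alpha, sigma2, theta, painting = p, seed = s)
    ll <- ou_loglik(y, tr, p, list(alpha = alpha, sigma2 = sigma2,
                                   theta = theta))
    W <- ou_design_weights(tr, p, alpha)
    V <- ou_covariance(tr, alpha, sigma2, root = "stationary")
    mu <- drop(W %*% theta)
    r <- y[rownames(W)] - mu
    brute <- -0.5 * (n * log(2 * pi) +
                       as.numeric(determinant(V)$modulus) +
                       drop(t(r) %*% solve(V, r)))
    expect_equal(ll, brute, tolerance = 1e-8)
  }
})

test_that("minimal-tree OU likelihood matches the explicit normal density", {
  tr <- read_newick("(A:3,B:3):0;")
  p <- regime_painting(tr)
  y <- c(A = 0.7, B = -0.2)
  alpha <- 0.4; sigma2 <- 1; theta <- 0.1
  ll <- ou_loglik(y, tr, p, list(alpha = alpha, sigma2 = sigma2,
                                 theta = theta))
  # by hand: mean theta at both tips (single optimum, rows sum to 1);
  # stationary variance sigma2/(2 alpha); the shared stationary root draw
  # decays over the patristic distance 6, giving covariance v e^{-6 alpha}
  v <- sigma2 / (2 * alpha)
  Vh <- v * matrix(c(1, exp(-6 * alpha), exp(-6 * alpha), 1), 2)
  r <- y - theta
  brute <- -0.5 * (2 * log(2 * pi) + log(det(Vh)) +
                     drop(t(r) %*% solve(Vh, r)))
  expect_equal(ll, brute, tolerance = 1e-10)
})

test_that("likelihood is invariant under regime relabeling and null shifts", {
  tr <- simulate_tree(12, 40, seed = 33)
  p <- regime_painting(tr, shift_edges = c(4L, 15L))
  theta <- c(0, 1.2, -0.7)
  y <- simulate_ou(tr, 0.1, 0.3, theta, painting = p, seed = 4)
  base <- ou_loglik(y, tr, p, list(alpha = 0.1, sigma2 = 0.3, theta = theta))
  # adding a shift whose optimum equals its parent regime's changes nothing
  extra <- 9L
  stopifnot(!extra %in% p$shift_edges)
  p2 <- regime_painting(tr, sort(c(p$shift_edges, extra)))
  # every new regime inherits the optimum its branches had under the old
  # painting (the new shift keeps its parent regime's optimum)
  theta2 <- vapply(seq_len(p2$n_regimes), function(r) {
    e_r <- which(p2$regime == r)[1]
    theta[p$regime[e_r]]
  }, numeric(1))
  ll2 <- ou_loglik(y, tr, p2, list(alpha = 0.1, sigma2 = 0.3,
                                   theta = theta2))
  expect_equal(ll2, base, tolerance = 1e-10)
  # BM limit: tiny alpha approaches the BM likelihood with the same rate
  p0 <- regime_painting(tr)
  llou <- ou_loglik(y, tr, p0, list(alpha = 1e-8, sigma2 = 0.3,
                                    theta = mean(y), root_mode = "free",
                                    x0 = mean(y)))
  C <- 0.3 * ape::vcv(tr)
  r <- y[tr$tip.label] - mean(y)
  llbm <- -0.5 * (12 * log(2 * pi) + as.numeric(determinant(C)$modulus) +
                    drop(t(r) %*% solve(C, r)))
  expect_equal(llou, llbm, tolerance = 1e-3)
})

test_that("OU covariance stays symmetric PSD across random trees and parameters", {
  for (s in 1:25) {
    tr <- simulate_tree(8, 20, seed = 700 + s)
    a <- stats::runif(1, 0.01, 2); s2 <- stats::runif(1, 0.1, 5)
    for (root in c("fixed", "stationary")) {
      V <- ou_covariance(tr, a, s2, root = root)
      expect_equal(V, t(V), tolerance = 1e-12)
      ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-9 * max(ev))
    }
  }
})
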