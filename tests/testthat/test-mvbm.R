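test_that("BM ancestral states match the 3-taxon closed form and phytools", {
  # ((A:1,B:1):1,C:2): the node above (A,B) has the GLS value
  # (y_A/1 + y_B/1 + y_anc/1)... solved jointly; check the root against the
  # classic weighted-mean formula via independent algebra
  tr <- tree_abc()
  y <- c(A = 1, B = 3, C = -2)
  st <- bm_ancestral_states(y, tr)
  # closed form: node AB given root r: x_AB = (y_A + y_B + r) / 3;
  # root: r = (x_AB / 1 + y_C / 2) / (1 + 1/2); solve the 2x2 system
  A <- matrix(c(1.5, -1, -1 / 3, 1), 2, byrow = TRUE)
  b <- c(y["C"] / 2, (y["A"] + y["B"]) / 3)
  sol <- solve(A, b)                    # (root, node AB)
  expect_equal(unname(st$states), unname(sol), tolerance = 1e-10)

  skip_if_not_installed("phytools")
  tr2 <- simulate_tree(25, 60, seed = 11)
  y2 <- simulate_bm(tr2, 0.02, x0 = 1, seed = 12)
  fa <- phytools::fastAnc(tr2, y2)
  expect_equal(unname(st2 <- bm_ancestral_states(y2, tr2)$states),
               unname(as.numeric(fa)), tolerance = 1e-8)
})

test_that("mvBM reduces to standard BM on constant-rate data", {
  tr <- simulate_tree(50, 100, seed = 13)
  y <- simulate_bm(tr, 0.01, x0 = 0, seed = 14)
  mv <- fit_mvbm(y, tr)
  bm <- bm_ancestral_states(y, tr)
  expect_true(mv$converged)
  z <- abs(mv$states - bm$states) / bm$se
  expect_gte(mean(z < 2), 0.95)
  expect_lt(stats::sd(mv$multipliers), 0.5)
  expect_equal(mean(mv$multipliers), 1, tolerance = 1e-10)
})

test_that("mvBM is invariant to trait shifts and branch-length rescaling", {
  tr <- simulate_tree(20, 50, seed = 15)
  y <- simulate_bm(tr, 0.05, x0 = 0, seed = 16)
  mv1 <- fit_mvbm(y, tr)
  mv2 <- fit_mvbm(y + 7, tr)
  expect_equal(mv2$states, mv1$states + 7, tolerance = 1e-8)
  expect_equal(mv2$multipliers, mv1$multipliers, tolerance = 1e-8)
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
  mv3 <- fit_mvbm(y, tr2)
  expect_equal(mv3$states, mv1$states, tolerance = 1e-8)
})

test_that("a branch evolving 25x faster carries the largest average multiplier", {
  tr <- simulate_tree(40, 100, seed = 17)
  n <- ape::Ntip(tr)
  e <- which.max(tr$edge.length * (tr$edge[, 2] <= n))  # longest terminal
  fast <- tr; fast$edge.length[e] <- fast$edge.length[e] * 25
  M <- vapply(1:5, function(s)
    fit_mvbm(simulate_bm(fast, 0.01, x0 = 0, seed = s), tr)$multipliers,
    numeric(nrow(tr$edge)))
  expect_equal(unname(which.max(rowMeans(M))), e)
  # per-replicate, the planted branch ranks highly in most replicates (the
  # realized change on a single branch is a chi-square(1) draw, so argmax
  # recovery in every replicate is not statistically attainable)
  ranks <- apply(-M, 2, function(m) rank(m)[e])
  expect_gte(sum(ranks <= 10), 3)
})

test_that("neutral change ratios are calibrated on self-consistent data", {
  tr <- simulate_tree(30, 100, seed = 19)
  gt <- stats::setNames(stats::runif(30, 5, 15), tr$tip.label)
  tg <- rescale_to_generations(tr, gt)
  rate <- 1e-7
  y <- simulate_bm(tg, rate, x0 = 0, seed = 20)
  nr <- neutral_change_ratio(y, tg, rate, reps = 100, seed = 21)
  expect_gte(mean(nr$ratio), 0.8)
  expect_lte(mean(nr$ratio), 1.2)
  expect_true(all(nr$ratio >= 0))
  expect_equal(attr(nr, "reps"), 100)
  # data simulated 5x faster than the null: ratios shift up accordingly
  y5 <- simulate_bm(tg, 5 * rate, x0 = 0, seed = 22)
  nr5 <- neutral_change_ratio(y5, tg, rate, reps = 100, seed = 21)
  expect_gt(mean(nr5$ratio), mean(nr$ratio) * 1.5)
})

test_that("raw simulated changes match the half-normal closed form", {
  # single branch of t generations at rate s: E|change| = sqrt(s t) sqrt(2/pi)
  tr <- read_newick("(A:1000,B:1000):0;", units = "generations")
  attr(tr, "units") <- "generations"
  rate <- 4e-4
  y <- c(A = 0.1, B = -0.2)
  nr <- neutral_change_ratio(y, tr, rate, reps = 4000, seed = 23,
                             observed_method = "bm", reestimate = FALSE)
  expected <- sqrt(rate * 1000) * sqrt(2 / pi)
  # SE of the mean of 4000 half-normal draws
  se <- sqrt(rate * 1000 * (1 - 2 / pi) / 4000)
  expect_true(all(abs(nr$expected - expected) < 3 * se))
})

test_that("neutral_change_ratio enforces its preconditions", {
  tr <- simulate_tree(10, 10, seed = 25)
  y <- stats::setNames(stats::rnorm(10), tr$tip.label)
  expect_error(neutral_change_ratio(y, tr, 1e-7, seed = 1), "generations")
  tg <- rescale_to_generations(
    tr, stats::setNames(rep(10, 10), tr$tip.label))
  expect_error(neutral_change_ratio(y, tg, -1, seed = 1), "per_gen_rate")
  expect_error(neutral_change_ratio(y, tg, 1e-7, reps = 1, seed = 1),
               "reps")
  expect_error(neutral_change_ratio(y, tg, 1e-7), "seed")
})
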