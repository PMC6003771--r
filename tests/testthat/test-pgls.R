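test_that("PGLS with lambda = 0 equals OLS and lambda = 1 equals PIC regression", {
  fx <- study_fixture()
  f0 <- fit_pgls(lateral ~ medial, fx$traits, fx$tree, lambda = 0)
  ols <- stats::coef(stats::lm(lateral ~ medial, fx$traits))
  expect_equal(unname(f0$coefficients), unname(ols), tolerance = 1e-10)

  f1 <- fit_pgls(lateral ~ medial, fx$traits, fx$tree, lambda = 1)
  px <- ape::pic(fx$traits[fx$tree$tip.label, "medial"], fx$tree)
  py <- ape::pic(fx$traits[fx$tree$tip.label, "lateral"], fx$tree)
  b_pic <- sum(px * py) / sum(px^2)
  expect_equal(unname(f1$coefficients[2]), b_pic, tolerance = 1e-8)
})

test_that("ML lambda and coefficients agree with nlme::gls(corPagel)", {
  skip_if_not_installed("nlme")
  # moderate phylogenetic signal so the ML optimum is interior (corPagel is
  # unbounded above 1, our lambda is a covariance weight in [0, 1])
  fx <- make_study_fixture(fixture_spec(lambda = 0.6, resid_sd = 0.25,
                                        seed = 102))
  fit <- fit_pgls(lateral ~ medial, fx$traits, fx$tree)
  dd <- fx$traits[fx$tree$tip.label, ]
  dd$species <- rownames(dd)
  ref <- nlme::gls(lateral ~ medial, data = dd,
                   correlation = ape::corPagel(0.8, phy = fx$tree,
                                               form = ~species),
                   method = "ML")
  expect_equal(fit$lambda, as.numeric(ref$modelStruct$corStruct[[1]]),
               tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-4)
})

test_that("PGLS output contract: CIs bracket estimates, residuals are y - Xb", {
  fx <- study_fixture()
  fit <- fit_pgls(lateral ~ medial, fx$traits, fx$tree)
  expect_true(all(fit$ci[, "lower"] <= fit$coefficients))
  expect_true(all(fit$ci[, "upper"] >= fit$coefficients))
  expect_gte(fit$F, 0)
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  y <- fx$traits[names(fit$residuals), "lateral"]
  pred <- fit$coefficients[1] + fit$coefficients[2] *
    fx$traits[names(fit$residuals), "medial"]
  expect_equal(unname(fit$residuals), y - pred, tolerance = 1e-10)
})

test_that("a perfect fit is flagged degenerate and collinearity is named", {
  fx <- study_fixture()
  d <- fx$traits
  d$copy <- 2 + 3 * d$medial
  fit <- fit_pgls(copy ~ medial, d, fx$tree)
  expect_true(fit$degenerate)
  expect_identical(fit$F, Inf)
  d$dup <- d$medial
  expect_error(fit_pgls(lateral ~ medial + dup, d, fx$tree), "collinear")
})

test_that("the lambda profile optimum beats a fine grid scan", {
  fx <- study_fixture()
  fit <- fit_pgls(lateral ~ medial, fx$traits, fx$tree)
  y <- fx$traits[fx$tree$tip.label, "lateral"]
  X <- cbind(1, fx$traits[fx$tree$tip.label, "medial"])
  C <- ape::vcv(fx$tree)
  prof <- gradeshift:::profile_loglik_lambda(y, X, C)
  grid_best <- max(vapply(seq(0, 1, by = 0.001), prof, numeric(1)))
  expect_gte(fit$loglik + 1e-9, grid_best)
})

test_that("relative size returns residuals, antilog ratios, and grade recovery", {
  fx <- study_fixture()
  rs <- relative_size("lateral", "medial", fx$traits, fx$tree)
  expect_equal(rs$ratio, 10^(rs$observed - rs$predicted))
  expect_equal(rs$ratio, 10^rs$residual)  # on-the-line species: resid 0 <-> ratio 1
  # planted +0.5 dex clade recovered within [0.35, 0.65]
  hi <- mean(rs[fx$truth$high_clade, "residual"])
  expect_gte(hi, 0.35); expect_lte(hi, 0.65)
  # slope (hence residual differences) invariant to shifting the predictor
  d2 <- fx$traits
  d2$medial <- d2$medial + 5
  rs2 <- relative_size("lateral", "medial", d2, fx$tree)
  f1 <- attr(rs, "fit"); f2 <- attr(rs2, "fit")
  expect_equal(unname(f1$coefficients[2]), unname(f2$coefficients[2]),
               tolerance = 1e-10)
  expect_equal(rs$residual, rs2$residual, tolerance = 1e-8)
})

test_that("pancova nested-RSS F equals the independent Wald F", {
  fx <- study_fixture()
  pa <- pancova(lateral ~ medial, fx$traits, fx$tree, fx$truth$grade)
  expect_equal(pa$F, pa$F_wald, tolerance = 1e-8)
  expect_equal(pa$df[1], 2L)
  expect_lt(pa$p.value, 0.001)      # planted grades are detected
  # treatment-vs-control nesting (pooled planted grades under the null)
  g0 <- ifelse(fx$truth$grade == "baseline", "baseline", "planted")
  names(g0) <- names(fx$truth$grade)
  pa2 <- pancova(lateral ~ medial, fx$traits, fx$tree, fx$truth$grade,
                 null_groups = g0)
  expect_equal(pa2$df[1], 1L)
  expect_equal(pa2$F, pa2$F_wald, tolerance = 1e-8)
  # slope test runs and does not reject (slopes are shared by construction)
  pa3 <- pancova(lateral ~ medial, fx$traits, fx$tree, fx$truth$grade,
                 test = "slopes")
  expect_gt(pa3$p.value, 0.01)
})

test_that("pancova rejects degenerate groupings", {
  fx <- study_fixture()
  one <- stats::setNames(rep("all", nrow(fx$traits)), rownames(fx$traits))
  expect_error(pancova(lateral ~ medial, fx$traits, fx$tree, one),
               "at least 2 groups")
  tiny <- fx$truth$grade
  tiny[[1]] <- "solo"                    # a 1-species group
  expect_error(pancova(lateral ~ medial, fx$traits, fx$tree, tiny,
                       test = "slopes"), "at least 2 species")
  expect_error(pancova(lateral ~ medial, fx$traits, fx$tree,
                       fx$truth$grade, null_groups = fx$truth$grade),
               "identical")
})
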