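# ---- GLS core -------------------------------------------------------------

# Whitened GLS fit for a fixed covariance matrix V (species order of y).
# Returns coefficients, RSS in the whitened space, and the ML log-likelihood
# of the Gaussian model y ~ N(Xb, sigma2 * V) profiled over b and sigma2.
gls_fit_fixed <- function(y, X, V) {
  n <- length(y)
  L <- chol(V)                       # V = t(L) %*% L ... chol() gives upper
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) {
    bad <- colnames(Xw)[qx$pivot[(qx$rank + 1):ncol(Xw)]]
    stop("singular design in GLS; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  b <- qr.coef(qx, yw)
  res_w <- yw - Xw %*% b
  rss <- sum(res_w^2)
  logdetV <- 2 * sum(log(diag(L)))
  sigma2_ml <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  list(coef = b, rss = rss, loglik = loglik, qr = qx, L = L,
       yw = yw, Xw = Xw, logdetV = logdetV)
}

# Profile log-likelihood of lambda for the model y ~ N(Xb, sigma2 V(lambda)).
profile_loglik_lambda <- function(y, X, C) {
  d <- diag(C)
  function(lambda) {
    V <- lambda * C
    diag(V) <- d
    gls_fit_fixed(y, X, V)$loglik
  }
}

# ML estimate of lambda: grid scan on [0, 1] followed by Brent refinement in
# the bracketing interval, so the reported value is a global optimum of the
# grid-refine scheme.
optimize_lambda <- function(y, X, C, grid_n = 1001L) {
  ll <- profile_loglik_lambda(y, X, C)
  grid <- seq(0, 1, length.out = grid_n)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  if (lo == hi) return(list(lambda = grid[i], loglik = vals[i]))
  opt <- stats::optimize(ll, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  if (opt$objective >= vals[i])
    list(lambda = opt$maximum, loglik = opt$objective)
  else
    list(lambda = grid[i], loglik = vals[i])
}

# ---- PGLS -----------------------------------------------------------------

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X b + e` with `e ~ N(0, sigma2 * V(lambda))`, where `V(lambda)`
#' is the shared-path-length matrix with off-diagonals scaled by lambda
#' ([phylo_covariance()]). Lambda is either fixed or estimated by maximum
#' likelihood (grid scan plus Brent refinement of the profile likelihood).
#' The overall regression F compares the fitted model with the intercept-only
#' GLS model, both whitened under the fuller model's fitted lambda, so the F
#' statistic is always the nested-RSS statistic of a single covariance
#' structure. Confidence intervals are phylogenetic GLS intervals: standard
#' errors from `sigma2_hat (X' V^-1 X)^-1` with t quantiles on `n - p` df.
#'
#' @param formula Model formula; variables are looked up in `data`.
#' @param data Data frame with species row names (already log-transformed as
#'   appropriate).
#' @param tree A `"phylo"` tree containing all species of `data`.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param grid_n Number of grid points for the lambda scan (default 1001).
#' @param ci_level Confidence level for coefficient intervals.
#' @return An object of class `"pgls_fit"`: coefficients, standard errors and
#'   confidence intervals, `lambda`, log-likelihood, overall `F` with its df
#'   and p value, `sigma2` (unbiased GLS residual variance), species-indexed
#'   GLS residuals (`y - X b`, response scale) and fitted values.
#' @export
fit_pgls <- function(formula, data, tree, lambda = "ML", grid_n = 1001L,
                     ci_level = 0.95) {
  md <- match_tree_traits(tree, data)
  tree <- md$tree
  mf <- stats::model.frame(formula, md$traits, na.action = stats::na.omit)
  keep <- rownames(mf)
  if (length(keep) < nrow(md$traits)) {
    tree <- as_gradeshift_tree(ape::keep.tip(tree, keep),
                               units = attr(tree, "units"))
    mf <- mf[tree$tip.label, , drop = FALSE]
  }
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (n < p + 2) stop("need at least p + 2 species (n = ", n, ", p = ", p, ")")
  C <- ape::vcv(tree)[rownames(mf), rownames(mf)]

  if (identical(lambda, "ML")) {
    opt <- optimize_lambda(y, X, C, grid_n = grid_n)
    lam <- opt$lambda
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("`lambda` must be \"ML\" or a value in [0, 1]")
    lam <- lambda
  }
  V <- lam * C; diag(V) <- diag(C)
  fit <- gls_fit_fixed(y, X, V)

  # Overall F against the intercept-only model under the same V.
  has_icpt <- "(Intercept)" %in% colnames(X)
  X0 <- if (has_icpt) X[, "(Intercept)", drop = FALSE] else
    matrix(0, n, 0)
  df1 <- p - ncol(X0)
  df2 <- n - p
  degenerate <- FALSE
  if (df1 > 0) {
    rss0 <- if (ncol(X0)) gls_fit_fixed(y, X0, V)$rss else sum(fit$yw^2)
    if (fit$rss < 1e-12 * max(rss0, 1)) {
      degenerate <- TRUE
      Fstat <- Inf
      pval <- 0
    } else {
      Fstat <- ((rss0 - fit$rss) / df1) / (fit$rss / df2)
      pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    }
  } else {
    Fstat <- NA_real_; pval <- NA_real_
  }

  sigma2 <- fit$rss / df2
  XtX_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df2)
  b <- drop(fit$coef)
  ci <- cbind(lower = b - tcrit * se, upper = b + tcrit * se)
  fitted <- drop(X %*% fit$coef)
  resid <- y - fitted
  names(resid) <- names(fitted) <- rownames(mf)

  structure(list(
    coefficients = b, se = se, ci = ci, lambda = lam,
    lambda_mode = if (identical(lambda, "ML")) "ML" else "fixed",
    loglik = fit$loglik, F = Fstat, df = c(df1, df2), p.value = pval,
    sigma2 = sigma2, residuals = resid, fitted = fitted,
    degenerate = degenerate, n = n, formula = formula, tree = tree,
    V = V, X = X, y = y
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, lambda = %.4f (%s)\n", x$n, x$lambda, x$lambda_mode))
  tab <- cbind(Estimate = x$coefficients, SE = x$se, x$ci)
  print(round(tab, 4))
  if (x$degenerate) {
    cat("Perfect fit: residuals are numerically zero (F degenerate).\n")
  } else if (!is.na(x$F)) {
    cat(sprintf("F = %.3f on %d, %d df; p = %.3g\n",
                x$F, x$df[1], x$df[2], x$p.value))
  }
  invisible(x)
}

#' Relative size of one structure against another
#'
#' GLS residuals of the phylogenetic regression of one log-volume on another
#' — e.g. the lateral-on-medial cerebellum residual used as the
#' "lateral-medial reorganization" measure — together with observed/predicted
#' ratios on the raw (antilog) scale.
#'
#' @param numerator,denominator Column names in `data` (log-scale volumes).
#' @param data Data frame with species row names.
#' @param tree A `"phylo"` tree.
#' @param lambda Passed to [fit_pgls()].
#' @param log_base Base used for the stored log volumes (for the antilog
#'   ratio), default 10.
#' @return Data frame (one row per species): `observed`, `predicted`,
#'   `residual` (log scale) and `ratio` (`base^(obs - pred)`), with the
#'   underlying `"pgls_fit"` attached as attribute `fit`.
#' @export
relative_size <- function(numerator, denominator, data, tree,
                          lambda = "ML", log_base = 10) {
  fml <- stats::as.formula(paste0("`", numerator, "` ~ `", denominator, "`"))
  fit <- fit_pgls(fml, data, tree, lambda = lambda)
  out <- data.frame(
    species = names(fit$residuals),
    observed = fit$y,
    predicted = fit$fitted,
    residual = fit$residuals,
    ratio = log_base^(fit$y - fit$fitted),
    row.names = names(fit$residuals),
    stringsAsFactors = FALSE
  )
  attr(out, "fit") <- fit
  out
}

# ---- phylogenetic ANCOVA --------------------------------------------------

# Build the grade design: base columns from `formula`, plus group indicator
# columns, plus (for the slope test) covariate-by-group interactions, for
# every non-control group. The slope test keeps the indicators in both
# nested designs so that intercept differences cannot masquerade as slope
# differences.
grade_design <- function(formula, data, groups, control,
                         intercepts = TRUE, slopes = FALSE) {
  X <- stats::model.matrix(formula, data)
  lev <- setdiff(levels(groups), control)
  add <- NULL
  for (g in lev) {
    ind <- as.numeric(groups == g)
    if (intercepts) {
      add <- cbind(add, ind)
      colnames(add)[ncol(add)] <- paste0("grade_", g)
    }
    if (slopes) {
      covars <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
      if (ncol(covars) == 0) stop("slope test requires a covariate in the model")
      inter <- covars * ind
      colnames(inter) <- paste0("slope_", g, ":", colnames(covars))
      add <- cbind(add, inter)
    }
  }
  cbind(X, add)
}

as_group_factor <- function(groups, species) {
  if (is.null(names(groups)))
    stop("`groups` must be a named vector (names are species)")
  g <- groups[species]
  if (anyNA(g)) stop("species without a group assignment: ",
                     paste(species[is.na(g)], collapse = ", "))
  factor(unname(g))
}

#' Phylogenetic analysis of covariance (grade and slope tests)
#'
#' Tests whether clade-specific intercepts (grades) or slopes improve a
#' phylogenetic regression. Group membership enters the GLS design as
#' indicator columns; the test compares the null design (no groups, or a
#' coarser grouping) against the alternative design by the nested-model F
#' statistic `F = [(RSS0 - RSS1)/dp] / [RSS1/(n - p1)]`, with both residual
#' sums of squares computed in the space whitened by `V(lambda)`. Lambda is
#' estimated by maximum likelihood on the fuller (alternative) model and the
#' same covariance is used for both fits. An independent Wald-test code path
#' (coefficients of the extra design directions, with their GLS covariance)
#' is computed alongside and returned as `F_wald`; the two agree
#' algebraically and serve as a mutual numerical check.
#'
#' "Treatment groups versus a control group" allocations are expressed by
#' `null_groups`: e.g. testing group A against pooled (A, B) holding a
#' control grade fixed uses `groups` with levels `{A, B, control}` and
#' `null_groups` with `{AB, control}`.
#'
#' @param formula Base regression (e.g. `lateral ~ medial`).
#' @param data Data frame with species row names.
#' @param tree A `"phylo"` tree.
#' @param groups Named vector mapping species to group labels (alternative
#'   model). Every species must be assigned.
#' @param null_groups Optional named vector for the null model's coarser
#'   grouping; default is a single grade (plain regression).
#' @param test `"intercepts"` (grade shifts at common slope) or `"slopes"`
#'   (slope heterogeneity, tested with group intercepts present in both
#'   nested models so the equality-of-slopes assumption is assessed on top
#'   of any grade structure).
#' @param control Label of the reference group whose species keep the base
#'   intercept; default the largest group.
#' @param lambda `"ML"` (estimated on the alternative model) or fixed value.
#' @return Object of class `"pancova"`: `F`, `df` (numerator, denominator),
#'   `p.value`, `F_wald`, `lambda`, and the alternative-model coefficients.
#' @export
pancova <- function(formula, data, tree, groups, null_groups = NULL,
                    test = c("intercepts", "slopes"), control = NULL,
                    lambda = "ML") {
  test <- match.arg(test)
  md <- match_tree_traits(tree, data)
  tree <- md$tree
  mf <- stats::model.frame(formula, md$traits, na.action = stats::na.omit)
  species <- rownames(mf)
  y <- stats::model.response(mf)
  g1 <- as_group_factor(groups, species)
  if (nlevels(g1) < 2) stop("grouping must contain at least 2 groups")
  if (test == "slopes" && any(table(g1) < 2))
    stop("each group needs at least 2 species for a slope test")
  if (is.null(control)) control <- names(which.max(table(g1)))
  if (!control %in% levels(g1)) stop("control group '", control, "' not found")

  if (test == "intercepts") {
    X1 <- grade_design(formula, mf, g1, control)
    if (is.null(null_groups)) {
      X0 <- stats::model.matrix(formula, mf)
    } else {
      g0 <- as_group_factor(null_groups, species)
      control0 <- as.character(g0[which(g1 == control)[1]])
      X0 <- grade_design(formula, mf, g0, control0)
    }
  } else {
    # slopes: null keeps group intercepts, alternative adds interactions
    if (!is.null(null_groups))
      stop("`null_groups` is only meaningful for the intercepts test")
    X0 <- grade_design(formula, mf, g1, control)
    X1 <- grade_design(formula, mf, g1, control, slopes = TRUE)
  }
  p1 <- ncol(X1); p0 <- ncol(X0); n <- length(y)
  # nesting check: columns of X0 must lie in the span of X1
  proj <- X0 - X1 %*% qr.coef(qr(X1), X0)
  proj[is.na(proj)] <- 0
  if (max(abs(proj)) > 1e-8 * max(abs(X0)))
    stop("null model is not nested in the alternative model")
  if (p1 == p0) stop("null and alternative designs are identical")

  C <- ape::vcv(tree)[species, species]
  if (identical(lambda, "ML")) {
    lam <- optimize_lambda(y, X1, C)$lambda
  } else lam <- lambda
  V <- lam * C; diag(V) <- diag(C)

  fit1 <- gls_fit_fixed(y, X1, V)
  fit0 <- gls_fit_fixed(y, X0, V)
  dp <- p1 - p0
  df2 <- n - p1
  Fstat <- ((fit0$rss - fit1$rss) / dp) / (fit1$rss / df2)
  pval <- stats::pf(Fstat, dp, df2, lower.tail = FALSE)

  # Independent Wald path: orthogonalize the extra directions against the
  # null design in the whitened space and test their coefficients.
  L <- fit1$L
  X0w <- backsolve(L, X0, transpose = TRUE)
  X1w <- fit1$Xw
  Zw <- X1w - X0w %*% qr.coef(qr(X0w), X1w)
  Zw[is.na(Zw)] <- 0
  keep <- sqrt(colSums(Zw^2)) > 1e-7 * max(sqrt(colSums(X1w^2)))
  Zw <- Zw[, keep, drop = FALSE]
  qz <- qr(Zw)
  Zw <- Zw[, qz$pivot[seq_len(qz$rank)], drop = FALSE]
  Xf <- cbind(X0w, Zw)
  qf <- qr(Xf)
  bf <- qr.coef(qf, fit1$yw)
  covb <- chol2inv(qr.R(qf)) * (fit1$rss / df2)
  iz <- (ncol(X0w) + 1):ncol(Xf)
  bz <- bf[iz]
  F_wald <- drop(t(bz) %*% solve(covb[iz, iz, drop = FALSE], bz)) / length(iz)

  structure(list(
    F = Fstat, df = c(dp, df2), p.value = pval, F_wald = F_wald,
    lambda = lam, test = test, control = control,
    coefficients = drop(fit1$coef), n = n,
    rss = c(null = fit0$rss, alt = fit1$rss)
  ), class = "pancova")
}

#' @export
print.pancova <- function(x, ...) {
  cat(sprintf("Phylogenetic ANCOVA (%s test, control = '%s')\n",
              x$test, x$control))
  cat(sprintf("F = %.3f on %d, %d df; p = %.4g (lambda = %.3f)\n",
              x$F, x$df[1], x$df[2], x$p.value, x$lambda))
  invisible(x)
}
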