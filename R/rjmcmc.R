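# Bayesian reversible-jump sampler over regime-shift configurations of a
# multi-regime OU model. The trans-dimensional state is (set of shift
# branches, one optimum per regime, root optimum, alpha, sigma2) with a
# conditional Poisson prior on the number of shifts (0 .. n_tips/2) and a
# uniform prior over shift placements given the count.

#' Run the reversible-jump OU shift sampler
#'
#' Metropolis-Hastings with move mix {birth of a shift on a uniformly chosen
#' free branch, death of a uniformly chosen shift, relocation of a shift,
#' update of one optimum, update of alpha, update of sigma2}. Birth draws the
#' new optimum from a Gaussian centred on the parent regime's optimum; the
#' birth/death acceptance ratio carries the conditional-Poisson prior ratio
#' and the proposal-vs-prior density ratio of the drawn optimum (the
#' reversible-jump Jacobian is 1 for this direct parameter proposal). States
#' are retained every `thin` iterations after discarding the first
#' `burnin` fraction. The cached log-likelihood is recomputed from scratch
#' every 10^4 iterations and the run aborts on disagreement.
#'
#' @param y Named numeric vector of tip values.
#' @param tree A `"phylo"` tree.
#' @param iterations Total iterations (must be at least `10 * thin`).
#' @param thin Keep every `thin`-th state (default 100).
#' @param seed Mandatory RNG seed.
#' @param prior List overriding prior settings: `k_mean` (conditional
#'   Poisson mean, default `max(1, n_tips/20)`), `k_max` (default
#'   `floor(n_tips/2)`), `theta_mean`, `theta_sd`, `log_alpha_mean`,
#'   `log_alpha_sd`, `log_sigma2_mean`, `log_sigma2_sd`.
#' @param proposal List overriding proposal scales: `theta_sd`, `birth_sd`,
#'   `log_alpha_sd`, `log_sigma2_sd`.
#' @param move_probs Probabilities of {birth, death, relocate, theta, alpha,
#'   sigma2} moves.
#' @param burnin Fraction of the chain discarded (default 0.2).
#' @param prior_only If `TRUE` the likelihood is held constant, so the chain
#'   samples the prior — used for prior-predictive and detailed-balance
#'   checks.
#' @param root_mode Root-state mode for the OU mean/covariance
#'   (`"stationary"` default).
#' @return Object of class `"rjou_fit"`: per-branch shift posterior
#'   probabilities (`pp`), retained samples (`samples$shifts`,
#'   `samples$thetas`, scalar traces in `trace`), modal-configuration
#'   posterior means, acceptance rates, and the inputs needed to interpret
#'   branch ids ([branch_table()]).
#' @export
run_rjmcmc <- function(y, tree, iterations, thin = 100L, seed,
                       prior = list(), proposal = list(),
                       move_probs = c(birth = 0.15, death = 0.15,
                                      relocate = 0.10, theta = 0.30,
                                      alpha = 0.15, sigma2 = 0.15),
                       burnin = 0.2, prior_only = FALSE,
                       root_mode = "stationary") {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (!identical(root_mode, "stationary"))
    stop("the sampler is parameterized with a stationary root; ",
         "use ou_loglik() directly for the free-root variant")
  if (iterations < 10 * thin)
    stop("chain too short: `iterations` must be at least 10 * thin")
  tree <- as_gradeshift_tree(tree)
  if (!all(tree$tip.label %in% names(y)))
    stop("`y` must be named and cover every tip")
  y <- y[tree$tip.label]
  set.seed(as.integer(seed))

  n <- ape::Ntip(tree)
  ne <- nrow(tree$edge)
  seg <- tip_path_segments(tree)
  seg_tip <- seg$tip; seg_edge <- seg$edge
  seg_a <- seg$depth - seg$t1        # time from segment end to the tip
  seg_b <- seg$depth - seg$t0
  depths <- node_depths(tree)
  tipd <- depths[seq_len(n)]
  parent_edge <- match(tree$edge[, 1], tree$edge[, 2])
  S <- ape::vcv(tree)
  D <- outer(tipd, tipd, "+") - 2 * S

  # ---- priors -------------------------------------------------------------
  td <- mean(tipd)
  s2hat <- {                         # quick BM rate for prior centring
    Cb <- S; L <- chol(Cb)
    yw <- backsolve(L, y, transpose = TRUE)
    ow <- backsolve(L, rep(1, n), transpose = TRUE)
    ahat <- sum(ow * yw) / sum(ow^2)
    max(sum((yw - ahat * ow)^2) / n, 1e-12)   # floor guards constant y
  }
  pr <- modifyList(list(
    k_mean = max(1, n / 20), k_max = floor(n / 2),
    theta_mean = mean(y), theta_sd = 2 * max(stats::sd(y), 1e-3),
    log_alpha_mean = log(log(2) / (td / 4)), log_alpha_sd = 1.5,
    log_sigma2_mean = log(s2hat), log_sigma2_sd = 2
  ), prior)
  ks <- 0:pr$k_max
  log_pk <- stats::dpois(ks, pr$k_mean, log = TRUE)
  log_pk <- log_pk - log(sum(exp(log_pk - max(log_pk))) ) - max(log_pk)
  qp <- modifyList(list(
    theta_sd = 0.25 * max(stats::sd(y), 1e-3),
    birth_sd = 0.5 * max(stats::sd(y), 1e-3),
    log_alpha_sd = 0.4, log_sigma2_sd = 0.4
  ), proposal)
  move_probs <- move_probs / sum(move_probs)

  # ---- cached likelihood machinery ---------------------------------------
  # theta_edge: optimum governing each branch, derived from the shift set.
  theta_edge_of <- function(shifts, thetas, root_theta) {
    te <- numeric(ne)
    for (e in seq_len(ne)) {
      j <- match(e, shifts)
      te[e] <- if (!is.na(j)) thetas[j]
      else if (is.na(parent_edge[e])) root_theta
      else te[parent_edge[e]]
    }
    te
  }
  chol_cache <- function(alpha) {
    Cu <- exp(-alpha * D) / (2 * alpha)       # stationary-root, unit sigma2
    if (root_mode != "stationary") Cu <- Cu * (1 - exp(-2 * alpha * S))
    L <- tryCatch(chol(Cu), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    list(L = L, logdet = 2 * sum(log(diag(L))), alpha = alpha,
         w = exp(-alpha * seg_a) - exp(-alpha * seg_b),
         root_w = exp(-alpha * tipd))
  }
  mean_of <- function(cache, te, root_theta) {
    as.vector(rowsum(cache$w * te[seg_edge], seg_tip)) +
      cache$root_w * root_theta
  }
  quad_of <- function(cache, mu) {
    z <- backsolve(cache$L, y - mu, transpose = TRUE)
    sum(z^2)
  }
  ll_of <- function(cache, quad, sigma2) {
    if (prior_only) return(0)
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + cache$logdet + quad / sigma2)
  }
  if (prior_only) {   # likelihood held constant: skip all linear algebra
    chol_cache <- function(alpha) list(alpha = alpha)
    mean_of <- function(cache, te, root_theta) 0
    quad_of <- function(cache, mu) 0
  }
  log_prior_full <- function(st) {
    k <- length(st$shifts)
    log_pk[k + 1] - lchoose(ne, k) +
      sum(stats::dnorm(c(st$root_theta, st$thetas), pr$theta_mean,
                       pr$theta_sd, log = TRUE)) +
      stats::dnorm(log(st$alpha), pr$log_alpha_mean, pr$log_alpha_sd,
                   log = TRUE) +
      stats::dnorm(log(st$sigma2), pr$log_sigma2_mean, pr$log_sigma2_sd,
                   log = TRUE)
  }

  # ---- initial state ------------------------------------------------------
  st <- list(shifts = integer(0), thetas = numeric(0),
             root_theta = mean(y), alpha = exp(pr$log_alpha_mean),
             sigma2 = s2hat)
  cache <- chol_cache(st$alpha)
  if (is.null(cache)) stop("initial covariance not positive definite")
  te <- theta_edge_of(st$shifts, st$thetas, st$root_theta)
  quad <- quad_of(cache, mean_of(cache, te, st$root_theta))
  ll <- ll_of(cache, quad, st$sigma2)

  # ---- bookkeeping --------------------------------------------------------
  keep_from <- ceiling(burnin * iterations)
  shift_counts <- numeric(ne)
  kept <- 0L
  samples <- list(shifts = list(), thetas = list())
  tr_n <- floor((iterations - keep_from) / thin) + 1L
  trace <- data.frame(iter = integer(tr_n), k = integer(tr_n),
                      alpha = numeric(tr_n), sigma2 = numeric(tr_n),
                      root_theta = numeric(tr_n), loglik = numeric(tr_n),
                      logprior = numeric(tr_n))
  acc <- att <- stats::setNames(numeric(6), names(move_probs))
  move_names <- names(move_probs)

  for (it in seq_len(iterations)) {
    mv <- sample.int(6L, 1L, prob = move_probs)
    mname <- move_names[mv]
    att[mv] <- att[mv] + 1
    k <- length(st$shifts)

    if (mname == "birth") {
      if (k < pr$k_max && k < ne) {
        free <- setdiff(seq_len(ne), st$shifts)
        e <- free[sample.int(length(free), 1L)]
        th_par <- te[e]
        th_new <- stats::rnorm(1, th_par, qp$birth_sd)
        ns <- c(st$shifts, e); nt <- c(st$thetas, th_new)
        te2 <- theta_edge_of(ns, nt, st$root_theta)
        quad2 <- quad_of(cache, mean_of(cache, te2, st$root_theta))
        lr <- ll_of(cache, quad2, st$sigma2) - ll +
          log_pk[k + 2] - log_pk[k + 1] +
          stats::dnorm(th_new, pr$theta_mean, pr$theta_sd, log = TRUE) -
          stats::dnorm(th_new, th_par, qp$birth_sd, log = TRUE) +
          log(move_probs["death"] / move_probs["birth"])
        if (log(stats::runif(1)) < lr) {
          st$shifts <- ns; st$thetas <- nt; te <- te2; quad <- quad2
          ll <- ll_of(cache, quad, st$sigma2); acc[mv] <- acc[mv] + 1
        }
      }
    } else if (mname == "death") {
      if (k > 0) {
        j <- sample.int(k, 1L)
        e <- st$shifts[j]; th_rem <- st$thetas[j]
        ns <- st$shifts[-j]; nt <- st$thetas[-j]
        te2 <- theta_edge_of(ns, nt, st$root_theta)
        th_par <- te2[e]                 # optimum the branch reverts to
        quad2 <- quad_of(cache, mean_of(cache, te2, st$root_theta))
        lr <- ll_of(cache, quad2, st$sigma2) - ll +
          log_pk[k] - log_pk[k + 1] +
          stats::dnorm(th_rem, th_par, qp$birth_sd, log = TRUE) -
          stats::dnorm(th_rem, pr$theta_mean, pr$theta_sd, log = TRUE) +
          log(move_probs["birth"] / move_probs["death"])
        if (log(stats::runif(1)) < lr) {
          st$shifts <- ns; st$thetas <- nt; te <- te2; quad <- quad2
          ll <- ll_of(cache, quad, st$sigma2); acc[mv] <- acc[mv] + 1
        }
      }
    } else if (mname == "relocate") {
      if (k > 0 && k < ne) {
        j <- sample.int(k, 1L)
        free <- setdiff(seq_len(ne), st$shifts)
        e_new <- free[sample.int(length(free), 1L)]
        ns <- st$shifts; ns[j] <- e_new
        te2 <- theta_edge_of(ns, st$thetas, st$root_theta)
        quad2 <- quad_of(cache, mean_of(cache, te2, st$root_theta))
        lr <- ll_of(cache, quad2, st$sigma2) - ll
        if (log(stats::runif(1)) < lr) {
          st$shifts <- ns; te <- te2; quad <- quad2
          ll <- ll_of(cache, quad, st$sigma2); acc[mv] <- acc[mv] + 1
        }
      }
    } else if (mname == "theta") {
      j <- sample.int(k + 1L, 1L) - 1L   # 0 = root optimum
      old <- if (j == 0) st$root_theta else st$thetas[j]
      new <- stats::rnorm(1, old, qp$theta_sd)
      if (j == 0) {
        te2 <- theta_edge_of(st$shifts, st$thetas, new)
        quad2 <- quad_of(cache, mean_of(cache, te2, new))
      } else {
        nt <- st$thetas; nt[j] <- new
        te2 <- theta_edge_of(st$shifts, nt, st$root_theta)
        quad2 <- quad_of(cache, mean_of(cache, te2, st$root_theta))
      }
      lr <- ll_of(cache, quad2, st$sigma2) - ll +
        stats::dnorm(new, pr$theta_mean, pr$theta_sd, log = TRUE) -
        stats::dnorm(old, pr$theta_mean, pr$theta_sd, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        if (j == 0) st$root_theta <- new else st$thetas[j] <- new
        te <- te2; quad <- quad2
        ll <- ll_of(cache, quad, st$sigma2); acc[mv] <- acc[mv] + 1
      }
    } else if (mname == "alpha") {
      la_new <- stats::rnorm(1, log(st$alpha), qp$log_alpha_sd)
      cache2 <- chol_cache(exp(la_new))
      if (!is.null(cache2)) {
        te2 <- te                         # optima unchanged, weights change
        quad2 <- quad_of(cache2, mean_of(cache2, te2, st$root_theta))
        lr <- ll_of(cache2, quad2, st$sigma2) - ll +
          stats::dnorm(la_new, pr$log_alpha_mean, pr$log_alpha_sd,
                       log = TRUE) -
          stats::dnorm(log(st$alpha), pr$log_alpha_mean, pr$log_alpha_sd,
                       log = TRUE)
        if (log(stats::runif(1)) < lr) {
          st$alpha <- exp(la_new); cache <- cache2; quad <- quad2
          ll <- ll_of(cache, quad, st$sigma2); acc[mv] <- acc[mv] + 1
        }
      }
    } else {                              # sigma2
      ls_new <- stats::rnorm(1, log(st$sigma2), qp$log_sigma2_sd)
      lr <- ll_of(cache, quad, exp(ls_new)) - ll +
        stats::dnorm(ls_new, pr$log_sigma2_mean, pr$log_sigma2_sd,
                     log = TRUE) -
        stats::dnorm(log(st$sigma2), pr$log_sigma2_mean, pr$log_sigma2_sd,
                     log = TRUE)
      if (log(stats::runif(1)) < lr) {
        st$sigma2 <- exp(ls_new)
        ll <- ll_of(cache, quad, st$sigma2); acc[mv] <- acc[mv] + 1
      }
    }

    if (it %% 10000L == 0L && !prior_only) {
      p0 <- regime_painting(tree, st$shifts)
      ll_fresh <- ou_loglik(y, tree, p0, list(
        alpha = st$alpha, sigma2 = st$sigma2,
        theta = theta_by_regime(st, p0), root_mode = root_mode))
      if (abs(ll_fresh - ll) > 1e-6 * max(1, abs(ll)))
        stop("internal error: cached log-likelihood drifted (",
             ll, " vs ", ll_fresh, ") at iteration ", it)
    }

    if (it >= keep_from && (it - keep_from) %% thin == 0L) {
      kept <- kept + 1L
      shift_counts[st$shifts] <- shift_counts[st$shifts] + 1
      samples$shifts[[kept]] <- st$shifts
      samples$thetas[[kept]] <- c(root = st$root_theta, st$thetas)
      trace$iter[kept] <- it
      trace$k[kept] <- length(st$shifts)
      trace$alpha[kept] <- st$alpha
      trace$sigma2[kept] <- st$sigma2
      trace$root_theta[kept] <- st$root_theta
      trace$loglik[kept] <- ll
      trace$logprior[kept] <- log_prior_full(st)
    }
  }

  trace <- trace[seq_len(kept), , drop = FALSE]
  pp <- shift_counts / kept
  names(pp) <- seq_len(ne)

  # modal configuration summary
  sig <- vapply(samples$shifts, function(s) paste(sort(s), collapse = ","),
                character(1))
  modal_sig <- names(sort(table(sig), decreasing = TRUE))[1]
  in_modal <- sig == modal_sig
  modal_shifts <- if (nzchar(modal_sig))
    as.integer(strsplit(modal_sig, ",")[[1]]) else integer(0)
  modal <- list(
    shifts = modal_shifts,
    freq = mean(in_modal),
    alpha = mean(trace$alpha[in_modal]),
    sigma2 = mean(trace$sigma2[in_modal]),
    theta = modal_theta_means(samples, in_modal, tree, modal_shifts)
  )

  structure(list(
    pp = pp, trace = trace, samples = samples, modal = modal,
    accept = ifelse(att > 0, acc / att, NA), kept = kept,
    branches = branch_table(tree), tree = tree, prior = pr,
    move_probs = move_probs, prior_only = prior_only, seed = seed
  ), class = "rjou_fit")
}

# Map the per-shift optima of a sampler state onto the regime numbering of
# regime_painting (root = 1, then cladewise order of the shift branches).
theta_by_regime <- function(st, painting) {
  if (!length(st$shifts)) return(st$root_theta)
  ord <- order(st$shifts)
  c(st$root_theta, st$thetas[ord])
}

modal_theta_means <- function(samples, in_modal, tree, modal_shifts) {
  sel <- which(in_modal)
  if (!length(sel)) return(numeric(0))
  mat <- t(vapply(sel, function(i) {
    th <- samples$thetas[[i]]
    shifts <- samples$shifts[[i]]
    c(th[1], th[-1][order(shifts)])
  }, numeric(length(modal_shifts) + 1)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  out <- colMeans(mat)
  names(out) <- c("root", if (length(modal_shifts))
    paste0("edge", sort(modal_shifts)))
  out
}

#' @export
print.rjou_fit <- function(x, ...) {
  cat("Reversible-jump OU shift sampler:", x$kept, "retained samples\n")
  cat("Posterior mean shift count:", round(mean(x$trace$k), 2), "\n")
  top <- sort(x$pp, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5, sum(x$pp > 0)))]
  if (length(top)) {
    cat("Top shift branches (PP):\n")
    lb <- x$branches$label[as.integer(names(top))]
    for (i in seq_along(top))
      cat(sprintf("  edge %s (%s): %.3f\n", names(top)[i], lb[i], top[i]))
  } else cat("No sampled shifts.\n")
  invisible(x)
}

#' Per-branch shift posterior probabilities with threshold flags
#'
#' `PP(branch)` is the fraction of retained samples containing a shift on
#' that branch; flags mark the conventional liberal (0.2), intermediate
#' (0.5) and conservative (0.8) calling thresholds.
#'
#' @param fit An `"rjou_fit"`, or a list of integer shift-branch vectors
#'   (one per retained sample) together with `n_branches`.
#' @param n_branches Number of branches (required when `fit` is a raw list).
#' @return Data frame: `edge`, `label`, `pp`, and logical `pp_ge_0.2`,
#'   `pp_ge_0.5`, `pp_ge_0.8`.
#' @export
branch_shift_pp <- function(fit, n_branches = NULL) {
  if (inherits(fit, "rjou_fit")) {
    samples <- fit$samples$shifts
    ne <- nrow(fit$branches)
    labels <- fit$branches$label
  } else {
    samples <- fit
    if (is.null(n_branches)) stop("`n_branches` required for a raw trace")
    ne <- n_branches
    labels <- as.character(seq_len(ne))
  }
  if (!length(samples)) stop("empty trace")
  counts <- numeric(ne)
  for (s in samples) counts[s] <- counts[s] + 1
  pp <- counts / length(samples)
  data.frame(edge = seq_len(ne), label = labels, pp = pp,
             pp_ge_0.2 = pp >= 0.2, pp_ge_0.5 = pp >= 0.5,
             pp_ge_0.8 = pp >= 0.8, stringsAsFactors = FALSE)
}

#' Signal-to-noise effect size of a multi-regime OU pattern
#'
#' `eta_phi = [min_{i != j} |theta_i - theta_j| / sqrt(sigma2 / (2 alpha))]
#' * phi` with `phi = 1 - exp(-alpha * tbar)` and `tbar` the mean
#' root-to-tip depth: the minimum separation between optima in units of the
#' stationary SD, discounted by the fraction of adaptation attained over the
#' tree's depth. Values much larger than 1 indicate an estimated pattern
#' with high power. The decomposition is returned so alternative discount
#' definitions can be substituted.
#'
#' @param params List with `alpha`, `sigma2`, `theta` (vector of regime
#'   optima, length >= 2 for a defined ratio).
#' @param tree A `"phylo"` tree.
#' @return Object of class `"effect_size"`: `eta_phi`, `min_dtheta`,
#'   `stationary_sd`, `phi`, `tbar`; for a single regime `eta_phi` is `NA`
#'   and `note = "single-regime"`.
#' @export
signal_to_noise <- function(params, tree) {
  tree <- as_gradeshift_tree(tree)
  tbar <- mean(node_depths(tree)[seq_len(ape::Ntip(tree))])
  theta <- params$theta
  if (length(theta) < 2) {
    return(structure(list(eta_phi = NA_real_, note = "single-regime",
                          tbar = tbar), class = "effect_size"))
  }
  dt <- abs(outer(theta, theta, "-"))
  min_dtheta <- min(dt[upper.tri(dt)])
  stat_sd <- sqrt(params$sigma2 / (2 * params$alpha))
  phi <- 1 - exp(-params$alpha * tbar)
  structure(list(
    eta_phi = min_dtheta / stat_sd * phi,
    min_dtheta = min_dtheta, stationary_sd = stat_sd, phi = phi, tbar = tbar
  ), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  if (!is.null(x$note)) {
    cat("Signal-to-noise ratio undefined:", x$note, "\n")
  } else {
    cat(sprintf(
      "eta_phi = %.3f (min |dtheta| = %.4g, stationary SD = %.4g, phi = %.3f)\n",
      x$eta_phi, x$min_dtheta, x$stationary_sd, x$phi))
  }
  invisible(x)
}
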