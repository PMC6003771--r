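# Multiple-variance Brownian motion: ancestral states under branch-specific
# rate multipliers estimated by an iterative heuristic, and per-branch
# observed-vs-neutral change ratios against a constant-rate simulation null
# on a generation-scaled tree.

#' Brownian-motion (GLS) ancestral states
#'
#' Maximum-likelihood ancestral states under standard BM: the internal-node
#' values minimizing the sum of squared changes per unit branch length.
#' Equivalently the conditional means of the tree-structured Gaussian model
#' given the tips, obtained by solving the weighted graph-Laplacian system.
#' Conditional standard errors (`sqrt(sigma2 * diag(A_II^-1))`) use the
#' Q-mode/GLS estimate of `sigma2` from [qmode_rate()].
#'
#' @param y Named numeric vector of tip values.
#' @param tree A `"phylo"` tree.
#' @return List: `states` (internal nodes, named by node number), `se`
#'   (matching analytic SEs), `node_values` (tips then internal), `sigma2`.
#' @export
bm_ancestral_states <- function(y, tree) {
  tree <- as_gradeshift_tree(tree)
  y <- y[tree$tip.label]
  st <- anc_states_lengths(y, tree, tree$edge.length, se = TRUE)
  st$sigma2 <- qmode_rate(y, tree)
  st$se <- sqrt(pmax(st$sigma2, .Machine$double.eps) * st$cond_var)
  st
}

# Core solver for arbitrary branch lengths: states minimise
# sum_e (x_child - x_parent)^2 / l_e with tips fixed at y, i.e. the
# conditional means of the tree-Gaussian model. `mapping = TRUE` also
# returns the linear map from tip values to internal states (rows of
# -A_II^-1 A_IT), needed to standardize estimated per-branch changes.
anc_states_lengths <- function(y, tree, lengths, se = FALSE,
                               mapping = FALSE) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  w <- 1 / pmax(lengths, 1e-12)
  A <- matrix(0, m, m)          # internal-internal block of the Laplacian
  B <- matrix(0, m, n)          # internal-tip block (negated weights)
  e1 <- tree$edge[, 1] - n      # parents are always internal
  e2 <- tree$edge[, 2]
  for (e in seq_along(w)) {
    i <- e1[e]
    A[i, i] <- A[i, i] + w[e]
    if (e2[e] <= n) {
      B[i, e2[e]] <- B[i, e2[e]] + w[e]
    } else {
      j <- e2[e] - n
      A[j, j] <- A[j, j] + w[e]
      A[i, j] <- A[i, j] - w[e]
      A[j, i] <- A[j, i] - w[e]
    }
  }
  G <- solve(A, B)              # states = G %*% y
  states <- drop(G %*% y)
  names(states) <- n + seq_len(m)
  out <- list(states = states,
              node_values = c(stats::setNames(y, seq_len(n)), states))
  if (se) out$cond_var <- diag(solve(A))
  if (mapping) out$G <- G
  out
}

# Variance factors of the estimated per-branch changes under unit-rate BM
# with the given branch lengths: v_e = d_e' C d_e where d_e maps tip values
# to (state_child - state_parent) and C is the tip covariance.
branch_change_varfactors <- function(tree, lengths, G) {
  n <- ape::Ntip(tree)
  tr2 <- tree; tr2$edge.length <- lengths
  C <- ape::vcv(tr2)
  M <- rbind(diag(n), G)        # node_values = M %*% y
  Md <- M[tree$edge[, 2], , drop = FALSE] - M[tree$edge[, 1], , drop = FALSE]
  rowSums((Md %*% C) * Md)
}

#' Multiple-variance Brownian-motion ancestral estimation
#'
#' Heuristic combining global and local information: (1) GLS ancestral
#' states under the given branch lengths; (2) each branch's squared
#' estimated change, standardized by its exact estimator variance (so the
#' statistic has unit expectation under constant-rate BM — the global
#' calibration), is smoothed over the branch's immediate neighborhood (the
#' local signal) and pulled toward 1 with weight `shrink`, giving a
#' per-branch rate multiplier; (3) branch lengths are rescaled by the
#' multipliers (total tree length held fixed) and ancestral states are
#' re-estimated under the rescaled lengths, the cycle repeating until the
#' largest ancestral-state change drops below `tol` or `max_iter` is
#' reached (non-convergence flags the result, it does not raise). The
#' standardized statistic is anchored to the input branch lengths, which
#' makes the iteration a damped update rather than a drifting fixed point:
#' it converges once the states under the rescaled lengths stabilize.
#' Multipliers are reported normalized to mean 1 across branches, so the
#' all-ones vector recovers standard BM exactly.
#'
#' @param y Named numeric vector of tip values.
#' @param tree A `"phylo"` tree (>= 4 tips).
#' @param tol Convergence tolerance on ancestral states (trait units).
#' @param max_iter Iteration cap.
#' @param shrink Weight in (0, 1\] pulling multipliers toward the smoothed
#'   standardized squared change (default 0.3; smaller is more damped and
#'   keeps the multiplier spread tighter under constant-rate data, larger
#'   tracks rate heterogeneity more aggressively).
#' @return Object of class `"mvbm_fit"`: `states` (internal nodes), `se`
#'   (analytic SEs of the matching standard-BM states), `node_values`,
#'   `multipliers` (per branch, mean 1), `iterations`, `converged`.
#' @export
fit_mvbm <- function(y, tree, tol = 1e-6, max_iter = 50L, shrink = 0.3) {
  tree <- as_gradeshift_tree(tree)
  if (ape::Ntip(tree) < 4) stop("mvBM needs at least 4 tips")
  if (!all(tree$tip.label %in% names(y)))
    stop("`y` must be named and cover every tip")
  y <- y[tree$tip.label]
  l0 <- tree$edge.length
  l <- l0
  ne <- nrow(tree$edge)
  # branch neighborhoods (self + parent edge + child edges) for smoothing
  parent_edge <- match(tree$edge[, 1], tree$edge[, 2])
  nbrs <- lapply(seq_len(ne), function(e) {
    unique(c(e, parent_edge[e],
             which(tree$edge[, 1] == tree$edge[e, 2]),
             which(!is.na(parent_edge) & parent_edge == e)))
  })
  nbrs <- lapply(nbrs, function(v) v[!is.na(v)])
  # Standardization is anchored to the input lengths: both the estimated
  # change and its variance factor come from the standard-BM fit, so under
  # constant-rate BM every branch's statistic is exactly chi-square(1) and
  # the multipliers stay tightly distributed around 1.
  st0 <- anc_states_lengths(y, tree, l0, mapping = TRUE)
  v0 <- branch_change_varfactors(tree, l0, st0$G)
  d0 <- st0$node_values[tree$edge[, 2]] - st0$node_values[tree$edge[, 1]]
  s2 <- mean(d0^2 / v0)
  u <- d0^2 / (pmax(s2, .Machine$double.eps) * v0)
  # local smoothing, self-weighted: half the branch's own signal, half its
  # neighborhood mean (which includes itself)
  u_sm <- 0.5 * u + 0.5 * vapply(nbrs, function(idx) mean(u[idx]), numeric(1))
  r <- (1 - shrink) + shrink * u_sm
  l <- l0 * r
  l <- l * sum(l0) / sum(l)
  # re-estimate states under the rescaled lengths until stable
  prev <- st0$states
  converged <- FALSE
  iter <- 1L
  repeat {
    iter <- iter + 1L
    st <- anc_states_lengths(y, tree, l)
    if (max(abs(st$states - prev)) < tol) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    prev <- st$states
  }
  mult <- l / l0
  mult <- mult / mean(mult)
  bm <- bm_ancestral_states(y, tree)
  structure(list(
    states = st$states, node_values = st$node_values,
    se = bm$se, multipliers = mult, iterations = iter,
    converged = converged, tree = tree, final_lengths = l
  ), class = "mvbm_fit")
}

#' @export
print.mvbm_fit <- function(x, ...) {
  cat(sprintf("mvBM fit: %d internal states, %d iterations (%s)\n",
              length(x$states), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("multiplier range: %.3f .. %.3f (mean 1)\n",
              min(x$multipliers), max(x$multipliers)))
  invisible(x)
}

#' Per-branch change ratios against a constant-rate neutral null
#'
#' Simulates constant-rate BM on a generation-scaled tree `reps` times, and
#' for each branch compares the observed amount of change (|descendant -
#' ancestor| with ancestors estimated by mvBM or plain BM) with the mean
#' simulated amount. Ratios below one mark slow-evolving branches, above one
#' fast-evolving ones.
#'
#' @param y Named numeric vector of tip values.
#' @param tree_generations Tree with `units == "generations"` (see
#'   [rescale_to_generations()]).
#' @param per_gen_rate Per-generation Brownian rate (variance per
#'   generation); no default — it must come from data external to the tree.
#' @param reps Number of constant-rate simulations (default 100).
#' @param seed Mandatory RNG seed.
#' @param observed_method Ancestral states for the observed data: `"mvbm"`
#'   (default) or `"bm"`.
#' @param reestimate Re-estimate ancestral values of each simulated
#'   replicate with the same method as the observed data (default `TRUE`;
#'   required for a calibrated ratio — mixing estimators biases it);
#'   `FALSE` uses the true simulated node values, in which case the
#'   per-branch expectation is the analytic half-normal mean
#'   `sqrt(rate * l) * sqrt(2/pi)`.
#' @return Object of class `"branch_change_ratio"`: data frame with `edge`,
#'   `label`, `observed`, `expected`, `ratio`.
#' @export
neutral_change_ratio <- function(y, tree_generations, per_gen_rate,
                                 reps = 100L, seed,
                                 observed_method = c("mvbm", "bm"),
                                 reestimate = TRUE) {
  observed_method <- match.arg(observed_method)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (!identical(attr(tree_generations, "units"), "generations"))
    stop("tree must be in generations (units attribute); ",
         "see rescale_to_generations()")
  if (!is.numeric(per_gen_rate) || per_gen_rate <= 0)
    stop("`per_gen_rate` must be > 0")
  if (reps < 2) stop("`reps` must be at least 2")
  tree <- as_gradeshift_tree(tree_generations, units = "generations")
  y <- y[tree$tip.label]

  obs_nodes <- if (observed_method == "mvbm")
    fit_mvbm(y, tree)$node_values
  else
    bm_ancestral_states(y, tree)$node_values
  obs <- abs(obs_nodes[tree$edge[, 2]] - obs_nodes[tree$edge[, 1]])

  set.seed(as.integer(seed))
  ne <- nrow(tree$edge)
  acc <- numeric(ne)
  x0 <- mean(y)
  for (r in seq_len(reps)) {
    sim <- simulate_bm(tree, sigma2 = per_gen_rate, x0 = x0)
    nodes <- if (!reestimate)
      attr(sim, "node_states")
    else if (observed_method == "mvbm")
      fit_mvbm(sim, tree)$node_values
    else
      bm_ancestral_states(sim, tree)$node_values
    acc <- acc + abs(nodes[tree$edge[, 2]] - nodes[tree$edge[, 1]])
  }
  expected <- acc / reps
  out <- data.frame(
    edge = seq_len(ne), label = branch_table(tree)$label,
    observed = unname(obs), expected = unname(expected),
    ratio = unname(obs / expected), stringsAsFactors = FALSE
  )
  class(out) <- c("branch_change_ratio", "data.frame")
  attr(out, "reps") <- reps
  attr(out, "per_gen_rate") <- per_gen_rate
  out
}
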