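# Multi-regime Ornstein-Uhlenbeck (Hansen) model machinery: regime
# paintings, design weights mapping optima to expected tip values, tip
# covariance, and the Gaussian log-likelihood. Standard BM is the alpha -> 0
# limit throughout.

#' Paint branches with regimes induced by a set of shift branches
#'
#' Every branch inherits the regime of its parent branch unless a shift
#' starts on it, in which case it opens a new regime. The root regime has id
#' 1; shifted regimes are numbered 2, 3, ... in cladewise branch order, so a
#' painting is a deterministic function of the shift set.
#'
#' @param tree A `"phylo"` tree.
#' @param shift_edges Integer vector of branch ids (rows of the cladewise
#'   edge matrix, see [branch_table()]); may be empty.
#' @return List of class `"regime_painting"`: `regime` (integer per branch),
#'   `shift_edges` (sorted), `n_regimes`, `root_regime = 1`.
#' @export
regime_painting <- function(tree, shift_edges = integer()) {
  tree <- as_gradeshift_tree(tree)
  ne <- nrow(tree$edge)
  shift_edges <- sort(unique(as.integer(shift_edges)))
  if (length(shift_edges) && (min(shift_edges) < 1 || max(shift_edges) > ne))
    stop("shift branch id out of range 1..", ne)
  parent_edge <- match(tree$edge[, 1], tree$edge[, 2])  # NA for root edges
  regime <- integer(ne)
  next_id <- 1L
  for (e in seq_len(ne)) {          # cladewise: parents precede children
    if (e %in% shift_edges) {
      next_id <- next_id + 1L
      regime[e] <- next_id
    } else {
      regime[e] <- if (is.na(parent_edge[e])) 1L else regime[parent_edge[e]]
    }
  }
  # renumber so regimes appear in cladewise order of their shift branch;
  # the root regime keeps id 1 even if no branch retains it
  ids <- sort(unique(c(1L, regime)))
  regime <- match(regime, ids)
  structure(list(regime = regime, shift_edges = shift_edges,
                 n_regimes = length(ids), root_regime = 1L),
            class = "regime_painting")
}

# Root-path segments of every tip: one row per (tip, branch) pair with the
# segment's start and end time measured from the root. Cached building block
# for design weights and the rjMCMC sampler.
tip_path_segments <- function(tree) {
  tree <- as_gradeshift_tree(tree)
  n <- ape::Ntip(tree)
  depths <- node_depths(tree)
  child_edge <- match(seq_len(n + tree$Nnode), tree$edge[, 2])
  tip <- integer(0); edge <- integer(0)
  for (i in seq_len(n)) {
    nd <- i
    while (!is.na(child_edge[nd])) {
      e <- child_edge[nd]
      tip <- c(tip, i); edge <- c(edge, e)
      nd <- tree$edge[e, 1]
    }
  }
  data.frame(tip = tip, edge = edge,
             t0 = depths[tree$edge[edge, 1]],
             t1 = depths[tree$edge[edge, 2]],
             depth = depths[tip])
}

#' OU design weights: expected tip values as a linear map of the optima
#'
#' For tip i with root-to-tip depth `T_i`, the weight of regime r is the sum
#' over the root-path segments painted r of
#' `exp(-alpha (T_i - t_end)) - exp(-alpha (T_i - t_start))`, the classic
#' Hansen-model exponential integral. The remaining weight `exp(-alpha T_i)`
#' belongs to the root state: under `root_mode = "stationary"` it is added to
#' the root regime's column (rows then sum to one); under `"free"` it forms
#' an extra `x0` column.
#'
#' @param tree A `"phylo"` tree.
#' @param painting A [regime_painting()].
#' @param alpha Adaptation rate (> 0), per unit branch length.
#' @param root_mode `"stationary"` or `"free"`.
#' @return Matrix with one row per tip (tip-label rownames) and one column
#'   per regime (plus `x0` under `"free"`).
#' @export
ou_design_weights <- function(tree, painting, alpha,
                              root_mode = c("stationary", "free")) {
  root_mode <- match.arg(root_mode)
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0")
  tree <- as_gradeshift_tree(tree)
  if (length(painting$regime) != nrow(tree$edge))
    stop("painting does not cover every branch")
  seg <- tip_path_segments(tree)
  n <- ape::Ntip(tree)
  k <- painting$n_regimes
  w <- exp(-alpha * (seg$depth - seg$t1)) - exp(-alpha * (seg$depth - seg$t0))
  W <- matrix(0, n, k, dimnames = list(tree$tip.label, paste0("theta", 1:k)))
  reg <- painting$regime[seg$edge]
  for (r in seq_len(k)) {
    sel <- reg == r
    if (any(sel)) {
      agg <- rowsum(w[sel], seg$tip[sel])
      W[as.integer(rownames(agg)), r] <- W[as.integer(rownames(agg)), r] + agg
    }
  }
  root_w <- exp(-alpha * node_depths(tree)[seq_len(n)])
  if (root_mode == "stationary") {
    W[, painting$root_regime] <- W[, painting$root_regime] + root_w
  } else {
    W <- cbind(W, x0 = root_w)
  }
  W
}

#' Tip covariance under a single-rate OU process
#'
#' With shared time `s_ij` (from the root) and tip depths `T_i`, the
#' covariance conditional on the root state is
#' `sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha s_ij))` with
#' `d_ij = T_i + T_j - 2 s_ij` (`root = "fixed"`, the default). Under a
#' stationary root (`root = "stationary"`) the bracket is 1. Works on
#' non-ultrametric trees via per-tip depths.
#'
#' @param tree A `"phylo"` tree.
#' @param alpha,sigma2 OU parameters (> 0).
#' @param root `"fixed"` or `"stationary"`.
#' @return Symmetric covariance matrix with tip-label dimnames.
#' @export
ou_covariance <- function(tree, alpha, sigma2,
                          root = c("fixed", "stationary")) {
  root <- match.arg(root)
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0")
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("`sigma2` must be > 0")
  S <- ape::vcv(as_gradeshift_tree(tree))
  Td <- diag(S)
  D <- outer(Td, Td, "+") - 2 * S
  out <- sigma2 / (2 * alpha) * exp(-alpha * D)
  if (root == "fixed") out <- out * (1 - exp(-2 * alpha * S))
  out
}

#' Log-likelihood of tip data under a multi-regime OU model
#'
#' Multivariate-normal log density with mean `ou_design_weights %*% theta`
#' and covariance [ou_covariance()], evaluated via a Cholesky factorization.
#' A covariance that is not numerically positive definite (extreme alpha)
#' yields the finite sentinel `-1e300` rather than an error, so samplers can
#' treat it as a rejection.
#'
#' @param y Named numeric vector of tip values.
#' @param tree A `"phylo"` tree.
#' @param painting A [regime_painting()].
#' @param params List with `alpha`, `sigma2`, `theta` (one optimum per
#'   regime), optional `root_mode` (`"stationary"` default, or `"free"` with
#'   `x0`).
#' @return Scalar log-likelihood.
#' @export
ou_loglik <- function(y, tree, painting, params) {
  tree <- as_gradeshift_tree(tree)
  if (!all(tree$tip.label %in% names(y)))
    stop("`y` must be named and cover every tip")
  y <- y[tree$tip.label]
  root_mode <- params$root_mode %||% "stationary"
  theta <- params$theta
  if (length(theta) != painting$n_regimes)
    stop("theta vector length (", length(theta),
         ") != regime count (", painting$n_regimes, ")")
  W <- ou_design_weights(tree, painting, params$alpha, root_mode = root_mode)
  coefs <- if (root_mode == "free") c(theta, params$x0) else theta
  mu <- drop(W %*% coefs)
  Vroot <- if (root_mode == "free") "fixed" else "stationary"
  V <- ou_covariance(tree, params$alpha, params$sigma2, root = Vroot)
  mvn_loglik(y - mu, V)
}

# Gaussian log density of a residual vector with covariance V; -1e300
# sentinel when V is not positive definite.
mvn_loglik <- function(r, V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-1e300)
  z <- backsolve(L, r, transpose = TRUE)
  -0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}
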