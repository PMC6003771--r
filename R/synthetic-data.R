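# Synthetic data with the statistical structure the analysis assumes: an
# ultrametric pure-birth tree, a log-log allometry with slope above 1 and
# lambda-structured residuals, planted intercept grades on designated
# clades, an optional cognition trait linked to the residuals on a subclade,
# and generation times. All simulators are bit-reproducible under a seed.

#' Simulate an ultrametric pure-birth tree
#'
#' Pure-birth (Yule) tree rescaled so every root-to-tip path equals `depth`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param depth Root-to-tip depth (Myr by convention).
#' @param seed Mandatory RNG seed.
#' @return A `"phylo"` tree (units `"time"`), tips `s01`, `s02`, ...
#' @export
simulate_tree <- function(n_tips, depth = 1, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (n_tips < 3) stop("`n_tips` must be >= 3")
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$tip.label <- sprintf("s%02d", seq_len(n_tips))
  d <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * depth / max(d[seq_len(n_tips)])
  as_gradeshift_tree(tr, units = "time")
}

# Shared traversal engine: exact node-to-node transition sampling. BM is the
# alpha = 0 closed form; the per-edge standard-normal draws are consumed in
# identical (cladewise) order in both cases, so the two processes coincide
# pathwise as alpha -> 0.
simulate_markov <- function(tree, sigma2, x0, alpha = 0, theta_edge = NULL) {
  tree <- as_gradeshift_tree(tree)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  x <- numeric(nn)
  x[n + 1L] <- x0                       # root node is Ntip + 1
  for (e in seq_len(nrow(tree$edge))) { # cladewise: parents first
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    l <- tree$edge.length[e]
    z <- stats::rnorm(1)
    if (alpha > 0) {
      th <- theta_edge[e]
      m <- th + (x[p] - th) * exp(-alpha * l)
      s <- sqrt(sigma2 * (1 - exp(-2 * alpha * l)) / (2 * alpha))
    } else {
      m <- x[p]
      s <- sqrt(sigma2 * l)
    }
    x[ch] <- m + s * z
  }
  tips <- stats::setNames(x[seq_len(n)], tree$tip.label)
  attr(tips, "node_states") <- stats::setNames(x, seq_len(nn))
  tips
}

#' Simulate Brownian motion on a tree
#'
#' Exact transition sampling (`Normal(parent, sigma2 * l)` per branch); no
#' Euler discretization. The full set of node states is attached as
#' attribute `node_states`.
#'
#' @param tree A `"phylo"` tree.
#' @param sigma2 Brownian rate (trait^2 per unit branch length).
#' @param x0 Root state.
#' @param seed Optional seed (set it for reproducibility; omit to continue
#'   the current RNG stream).
#' @return Named tip-value vector with attribute `node_states`.
#' @export
simulate_bm <- function(tree, sigma2, x0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  simulate_markov(tree, sigma2, x0)
}

#' Simulate a (multi-regime) Ornstein-Uhlenbeck process on a tree
#'
#' Exact transition sampling per branch:
#' `Normal(theta + (parent - theta) e^{-alpha l}, sigma2 (1 - e^{-2 alpha l})
#' / (2 alpha))`, with `theta` the optimum of the branch's regime.
#'
#' @param tree A `"phylo"` tree.
#' @param alpha,sigma2 OU parameters (> 0).
#' @param theta Optimum vector, one per regime of `painting` (a scalar for a
#'   single regime).
#' @param painting A [regime_painting()]; defaults to a single regime.
#' @param x0 Root state; defaults to the root regime's optimum.
#' @param seed Optional seed.
#' @return Named tip-value vector with attribute `node_states`.
#' @export
simulate_ou <- function(tree, alpha, sigma2, theta,
                        painting = NULL, x0 = NULL, seed = NULL) {
  if (alpha <= 0 || sigma2 < 0) stop("need alpha > 0 and sigma2 >= 0")
  tree <- as_gradeshift_tree(tree)
  if (is.null(painting)) painting <- regime_painting(tree)
  if (length(theta) != painting$n_regimes)
    stop("length(theta) must equal the painting's regime count")
  if (is.null(x0)) x0 <- theta[painting$root_regime]
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (sigma2 == 0) {                    # deterministic decay toward theta
    n <- ape::Ntip(tree)
    x <- numeric(n + tree$Nnode); x[n + 1L] <- x0
    for (e in seq_len(nrow(tree$edge))) {
      th <- theta[painting$regime[e]]
      x[tree$edge[e, 2]] <- th + (x[tree$edge[e, 1]] - th) *
        exp(-alpha * tree$edge.length[e])
    }
    tips <- stats::setNames(x[seq_len(n)], tree$tip.label)
    attr(tips, "node_states") <- stats::setNames(x, seq_along(x))
    return(tips)
  }
  simulate_markov(tree, sigma2, x0, alpha = alpha,
                  theta_edge = theta[painting$regime])
}

#' Specification of the synthetic study fixture
#'
#' Defaults emulate the target data's structure: ~50 species, a 180-Myr-deep
#' ultrametric tree, log10 volumes with an allometric slope above unity,
#' phylogenetic signal lambda near 0.9 in the residuals, and three intercept
#' grades (high / baseline / low) planted on designated clades.
#'
#' @param n_tips Tips (default 50).
#' @param depth Tree depth in Myr (default 180, roughly the span of crown
#'   mammal evolution).
#' @param slope,intercept Allometric slope (default 1.3, inside the
#'   reported-range of lateral-on-medial scaling) and intercept (0.15 dex).
#' @param lambda Phylogenetic signal of the residuals (default 0.9).
#' @param resid_sd Residual SD in dex (default 0.15).
#' @param grade_offsets Intercept shifts in dex for the planted high and low
#'   grades (default `c(high = 0.5, low = -0.55)`).
#' @param grade_clade_sizes Target tip counts of the two grade clades.
#' @param medial_sigma2 BM rate of the driver (medial) log-volume per Myr.
#' @param medial_root Root state of the driver log-volume (log10 mm^3-ish
#'   units; only location, not scale, matters downstream).
#' @param cognition_slope,cognition_sd Link slope and noise SD of the
#'   cognition trait (simulated on a designated subclade only).
#' @param cognition_clade_size Target size of the cognition subclade.
#' @param generation_range Uniform range of generation times in years.
#' @param ou Optional list `(shift_edges, alpha, sigma2, theta)` to plant an
#'   explicit multi-regime OU trait (`ou_trait` column).
#' @param seed Mandatory seed.
#' @return List of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_tips = 50L, depth = 180, slope = 1.3,
                         intercept = 0.15, lambda = 0.9, resid_sd = 0.15,
                         grade_offsets = c(high = 0.5, low = -0.55),
                         grade_clade_sizes = c(8L, 8L),
                         medial_sigma2 = 0.003, medial_root = 0.5,
                         cognition_slope = 1, cognition_sd = 0.1,
                         cognition_clade_size = 20L,
                         generation_range = c(2, 25),
                         ou = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  stopifnot(resid_sd > 0, cognition_sd > 0, medial_sigma2 > 0,
            lambda >= 0, lambda <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

# Clade whose tip count is closest to `size` among clades disjoint from
# `exclude` (and smaller than ~half the tree, so the unplanted remainder
# stays the largest group); ties broken by node id — deterministic for a
# given tree.
pick_clade <- function(tree, size, exclude = integer()) {
  n <- ape::Ntip(tree)
  cand <- NULL
  for (nd in (n + 2L):(n + tree$Nnode)) {   # skip the root
    tips <- tip_descendants(tree, nd)
    if (length(tips) > ceiling(0.45 * n)) next
    if (any(tips %in% exclude)) next
    cand <- rbind(cand, c(nd, length(tips)))
  }
  if (is.null(cand)) stop("no clade disjoint from the excluded tips found")
  best <- cand[order(abs(cand[, 2] - size), cand[, 1]), , drop = FALSE][1, ]
  list(node = best[1], tips = tip_descendants(tree, best[1]))
}

#' Generate the synthetic study fixture
#'
#' Medial log-volume evolves by BM; lateral log-volume is
#' `intercept + slope * medial + grade offset + residual`, the residual
#' being a mixture of a Brownian component (weight `lambda`) and
#' independent Gaussian noise (weight `1 - lambda`) scaled to `resid_sd` —
#' the standard generative reading of Pagel's lambda. A rest-of-brain
#' log-volume (BM increment above the medial channel) supports the
#' relative-cerebellum-size analysis, cognition follows the residuals on a
#' designated subclade, and generation times are uniform in
#' `generation_range`. The generating truth is returned for recovery tests.
#'
#' @param spec A [fixture_spec()].
#' @return List: `tree`, `traits` (data frame: lateral, medial, rest,
#'   cognition, gen_time), `truth` (all generating parameters, the grade
#'   clade tip sets, the grade factor, and the edges subtending the grade
#'   clades).
#' @export
make_study_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  tree <- simulate_tree(spec$n_tips, spec$depth, seed = spec$seed)
  n <- spec$n_tips
  # clade choices are a function of the tree only, hence of the seed
  hi <- pick_clade(tree, spec$grade_clade_sizes[1])
  lo <- pick_clade(tree, spec$grade_clade_sizes[2], exclude = hi$tips)
  cog <- pick_clade(tree, spec$cognition_clade_size,
                    exclude = c(hi$tips, lo$tips))

  set.seed(as.integer(spec$seed) + 1L)
  medial <- simulate_bm(tree, spec$medial_sigma2, x0 = spec$medial_root)
  # lambda-structured residual: BM share lambda, white-noise share 1-lambda
  bm_part <- simulate_bm(tree, sigma2 = spec$resid_sd^2 / spec$depth, x0 = 0)
  white <- stats::rnorm(n, 0, spec$resid_sd)
  resid <- sqrt(spec$lambda) * as.numeric(bm_part) +
    sqrt(1 - spec$lambda) * white
  offset <- numeric(n)
  offset[hi$tips] <- spec$grade_offsets[["high"]]
  offset[lo$tips] <- spec$grade_offsets[["low"]]
  lateral <- spec$intercept + spec$slope * as.numeric(medial) +
    offset + resid
  rest <- as.numeric(medial) + 1.1 +
    as.numeric(simulate_bm(tree, sigma2 = 0.001, x0 = 0))
  cognition <- rep(NA_real_, n)
  cognition[cog$tips] <- spec$cognition_slope * resid[cog$tips] +
    stats::rnorm(length(cog$tips), 0, spec$cognition_sd)
  gen_time <- stats::runif(n, spec$generation_range[1],
                           spec$generation_range[2])

  traits <- data.frame(
    lateral = lateral, medial = as.numeric(medial), rest = rest,
    cognition = cognition, gen_time = gen_time,
    row.names = tree$tip.label
  )
  ou_trait <- NULL
  if (!is.null(spec$ou)) {
    painting <- regime_painting(tree, spec$ou$shift_edges)
    ou_trait <- simulate_ou(tree, spec$ou$alpha, spec$ou$sigma2,
                            spec$ou$theta, painting = painting)
    traits$ou_trait <- as.numeric(ou_trait)
  }

  grade <- rep("baseline", n)
  grade[hi$tips] <- "high"
  grade[lo$tips] <- "low"
  names(grade) <- tree$tip.label
  bt <- branch_table(tree)
  truth <- list(
    slope = spec$slope, intercept = spec$intercept, lambda = spec$lambda,
    resid_sd = spec$resid_sd, grade_offsets = spec$grade_offsets,
    grade = grade,
    high_clade = tree$tip.label[hi$tips], low_clade = tree$tip.label[lo$tips],
    cognition_clade = tree$tip.label[cog$tips],
    high_edge = bt$edge[bt$child == hi$node],
    low_edge = bt$edge[bt$child == lo$node],
    cognition_slope = spec$cognition_slope, ou = spec$ou,
    residual = stats::setNames(resid, tree$tip.label),
    seed = spec$seed
  )
  list(tree = tree, traits = traits, truth = truth)
}

#' Write a fixture to disk
#'
#' Writes `tree.nwk`, `traits.csv` and `truth.json` under `dir`.
#'
#' @param fixture Output of [make_study_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(fixture$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(cbind(species = rownames(fixture$traits),
                         fixture$traits),
                   file.path(dir, "traits.csv"), row.names = FALSE)
  truth <- fixture$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
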