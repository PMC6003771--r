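# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; no data files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the default synthetic study fixture (50 tips, planted grades)
study_fixture <- function() cached("fx50", make_study_fixture(fixture_spec(seed = 101)))

# a mid-sized ultrametric tree for simulation studies
tree30 <- function() cached("tree30", simulate_tree(30, 100, seed = 301))

# hand-checkable 3-tip tree: ((A:1,B:1):1,C:2);
tree_abc <- function() read_newick("((A:1,B:1):1,C:2):0;")

# brute-force shared-path covariance by walking root paths (independent of
# ape::vcv); used as the oracle for phylo_covariance
bruteforce_vcv <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- ape::Ntip(tree)
  paths <- lapply(seq_len(n), function(i) {
    nd <- i
    edges <- integer(0)
    repeat {
      e <- which(tree$edge[, 2] == nd)
      if (!length(e)) break
      edges <- c(edges, e)
      nd <- tree$edge[e, 1]
    }
    edges
  })
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(tree$edge.length[shared])
  }
  V
}
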