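#' Read a rooted, branch-length-bearing tree from a Newick string or file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract the rest
#' of the package relies on: a single rooted tree, branch lengths on every
#' edge, unique tip labels, and a deterministic cladewise (preorder) edge
#' ordering so that branch ids are stable across runs. The returned object is
#' an ordinary `ape` `"phylo"` with a `units` attribute (`"time"` by default)
#' tracking whether branch lengths are in time (Myr) or generations.
#'
#' @param text Newick string. Exactly one of `text`/`file` must be given.
#' @param file Path to a Newick file.
#' @param underscores_as_spaces Convert underscores in labels to spaces
#'   (classic Newick dialect); default `FALSE`, i.e. underscores are kept
#'   verbatim.
#' @param units Unit tag for branch lengths, `"time"` or `"generations"`.
#' @return A `"phylo"` tree in cladewise order with a `units` attribute.
#' @export
read_newick <- function(text = NULL, file = NULL,
                        underscores_as_spaces = FALSE, units = "time") {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: no tree found in input")
  if (inherits(tr, "multiPhylo"))
    stop("input contains more than one tree; a single rooted tree is required")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("every branch must carry a length; missing branch lengths are not defaulted")
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not supported")
  if (anyDuplicated(tr$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (underscores_as_spaces) tr$tip.label <- gsub("_", " ", tr$tip.label)
  as_gradeshift_tree(tr, units = units)
}

# Pre-scan for the malformations ape reports unhelpfully, naming the
# 1-based character offset of the first offending character.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i)
    }
  }
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' by character ",
         length(chars))
  if (!grepl(";", text)) stop("Newick parse error: missing terminal ';'")
  invisible(TRUE)
}

#' Write a tree to a Newick string or file
#'
#' Branch lengths are serialized at full double precision so that
#' read -> write -> read is the identity on topology and branch lengths.
#'
#' @param tree A `"phylo"` tree.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 17)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Normalize a phylo object: cladewise order + units attribute + validation.
as_gradeshift_tree <- function(tree, units = attr(tree, "units") %||% "time") {
  stopifnot(inherits(tree, "phylo"))
  units <- match.arg(units, c("time", "generations"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "units") <- units
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Branch (edge) identifiers
#'
#' Branch ids are the row indices of the tree's edge matrix in cladewise
#' (preorder) order; they are deterministic for a given Newick input, which
#' keeps shift locations and posterior summaries reproducible. Each id is
#' also given a human-readable label: the tip label for terminal branches,
#' `"node<k>"` for internal ones.
#'
#' @param tree A `"phylo"` tree.
#' @return A data frame with columns `edge` (id), `parent`, `child`,
#'   `length`, `label`, and `is_tip`.
#' @export
branch_table <- function(tree) {
  tree <- as_gradeshift_tree(tree)
  n <- ape::Ntip(tree)
  child <- tree$edge[, 2]
  data.frame(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1],
    child = child,
    length = tree$edge.length,
    label = ifelse(child <= n, tree$tip.label[child], paste0("node", child)),
    is_tip = child <= n,
    stringsAsFactors = FALSE
  )
}

#' Read a species-by-trait table
#'
#' Delimited text with a header row; the first column holds species labels.
#' The delimiter is sniffed from the header line (tab wins over comma when
#' both occur) and reported via a message. Volume columns can be
#' log-transformed exactly once at load time.
#'
#' @param file Path to a CSV/TSV file.
#' @param log_columns Character vector of columns to log-transform at load
#'   (applied once; values must be positive).
#' @param log_base Base of the logarithm, default 10 (allometric slopes are
#'   conventionally reported in log10 space).
#' @return A data frame with species labels as row names.
#' @export
read_trait_table <- function(file, log_columns = character(), log_base = 10) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  message("reading trait table with ",
          if (sep == "\t") "tab" else "comma", " delimiter: ", file)
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("duplicated species labels in trait table: ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  rownames(tab) <- tab[[1]]
  tab <- tab[, -1, drop = FALSE]
  for (cl in log_columns) {
    if (!cl %in% names(tab)) stop("no column named '", cl, "' to log-transform")
    if (any(tab[[cl]] <= 0, na.rm = TRUE))
      stop("column '", cl, "' has non-positive values; cannot log-transform")
    tab[[cl]] <- log(tab[[cl]], base = log_base)
  }
  tab
}

#' Restrict a tree and trait table to their common species
#'
#' The analysis set is the intersection of tip labels and table rows; dropped
#' names are listed in a warning so silent pruning never happens.
#'
#' @param tree A `"phylo"` tree.
#' @param traits Data frame with species row names.
#' @return List with elements `tree` and `traits`, aligned (traits rows in
#'   tip-label order).
#' @export
match_tree_traits <- function(tree, traits) {
  tree <- as_gradeshift_tree(tree)
  common <- intersect(tree$tip.label, rownames(traits))
  if (length(common) < 3) stop("fewer than 3 species shared by tree and traits")
  drop_tree <- setdiff(tree$tip.label, common)
  drop_tab <- setdiff(rownames(traits), common)
  if (length(drop_tree))
    warning("dropping tips absent from trait table: ",
            paste(drop_tree, collapse = ", "))
  if (length(drop_tab))
    warning("dropping trait rows absent from tree: ",
            paste(drop_tab, collapse = ", "))
  if (length(drop_tree))
    tree <- as_gradeshift_tree(ape::drop.tip(tree, drop_tree),
                               units = attr(tree, "units"))
  list(tree = tree, traits = traits[tree$tip.label, , drop = FALSE])
}

#' Phylogenetic covariance matrix with Pagel's lambda
#'
#' Entry (i, j) is the shared root-to-tip path length of species i and j,
#' multiplied by `lambda` off the diagonal; the diagonal (root-to-tip depth)
#' is left unscaled. `lambda = 1` is the Brownian-motion expectation,
#' `lambda = 0` a star phylogeny.
#'
#' @param tree A `"phylo"` tree.
#' @param lambda Scalar in \[0, 1\].
#' @return Symmetric positive semi-definite matrix with tip-label dimnames
#'   and a `lambda` attribute.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("`lambda` must be a scalar in [0, 1]")
  tree <- as_gradeshift_tree(tree)
  C <- ape::vcv(tree)
  if (any(diag(C) <= 0)) stop("tree has non-positive root-to-tip depths")
  V <- lambda * C
  diag(V) <- diag(C)
  attr(V, "lambda") <- lambda
  V
}

#' Rescale branch lengths from time to generations
#'
#' Each branch length is divided by the generation time (age at first
#' reproduction, years) of its descendant node. Tips use their own species
#' value; a species with no value inherits that of the phylogenetically
#' closest species with a known value (patristic distance, ties broken by
#' tip-label order). Internal nodes take the value of their closest
#' descendant tip after this fill-in. Branch lengths in Myr become numbers
#' of generations (1 Myr / g years = 1e6 / g generations).
#'
#' @param tree A `"phylo"` tree with `units == "time"`, lengths in Myr.
#' @param generation_times Named numeric vector (years), names are species;
#'   `NA`s allowed, at least one value required.
#' @return The rescaled tree, `units` set to `"generations"`, with an
#'   attribute `generation_time` (the per-node values used, indexed by node
#'   number).
#' @export
rescale_to_generations <- function(tree, generation_times) {
  tree <- as_gradeshift_tree(tree)
  n <- ape::Ntip(tree)
  g <- generation_times[tree$tip.label]
  names(g) <- tree$tip.label
  known <- !is.na(g)
  if (!any(known)) stop("no generation times available for any tip")
  if (any(g[known] <= 0)) stop("generation times must be positive")

  if (!all(known)) {
    D <- stats::cophenetic(tree)  # patristic distances between tips
    for (sp in tree$tip.label[!known]) {
      cand <- tree$tip.label[known]
      d <- D[sp, cand]
      best <- cand[d == min(d)]
      best <- sort(best)[1]  # lexicographic tie-break
      g[sp] <- g[best]
    }
  }

  # Internal nodes: generation time of the closest descendant tip (path
  # distance from the node), lexicographic tie-break.
  node_g <- numeric(n + tree$Nnode)
  node_g[seq_len(n)] <- g
  depths <- ape::node.depth.edgelength(tree)
  for (nd in (n + 1):(n + tree$Nnode)) {
    tips <- tip_descendants(tree, nd)
    d <- depths[tips] - depths[nd]
    best <- tips[d == min(d)]
    best <- best[order(tree$tip.label[best])][1]
    node_g[nd] <- g[tree$tip.label[best]]
  }

  tree$edge.length <- tree$edge.length * 1e6 / node_g[tree$edge[, 2]]
  attr(tree, "units") <- "generations"
  attr(tree, "generation_time") <- node_g
  tree
}

# Tip numbers descending from (and including, when nd is a tip) node nd.
tip_descendants <- function(tree, nd) {
  n <- ape::Ntip(tree)
  if (nd <= n) return(nd)
  kids <- tree$edge[tree$edge[, 1] == nd, 2]
  unlist(lapply(kids, tip_descendants, tree = tree))
}

# Root-to-tip depth of every node, cladewise order assumed.
node_depths <- function(tree) ape::node.depth.edgelength(tree)
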