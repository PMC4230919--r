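#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard neighbor joining (Q-criterion agglomeration, via
#' [ape::nj()]) on an uncorrected p-distance matrix. The result is unrooted
#' with branch lengths in substitutions per site. Negative branch-length
#' estimates, which NJ can produce on non-additive matrices, are clamped to
#' zero with the deficit transferred to the longest adjacent edge so path
#' lengths are approximately preserved. NJ is exact on additive matrices:
#' it recovers the generating topology and branch lengths.
#'
#' @param dm A `p_dist` object or a symmetric numeric matrix with dimnames,
#'   at least 3 sequences.
#' @return An [ape::phylo] tree with tip labels equal to the sequence ids.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "p_dist")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) abort("need at least 3 sequences for a tree")
  if (is.null(rownames(d))) abort("distance matrix must have dimnames")
  if (!isSymmetric(unname(d), tol = 1e-12)) {
    abort("distance matrix must be symmetric")
  }
  tree <- ape::nj(d)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    adj <- setdiff(which(tree$edge[, 1] == tree$edge[e, 1] |
                           tree$edge[, 2] == tree$edge[e, 1]), e)
    if (length(adj)) {
      tgt <- adj[which.max(tree$edge.length[adj])]
      tree$edge.length[tgt] <- max(tree$edge.length[tgt] + deficit, 0)
    }
  }
  tree
}

# Canonical string key for the bipartition induced by a tip subset: the side
# not containing the alphabetically first tip label, sorted and joined.
canonical_split <- function(tips_in, all_tips) {
  ref <- min(all_tips)
  side <- if (ref %in% tips_in) setdiff(all_tips, tips_in) else tips_in
  paste(sort(side), collapse = "|")
}

#' Internal splits (bipartitions) of an unrooted tree
#'
#' One row per internal edge; trivial splits (single tips or their
#' complements) are excluded. Each split is keyed by a canonical string so
#' split sets can be compared across trees regardless of leaf order or
#' rooting.
#'
#' @param tree An [ape::phylo] tree.
#' @return Tibble with `node` (the ape node id below the edge), `key`
#'   (canonical split string) and `tips` (list-column of tip labels on the
#'   smaller-defined side).
#' @export
tree_splits <- function(tree) {
  all_tips <- tree$tip.label
  n <- length(all_tips)
  pp <- ape::prop.part(tree)
  nodes <- seq_len(tree$Nnode) + n
  rows <- purrr::map(seq_along(pp), function(i) {
    tips_in <- all_tips[pp[[i]]]
    k <- length(tips_in)
    if (k < 2 || k > n - 2) return(NULL)
    tibble(node = nodes[i], key = canonical_split(tips_in, all_tips),
           tips = list(tips_in))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(node = integer(), key = character(), tips = list())
  }
  # the root "clade" (all tips) duplicates no edge but prop.part's first
  # entry is the full set, already excluded as trivial above
  dplyr::distinct(out, .data$key, .keep_all = TRUE)
}

#' Test monophyly of a leaf set on an unrooted tree
#'
#' A leaf set is monophyletic iff some edge bipartitions the leaves into
#' exactly that set and its complement. Singletons, the full leaf set, and
#' sets missing exactly one leaf are trivially monophyletic (terminal edges).
#'
#' @param tree An [ape::phylo] tree.
#' @param leaf_set Non-empty character vector of tip labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(tree, leaf_set) {
  if (length(leaf_set) == 0) abort("leaf_set is empty")
  unknown <- setdiff(leaf_set, tree$tip.label)
  if (length(unknown)) {
    abort(paste0("unknown leaf id(s): ", paste(unknown, collapse = ", ")))
  }
  k <- length(unique(leaf_set))
  n <- length(tree$tip.label)
  if (k <= 1 || k >= n - 1) return(TRUE)
  key <- canonical_split(unique(leaf_set), tree$tip.label)
  key %in% tree_splits(tree)$key
}

#' Bootstrap supports for a distance tree
#'
#' Nonparametric bootstrap over alignment columns: columns are resampled with
#' replacement, the tree is rebuilt per replicate, and each internal split of
#' the point-estimate tree is scored by the percentage of replicates
#' containing it. Replicates in which some pair has zero comparable sites are
#' discarded with a warning; more than 10% discarded is an error. Supports
#' are attached to the returned tree as integer internal node labels.
#'
#' @param aln An [aligned_seqs] matrix (post-masking, if a mask is used:
#'   resampling operates on the columns actually analysed).
#' @param tree_fun Tree builder mapping an alignment to an [ape::phylo];
#'   default is NJ on the p-distance matrix.
#' @param reps Number of bootstrap replicates, at least 100.
#' @param seed Integer seed; identical seeds give identical supports.
#' @return The point-estimate tree with `node.label` holding integer percent
#'   supports (empty where an internal node defines no nontrivial split).
#' @export
bootstrap_supports <- function(aln,
                               tree_fun = function(a)
                                 nj_tree(p_distance_matrix(a)),
                               reps = 100, seed = 1) {
  if (reps < 100) abort("reps must be at least 100")
  point <- tree_fun(aln)
  splits <- tree_splits(point)
  counts <- setNames(rep(0L, nrow(splits)), splits$key)
  discarded <- 0L
  with_seed_(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      rep_aln <- unclass(aln)[, idx, drop = FALSE]
      class(rep_aln) <- class(aln)
      rep_tree <- tryCatch(tree_fun(rep_aln), error = function(e) NULL)
      if (is.null(rep_tree)) {
        discarded <- discarded + 1L
        next
      }
      hit <- splits$key %in% tree_splits(rep_tree)$key
      counts[hit] <- counts[hit] + 1L
    }
  })
  used <- reps - discarded
  if (discarded > 0) {
    warn(paste0(discarded, " bootstrap replicate(s) discarded ",
                "(undefined distances)"))
  }
  if (discarded > 0.1 * reps) {
    abort(paste0("more than 10% of bootstrap replicates discarded (",
                 discarded, "/", reps, ")"))
  }
  support <- round(100 * counts / used)
  labels <- rep("", point$Nnode)
  node_pos <- splits$node - length(point$tip.label)
  labels[node_pos] <- as.character(as.integer(support))
  point$node.label <- labels
  point
}

#' Write a tree as Newick
#'
#' Standard Newick with branch lengths; bootstrap supports (if present as
#' node labels) are serialised as internal node labels. Reading the file back
#' reproduces topology, branch lengths to 6 decimals, and supports.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ok <- tryCatch({
    ape::write.tree(tree, file = path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    abort(paste0("could not write Newick file: ", path))
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file (terminating semicolon required).
#' @return An [ape::phylo] tree; internal node labels, if present, carry
#'   bootstrap supports.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("Newick file not found: ", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("could not parse Newick file: ", path))
  tree
}
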