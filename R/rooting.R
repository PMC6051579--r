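#' Root a tree on the branch subtending a designated outgroup
#'
#' The outgroup tips must be present and monophyletic in the unrooted tree
#' (in the bipartition sense); the root is placed on the branch separating
#' them from the ingroup, and internal-node support labels stay attached to
#' their edges.
#'
#' @param tree An unrooted \code{ape::phylo}.
#' @param outgroup_tips Character vector of outgroup tip labels.
#' @return Rooted \code{ape::phylo}.
#' @export
root_with_outgroup <- function(tree, outgroup_tips) {
  missing_tips <- setdiff(outgroup_tips, tree$tip.label)
  if (length(missing_tips))
    stop("outgroup tip(s) absent from tree: ",
         paste(missing_tips, collapse = ", "))
  if (!is_monophyletic_unrooted(tree, outgroup_tips))
    stop("outgroup is not monophyletic; cannot root")
  ape::root(tree, outgroup = outgroup_tips, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Screen a set of trees for well-supported topological conflict
#'
#' Trees are pruned to their shared taxa; every bipartition whose support
#' meets \code{support_floor} is compared across trees, and incompatible
#' pairs (all four side intersections non-empty) are reported. An empty
#' report means no well-supported conflict — the congruence condition under
#' which per-locus alignments are concatenated.
#'
#' @param trees List of at least two support-annotated \code{ape::phylo}
#'   trees (supports as node labels, in percent).
#' @param support_floor Minimum support, in percent, for a bipartition to
#'   participate in the comparison (default 75). Bipartitions with absent
#'   support never participate.
#' @return Data frame with one row per conflicting pair: \code{tree_a},
#'   \code{tree_b}, \code{split_a}, \code{split_b}, \code{support_a},
#'   \code{support_b}. Splits are printed as comma-joined tip sets.
#' @export
congruence_report <- function(trees, support_floor = 75) {
  if (length(trees) < 2L) stop("need at least two trees")
  shared <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  if (length(shared) < 2L) stop("fewer than 2 taxa shared across trees")
  pruned <- lapply(trees, function(tr) {
    drop <- setdiff(tr$tip.label, shared)
    if (length(drop)) tr <- ape::drop.tip(tr, drop)
    tr
  })
  per_tree <- lapply(pruned, function(tr) {
    if (length(tr$tip.label) < 4L || is.null(tr$node.label))
      return(data.frame(split = character(), support = numeric()))
    ns <- tree_splits(tr, with_nodes = TRUE)
    ns$support <- node_support(tr)
    ns <- ns[!is.na(ns$split) & !is.na(ns$support) &
               ns$support >= support_floor, c("split", "support")]
    ns[!duplicated(ns$split), , drop = FALSE]
  })
  out <- data.frame(tree_a = integer(), tree_b = integer(),
                    split_a = character(), split_b = character(),
                    support_a = numeric(), support_b = numeric())
  pretty <- function(s) gsub("\r", ",", s, fixed = TRUE)
  for (i in seq_along(per_tree)) {
    for (j in seq_along(per_tree)) {
      if (j <= i) next
      si <- per_tree[[i]]; sj <- per_tree[[j]]
      for (a in seq_len(nrow(si))) for (b in seq_len(nrow(sj))) {
        if (splits_incompatible(si$split[a], sj$split[b], shared)) {
          out <- rbind(out, data.frame(
            tree_a = i, tree_b = j,
            split_a = pretty(si$split[a]), split_b = pretty(sj$split[b]),
            support_a = si$support[a], support_b = sj$support[b]))
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}
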