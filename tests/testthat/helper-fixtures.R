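# shared fixtures built in code: tiny alignments, random additive trees,
# and an independent (graph-based) monophyly oracle

make_alignment <- function(seqs, locus = "test") new_alignment(seqs, locus)

random_additive_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, br = function(k) runif(k, 0.1, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tr
}

# independent monophyly oracle: tip set S forms one side of a bipartition
# iff deleting some edge disconnects exactly S from the rest (components
# computed with igraph, not with the package's split machinery)
oracle_monophyletic <- function(tree, tips) {
  n <- length(tree$tip.label)
  k <- length(tips)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  for (e in seq_len(nrow(tree$edge))) {
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership
    side <- tree$tip.label[comp[as.character(seq_len(n))] == 1]
    if (setequal(side, tips) || setequal(setdiff(tree$tip.label, side), tips))
      return(TRUE)
  }
  FALSE
}

# support-annotated quartet tree from a newick string with node labels
quartet_tree <- function(text) ape::read.tree(text = text)

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
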