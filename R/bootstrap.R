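# ---- bipartition utilities --------------------------------------------------

# canonical string for the split side not containing the reference tip
# (the alphabetically first label of the universe); trivial splits -> NA
canonical_split <- function(side, universe) {
  ref <- sort(universe)[1L]
  if (ref %in% side) side <- setdiff(universe, side)
  if (length(side) < 2L || length(side) > length(universe) - 2L)
    return(NA_character_)
  paste(sort(side), collapse = "\r")
}

# all non-trivial splits of a tree, as canonical strings; optionally the
# mapping from internal node number to split
tree_splits <- function(tree, with_nodes = FALSE) {
  universe <- tree$tip.label
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  nodes <- seq_along(parts) + length(universe)  # prop.part order: root first
  splits <- vapply(parts, function(idx)
    canonical_split(labels[idx], universe), NA_character_)
  if (with_nodes) data.frame(node = nodes, split = splits,
                             stringsAsFactors = FALSE)
  else unique(splits[!is.na(splits)])
}

split_sides <- function(split, universe) {
  side <- strsplit(split, "\r", fixed = TRUE)[[1]]
  list(side = side, other = setdiff(universe, side))
}

# two splits over the same taxon set conflict iff all four pairwise
# intersections of their sides are non-empty
splits_incompatible <- function(split_a, split_b, universe) {
  a <- split_sides(split_a, universe)
  b <- split_sides(split_b, universe)
  all(length(intersect(a$side, b$side)) > 0,
      length(intersect(a$side, b$other)) > 0,
      length(intersect(a$other, b$side)) > 0,
      length(intersect(a$other, b$other)) > 0)
}

# does tip set `tips` form one side of a bipartition of the unrooted tree?
# (size 1 and size n-1 subsets are trivially monophyletic)
is_monophyletic_unrooted <- function(tree, tips) {
  universe <- tree$tip.label
  stopifnot(all(tips %in% universe))
  k <- length(tips)
  if (k <= 1L || k >= length(universe) - 1L) return(TRUE)
  cs <- canonical_split(tips, universe)
  cs %in% tree_splits(tree)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Nonparametric bootstrap support for a neighbor-joining tree
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement \code{n_reps} times, rebuilding distances and the NJ tree
#' per replicate, and maps onto each internal edge of the full-data tree
#' the percentage of replicates whose tree contains the same bipartition.
#' Supports are stored as internal node labels (the usual Newick dialect
#' for bootstrap values); trivial edges get an empty label.
#'
#' @param x A \code{locus_alignment} or \code{supermatrix}.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param model Distance model, see \code{\link{pairwise_distance}}.
#' @param seed Integer seed; a fixed seed reproduces supports exactly, and
#'   supports are invariant to the input order of taxa.
#' @return The full-data NJ tree (\code{ape::phylo}) with \code{node.label}
#'   carrying supports in percent and attribute \code{n_reps}.
#' @export
bootstrap_support <- function(x, n_reps, model = "JC69", seed) {
  if (inherits(x, "supermatrix")) x <- x$alignment
  stopifnot(inherits(x, "locus_alignment"))
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  L <- x$n_columns
  if (L < 1L) stop("alignment has no columns to resample")

  # canonical taxon order so supports do not depend on input order
  x$seqs <- x$seqs[order(names(x$seqs))]
  main <- nj_tree(dist_matrix(x, model))
  node_splits <- tree_splits(main, with_nodes = TRUE)
  uniq <- node_splits$split[!is.na(node_splits$split)]
  counts <- stats::setNames(integer(length(uniq)), uniq)

  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_tree <- nj_tree(dist_matrix(x, model, columns = cols))
      found <- tree_splits(rep_tree)
      hit <- names(counts)[names(counts) %in% found]
      counts[hit] <- counts[hit] + 1L
    }
  })

  supp <- 100 * counts[node_splits$split] / n_reps
  main$node.label <- ifelse(is.na(node_splits$split), "",
                            format_support(supp))
  attr(main, "n_reps") <- n_reps
  main
}

format_support <- function(x) {
  ifelse(is.na(x), "", sub("\\.0+$", "", sprintf("%.4g", x)))
}

node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Read or write a support-annotated Newick tree
#'
#' The default dialect stores bootstrap supports as internal node labels
#' (as RAxML writes them); \code{dialect = "comment"} instead expects or
#' emits supports in square-bracket comments after the closing parenthesis,
#' e.g. \code{(A,B)[97]}. Unlabelled internal nodes mean "support absent",
#' never 0.
#'
#' @param path File path.
#' @param dialect \code{"label"} or \code{"comment"}.
#' @return \code{read_support_tree}: an \code{ape::phylo}.
#' @export
read_support_tree <- function(path, dialect = c("label", "comment")) {
  dialect <- match.arg(dialect)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (dialect == "comment")
    txt <- gsub("\\)\\[([0-9.]+)\\]", ")\\1", txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  tree
}

#' @param tree An \code{ape::phylo}, optionally with support node labels.
#' @rdname read_support_tree
#' @export
write_support_tree <- function(tree, path, dialect = c("label", "comment")) {
  dialect <- match.arg(dialect)
  txt <- ape::write.tree(tree)
  if (dialect == "comment")
    txt <- gsub("\\)([0-9.]+)", ")[\\1]", txt)
  writeLines(txt, path)
  invisible(path)
}
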