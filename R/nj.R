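#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining with the Saitou–Nei Q-criterion. On an additive
#' distance matrix the generating tree is recovered exactly, topology and
#' branch lengths. Ties in the minimal Q value are broken by joining the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest tip). Negative branch-length estimates are clamped to
#' zero with the deficit transferred to the sister edge, preserving the
#' joined pair's distance.
#'
#' @param distances Square symmetric numeric matrix with zero diagonal and
#'   tip labels as dimnames (or a \code{dist} object), at least 3 taxa.
#' @return Unrooted \code{ape::phylo} tree with branch lengths.
#' @export
nj_tree <- function(distances) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    stop("distances must be a square matrix")
  n <- nrow(distances)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(distances) %||% colnames(distances)
  if (is.null(labs)) stop("distance matrix must carry tip labels")
  if (any(grepl("[ ,():;\\[\\]]", labs)))
    stop("tip labels must not contain Newick metacharacters or spaces")
  if (max(abs(distances - t(distances))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(diag(distances) != 0)) stop("diagonal must be zero")
  if (any(distances < 0)) stop("distances must be non-negative")

  D <- distances
  nwk <- labs           # Newick fragment per active cluster
  rep_lab <- labs       # smallest member tip, for deterministic tie-breaks
  dimnames(D) <- NULL

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]

    d_iu <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    d_ju <- D[i, j] - d_iu
    if (d_iu < 0) { d_ju <- D[i, j]; d_iu <- 0 }
    if (d_ju < 0) { d_iu <- D[i, j]; d_ju <- 0 }

    new_nwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], d_iu, nwk[j], d_ju)
    new_rep <- min(rep_lab[i], rep_lab[j])
    keep <- setdiff(seq_len(m), c(i, j))
    new_d <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    new_d[new_d < 0] <- 0

    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d),
               c(new_d, 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
  }

  # final three clusters joined at a central (unresolved) node
  da <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  db <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  dc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  da <- max(da, 0); db <- max(db, 0); dc <- max(dc, 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nwk[1], da, nwk[2], db, nwk[3], dc)
  ape::read.tree(text = txt)
}
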