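#' Pairwise evolutionary distance between two aligned sequences
#'
#' Distances are computed over the columns where both residues are plain
#' nucleotides (\code{A C G T}): gaps, \code{N} and \code{?} padding are
#' excluded pairwise, so partial-taxon supermatrix rows still yield usable
#' distances. Models: \code{p} (raw mismatch proportion), \code{JC69}
#' (\code{-3/4 log(1 - 4p/3)}) and \code{K2P} (Kimura two-parameter from
#' transition and transversion proportions).
#'
#' @param seq_a,seq_b Equal-length aligned sequences (character scalars).
#' @param model One of \code{"p"}, \code{"JC69"}, \code{"K2P"}.
#' @return Distance in substitutions/site.
#' @export
#' @examples
#' pairwise_distance("ACGTACGTAC", "ACGTACGTTT", "p")    # 0.2
pairwise_distance <- function(seq_a, seq_b, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) stop("no comparable columns (pairwise deletion removed all)")
  a <- a[ok]; b <- b[ok]
  mism <- a != b
  p <- sum(mism) / n
  if (model == "p") return(p)
  if (model == "JC69") {
    if (p >= 0.75) stop("JC69 saturation: p = ", signif(p, 4), " >= 3/4")
    return(-0.75 * log(1 - 4 * p / 3))
  }
  purine <- c("A", "G")
  ts <- mism & (a %in% purine) == (b %in% purine)  # A<->G, C<->T
  P <- sum(ts) / n
  Q <- p - P
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("K2P saturation: log argument non-positive")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' All pairwise distances for an alignment
#'
#' Vectorized over the whole alignment using base-indicator cross-products,
#' so bootstrap replicates on resampled column sets are cheap.
#'
#' @param alignment A \code{locus_alignment} (or \code{supermatrix}).
#' @param model Substitution model, as in \code{\link{pairwise_distance}}.
#' @param columns Optional integer vector of column indices (with
#'   repetition allowed), e.g. a bootstrap resample; default all columns.
#' @return Square symmetric numeric matrix with tip labels as dimnames.
#' @export
dist_matrix <- function(alignment, model = c("p", "JC69", "K2P"),
                        columns = NULL) {
  model <- match.arg(model)
  if (inherits(alignment, "supermatrix")) alignment <- alignment$alignment
  stopifnot(inherits(alignment, "locus_alignment"))
  m <- alignment_matrix(alignment)
  if (!is.null(columns)) {
    if (!length(columns)) stop("no columns to compare")
    m <- m[, columns, drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  X <- lapply(bases, function(b) (m == b) * 1)
  valid <- Reduce(`+`, X)
  compared <- tcrossprod(valid)
  matches <- Reduce(`+`, lapply(X, tcrossprod))
  mism <- compared - matches
  off <- upper.tri(compared)
  if (any(compared[off] == 0))
    stop("no comparable columns for at least one taxon pair")
  p <- mism / compared
  d <- switch(model,
    p = p,
    JC69 = {
      if (any(p[off] >= 0.75)) stop("JC69 saturation in distance matrix")
      -0.75 * log(1 - 4 * p / 3)
    },
    K2P = {
      ts <- tcrossprod(X[[1]], X[[3]]) + tcrossprod(X[[3]], X[[1]]) +
            tcrossprod(X[[2]], X[[4]]) + tcrossprod(X[[4]], X[[2]])
      P <- ts / compared
      Q <- p - P
      w1 <- 1 - 2 * P - Q
      w2 <- 1 - 2 * Q
      if (any(w1[off] <= 0) || any(w2[off] <= 0))
        stop("K2P saturation in distance matrix")
      -0.5 * log(w1) - 0.25 * log(w2)
    })
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
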