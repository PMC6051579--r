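ALIGN_ALPHABET <- c("A", "C", "G", "T", "-", "N", "?")

#' Create an aligned-locus object from named sequences
#'
#' @param seqs Named character vector of equal-length aligned sequences over
#'   the alphabet \code{A C G T - N ?} (case-insensitive).
#' @param locus_name Locus label (e.g. "ITS").
#' @return Object of class \code{locus_alignment} with elements
#'   \code{locus}, \code{seqs}, \code{n_columns}.
#' @export
new_alignment <- function(seqs, locus_name) {
  if (!length(seqs)) stop("alignment is empty")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be labelled")
  if (anyDuplicated(names(seqs)))
    stop("duplicate tip label(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(w), collapse = ", "))
  if (w[1] == 0L) stop("alignment has zero columns")
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  if (length(bad <- setdiff(letters_used, ALIGN_ALPHABET)))
    stop("invalid residue(s): ", paste(bad, collapse = ", "))
  structure(list(locus = locus_name, seqs = seqs, n_columns = unname(w[1])),
            class = "locus_alignment")
}

#' Read an aligned multi-FASTA file
#'
#' @param path Path to an aligned (equal-width) multi-FASTA file.
#' @param locus_name Locus label to attach.
#' @return A \code{\link{new_alignment}} object.
#' @export
read_alignment <- function(path, locus_name) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1L)
  new_alignment(seqs, locus_name)
}

#' @param alignment A \code{locus_alignment}.
#' @rdname read_alignment
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "locus_alignment"))
  set <- Biostrings::BStringSet(alignment$seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment>", x$locus, ":", length(x$seqs), "sequences x",
      x$n_columns, "columns\n")
  invisible(x)
}

# alignment as a tips x columns character matrix
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$seqs, ""))
  rownames(m) <- names(alignment$seqs)
  m
}

#' Concatenate per-locus alignments into a partitioned supermatrix
#'
#' Taxa are taken as the union across loci; a taxon absent from a locus is
#' padded with \code{?} over that locus block. The partition table records
#' 1-based inclusive column coordinates per locus, tiling the supermatrix
#' without gaps or overlap.
#'
#' @param alignments Non-empty list of \code{locus_alignment} objects.
#' @return Object of class \code{supermatrix}: \code{alignment} (the
#'   concatenated \code{locus_alignment}) and \code{partitions} (data frame
#'   \code{locus}, \code{start}, \code{end}).
#' @export
concatenate_loci <- function(alignments) {
  if (!length(alignments)) stop("need at least one alignment")
  stopifnot(all(vapply(alignments, inherits, TRUE, "locus_alignment")))
  loci <- vapply(alignments, `[[`, "", "locus")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  taxa <- unique(unlist(lapply(alignments, function(a) names(a$seqs))))
  lens <- vapply(alignments, `[[`, 0L, "n_columns")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rows <- vapply(taxa, function(tx) {
    paste(vapply(alignments, function(a) {
      if (tx %in% names(a$seqs)) a$seqs[[tx]]
      else strrep("?", a$n_columns)
    }, ""), collapse = "")
  }, "")
  names(rows) <- taxa
  structure(list(
    alignment = new_alignment(rows, "concat"),
    partitions = data.frame(locus = loci, start = as.integer(starts),
                            end = as.integer(ends))),
    class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix>", length(x$alignment$seqs), "taxa x",
      x$alignment$n_columns, "columns;", nrow(x$partitions), "partitions\n")
  invisible(x)
}

#' Extract one locus block from a supermatrix
#'
#' @param supermatrix A \code{\link{concatenate_loci}} result.
#' @param locus Locus name from the partition table.
#' @param drop_missing Drop taxa whose block is entirely \code{?} padding
#'   (default TRUE), recovering the original per-locus taxon set.
#' @return A \code{locus_alignment}.
#' @export
slice_supermatrix <- function(supermatrix, locus, drop_missing = TRUE) {
  stopifnot(inherits(supermatrix, "supermatrix"))
  p <- supermatrix$partitions
  i <- match(locus, p$locus)
  if (is.na(i)) stop("no such locus in partition table: ", locus)
  block <- substr(supermatrix$alignment$seqs, p$start[i], p$end[i])
  if (drop_missing) {
    pad <- strrep("?", p$end[i] - p$start[i] + 1L)
    block <- block[block != pad]
  }
  new_alignment(block, locus)
}

#' Write or read a RAxML-style partition table
#'
#' One line per locus of the form \code{DNA, ITS = 1-521}, 1-based
#' inclusive coordinates.
#'
#' @param supermatrix A \code{supermatrix} (for writing).
#' @param path File path.
#' @return \code{read_partitions}: data frame \code{locus}, \code{start},
#'   \code{end}.
#' @export
write_partitions <- function(supermatrix, path) {
  p <- supermatrix$partitions
  writeLines(sprintf("DNA, %s = %d-%d", p$locus, p$start, p$end), path)
  invisible(path)
}

#' @rdname write_partitions
#' @export
read_partitions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec(
    "^\\s*DNA\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  if (any(vapply(m, length, 0L) != 4L))
    stop("malformed partition line(s)")
  data.frame(locus = vapply(m, `[[`, "", 2L),
             start = as.integer(vapply(m, `[[`, "", 3L)),
             end = as.integer(vapply(m, `[[`, "", 4L)))
}
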