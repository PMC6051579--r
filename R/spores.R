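#' Basidiospore shape index and Q-ratio
#'
#' The spore shape index (SSI) is \code{100 * width / length}: the
#' percentage of the spore length explained by its width, so rounder spores
#' score near 100 and elongated spores score low. The Q-ratio is the
#' complementary \code{length / width} ratio. Both are computed per spore;
#' for each spore \code{SSI * Q == 100} exactly.
#'
#' @param length,width Spore dimensions in micrometres (positive; length is
#'   measured base to truncated apex, width at the widest point). Vectorized.
#' @return Numeric vector: SSI in percent, or Q as a unitless ratio.
#' @export
#' @examples
#' spore_shape_index(10.6, 6.4)  # 60.4 at one decimal
#' q_ratio(10.6, 6.4)            # 1.7 at one decimal
spore_shape_index <- function(length, width) {
  check_dims(length, width)
  100 * width / length
}

#' @rdname spore_shape_index
#' @export
q_ratio <- function(length, width) {
  check_dims(length, width)
  length / width
}

check_dims <- function(length, width) {
  if (!is.numeric(length) || !is.numeric(width))
    stop("spore dimensions must be numeric")
  if (any(is.na(length)) || any(is.na(width)) ||
      any(length <= 0) || any(width <= 0))
    stop("spore dimensions must be positive")
  if (any(width > length))
    warning("width exceeds length for some spores; unusual for this group")
  invisible(NULL)
}

#' Summarize per-spore measurements for one taxon or collection
#'
#' Means, ranges, mean SSI and mean Q over a set of per-spore measurements.
#' SSI and Q are averaged per spore (mean of ratios), not computed from the
#' mean dimensions: published per-taxon values are per-spore averages, and
#' the ratio of means generally differs in the second decimal.
#'
#' @param measurements Data frame with columns \code{length_um} and
#'   \code{width_um} (optionally \code{specimen_id}, \code{spore_id}).
#' @param round_dp Decimal places for the returned summary (default 1,
#'   matching the published reporting style); use \code{NULL} to disable.
#' @param group_labels Optional externally computed means-separation labels
#'   (e.g. Tukey HSD letters) carried through to reports; not computed here.
#' @return List of class \code{spore_summary}: \code{n}, \code{mean_length},
#'   \code{min_length}, \code{max_length}, \code{mean_width},
#'   \code{min_width}, \code{max_width}, \code{mean_ssi}, \code{mean_q}.
#' @export
summarize_spores <- function(measurements, round_dp = 1, group_labels = NULL) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0L)
    stop("measurements must be a non-empty data frame")
  need <- c("length_um", "width_um")
  if (length(miss <- setdiff(need, names(measurements))))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  len <- measurements$length_um
  wid <- measurements$width_um
  check_dims(len, wid)
  rd <- if (is.null(round_dp)) identity else function(x) round_half_away(x, round_dp)
  out <- list(n = nrow(measurements),
              mean_length = rd(mean(len)),
              min_length = rd(min(len)),
              max_length = rd(max(len)),
              mean_width = rd(mean(wid)),
              min_width = rd(min(wid)),
              max_width = rd(max(wid)),
              mean_ssi = rd(mean(spore_shape_index(len, wid))),
              mean_q = rd(mean(q_ratio(len, wid))),
              group_labels = group_labels)
  structure(out, class = "spore_summary")
}

#' Format a spore summary in the standard "mean (min-max)" style
#'
#' @param summary A \code{spore_summary}.
#' @param axis \code{"length"} or \code{"width"}.
#' @return Character scalar, e.g. \code{"10.6 (8.3-12.1)"}.
#' @export
format_spore_summary <- function(summary, axis = c("length", "width")) {
  axis <- match.arg(axis)
  sprintf("%s (%s–%s)",
          summary[[paste0("mean_", axis)]],
          summary[[paste0("min_", axis)]],
          summary[[paste0("max_", axis)]])
}

#' @export
print.spore_summary <- function(x, ...) {
  cat("<spore_summary> n =", x$n, "\n")
  cat("  length:", format_spore_summary(x, "length"), "um\n")
  cat("  width: ", format_spore_summary(x, "width"), "um\n")
  cat("  SSI:", x$mean_ssi, "  Q:", x$mean_q, "\n")
  invisible(x)
}

#' Read or write a per-spore measurement table
#'
#' Tab-separated with columns \code{specimen_id}, \code{spore_id},
#' \code{length_um}, \code{width_um}.
#'
#' @param path File path.
#' @return \code{read_spores}: validated data frame.
#' @export
read_spores <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("specimen_id", "spore_id", "length_um", "width_um")
  if (length(miss <- setdiff(need, names(tab))))
    stop("spore table missing column(s): ", paste(miss, collapse = ", "))
  check_dims(tab$length_um, tab$width_um)
  tab
}

#' @param measurements Data frame as returned by \code{read_spores}.
#' @rdname read_spores
#' @export
write_spores <- function(measurements, path) write_tsv_strict(measurements, path)

#' Shipped per-taxon spore statistics (means and printed ranges)
#'
#' Mean, minimum and maximum basidiospore length and width per taxon, plus
#' the published per-taxon mean SSI and Q for reference. These parameters
#' seed the truncated-normal spore simulator.
#'
#' @return Data frame keyed by \code{species}.
#' @export
spore_parameters <- function() {
  tab <- read_tsv_strict(extdata_path("spore_parameters.tsv"))
  assert_species(tab$species)
  tab
}
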