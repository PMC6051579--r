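CLADE_STATUSES <- c("supported", "monophyletic_below_threshold",
                    "resolved_unscored", "not_resolved", "not_tested")

#' Support thresholds for calling a terminal clade well supported
#'
#' @param ml_bs_floor Bootstrap support floor in percent (default 75; the
#'   comparison is \code{>=}).
#' @param pp_floor Posterior-probability floor in percent (default 95),
#'   applied only when a second, posterior support annotation is supplied.
#' @return List of class \code{support_thresholds}.
#' @export
support_thresholds <- function(ml_bs_floor = 75, pp_floor = 95) {
  stopifnot(ml_bs_floor >= 0, ml_bs_floor <= 100,
            pp_floor >= 0, pp_floor <= 100)
  structure(list(ml_bs_floor = ml_bs_floor, pp_floor = pp_floor),
            class = "support_thresholds")
}

#' Construct per-species terminal-clade records
#'
#' @param species Character vector of taxon labels.
#' @param status One of \code{supported},
#'   \code{monophyletic_below_threshold}, \code{resolved_unscored},
#'   \code{not_resolved}, \code{not_tested} per species.
#' @param score Bootstrap support in percent; required exactly for the two
#'   scored statuses, \code{NA} otherwise.
#' @return Data frame of class \code{clade_records}.
#' @export
clade_records <- function(species, status, score = NA_real_) {
  assert_species(species)
  if (length(bad <- setdiff(status, CLADE_STATUSES)))
    stop("invalid status value(s): ", paste(bad, collapse = ", "))
  score <- rep_len(as.numeric(score), length(species))
  scored <- status %in% c("supported", "monophyletic_below_threshold")
  if (any(scored & is.na(score)))
    stop("scored statuses require a score")
  if (any(!scored & !is.na(score)))
    stop("score present for an unscored status")
  if (any(score[scored] < 0 | score[scored] > 100))
    stop("scores must lie in [0, 100]")
  structure(data.frame(species = species, status = status, score = score,
                       stringsAsFactors = FALSE),
            class = c("clade_records", "data.frame"))
}

#' Parse printed support-table cells into clade records
#'
#' Cell vocabulary: a number is the bootstrap support of a resolved terminal
#' clade (classified against the floor); \code{NR} is a non-resolved clade;
#' \code{R*} (also printed \code{NR*} in some columns) is a clade resolved
#' as a single-sample lineage for which no support could be computed;
#' \code{NT} means the taxon had no sequence for that locus.
#'
#' @param cells Character vector of cells.
#' @param species Taxon per cell.
#' @param thresholds A \code{\link{support_thresholds}}.
#' @return A \code{\link{clade_records}} data frame.
#' @export
parse_support_cells <- function(cells, species,
                                thresholds = support_thresholds()) {
  cells <- trimws(as.character(cells))
  status <- character(length(cells))
  score <- rep(NA_real_, length(cells))
  num <- suppressWarnings(as.numeric(cells))
  is_num <- !is.na(num)
  status[is_num] <- ifelse(num[is_num] >= thresholds$ml_bs_floor,
                           "supported", "monophyletic_below_threshold")
  score[is_num] <- num[is_num]
  status[cells %in% c("R*", "NR*")] <- "resolved_unscored"
  status[cells == "NR"] <- "not_resolved"
  status[cells == "NT"] <- "not_tested"
  if (any(!nzchar(status)))
    stop("unrecognized cell value(s): ",
         paste(unique(cells[!nzchar(status)]), collapse = ", "))
  clade_records(species, status, score)
}

#' Assess per-species terminal-clade resolution on a support tree
#'
#' For each species in the taxon map: a species absent from the tree is
#' \code{not_tested}; a single-tip species is a resolved lineage without a
#' support value (\code{resolved_unscored}); a multi-tip species whose tips
#' form one side of a tree bipartition (unrooted monophyly, so placement
#' relative to the root is immaterial) is \code{supported} when the
#' subtending support meets the floor, \code{monophyletic_below_threshold}
#' when below it, and \code{not_resolved} when the edge carries no support;
#' a non-monophyletic species is \code{not_resolved}.
#'
#' @param tree Support-annotated \code{ape::phylo} (supports as node
#'   labels, percent).
#' @param map Data frame with columns \code{tip_label} and \code{species};
#'   every tree tip must be mapped (an unmapped tip is an error naming the
#'   tip). Species present in the map but absent from the tree are reported
#'   \code{not_tested}.
#' @param thresholds A \code{\link{support_thresholds}}.
#' @param outgroup_tips Optional tips excluded from the bipartition
#'   universe when testing ingroup species (their own species, if mapped,
#'   is still assessed on the full tree).
#' @return A \code{\link{clade_records}} data frame, one row per species in
#'   the map (map order).
#' @export
assess_terminal_clades <- function(tree, map,
                                   thresholds = support_thresholds(),
                                   outgroup_tips = NULL) {
  stopifnot(is.data.frame(map), all(c("tip_label", "species") %in% names(map)))
  unmapped <- setdiff(tree$tip.label, map$tip_label)
  if (length(unmapped))
    stop("unmapped tip label(s): ", paste(unmapped, collapse = ", "))
  assert_species(map$species)
  species <- unique(map$species)
  ingroup_tree <- tree
  if (length(outgroup_tips)) {
    if (length(bad <- setdiff(outgroup_tips, tree$tip.label)))
      stop("outgroup tip(s) absent from tree: ", paste(bad, collapse = ", "))
    if (length(tree$tip.label) - length(outgroup_tips) >= 3L)
      ingroup_tree <- ape::drop.tip(tree, outgroup_tips)
  }
  out <- lapply(species, function(sp) {
    tips <- map$tip_label[map$species == sp]
    use_tree <- if (any(tips %in% (outgroup_tips %||% character())))
      tree else ingroup_tree
    tips <- intersect(tips, use_tree$tip.label)
    if (!length(tips)) return(list(status = "not_tested", score = NA_real_))
    if (length(tips) == 1L)
      return(list(status = "resolved_unscored", score = NA_real_))
    if (!is_monophyletic_unrooted(use_tree, tips))
      return(list(status = "not_resolved", score = NA_real_))
    supp <- clade_support(use_tree, tips)
    if (is.na(supp)) return(list(status = "not_resolved", score = NA_real_))
    if (supp >= thresholds$ml_bs_floor)
      list(status = "supported", score = supp)
    else list(status = "monophyletic_below_threshold", score = supp)
  })
  clade_records(species,
                vapply(out, `[[`, "", "status"),
                vapply(out, `[[`, 0, "score"))
}

# support on the edge subtending the bipartition tips | rest: the node label
# of the internal node whose descendant set equals tips or its complement
clade_support <- function(tree, tips) {
  universe <- tree$tip.label
  target <- canonical_split(tips, universe)
  if (is.na(target)) return(NA_real_)  # trivial edge carries no support
  ns <- tree_splits(tree, with_nodes = TRUE)
  supp <- node_support(tree)
  hit <- which(ns$split == target)
  if (!length(hit)) return(NA_real_)
  supp[ns$node[hit[1]] - length(universe)]
}

#' Score one locus from its terminal-clade records
#'
#' The locus score pair is: the number of terminal clades — species
#' resolved either as a supported multi-tip clade or as a single-sample
#' lineage (\code{resolved_unscored}) — and the total score, the sum of
#' bootstrap supports of the well-supported clades only. A monophyletic
#' clade below the floor contributes to neither number. Records carrying a
#' score are (re)classified against the supplied floor, so the same records
#' can be scored under different thresholds.
#'
#' @param records A \code{\link{clade_records}} data frame (one row per
#'   species; duplicates are an error).
#' @param thresholds A \code{\link{support_thresholds}}.
#' @param locus_name Optional locus label carried into the result.
#' @return List of class \code{locus_score}: \code{locus_name},
#'   \code{n_terminal_clades}, \code{total_score}.
#' @export
score_locus <- function(records, thresholds = support_thresholds(),
                        locus_name = NA_character_) {
  stopifnot(is.data.frame(records),
            all(c("species", "status", "score") %in% names(records)))
  if (anyDuplicated(records$species))
    stop("duplicate species record(s): ",
         paste(unique(records$species[duplicated(records$species)]),
               collapse = ", "))
  has_score <- !is.na(records$score)
  supported <- has_score & records$score >= thresholds$ml_bs_floor
  singles <- records$status == "resolved_unscored"
  structure(list(
    locus_name = locus_name,
    n_terminal_clades = sum(supported) + sum(singles),
    total_score = sum(records$score[supported])),
    class = "locus_score")
}

#' @export
print.locus_score <- function(x, ...) {
  cat(sprintf("<locus_score> %s: %d terminal clades, total score %g\n",
              x$locus_name, x$n_terminal_clades, x$total_score))
  invisible(x)
}

#' Rank candidate barcode loci by resolving power
#'
#' Orders loci by decreasing number of terminal clades, ties broken by
#' decreasing total bootstrap score, then alphabetically by locus name.
#'
#' @param scores List of \code{\link{score_locus}} results.
#' @return Data frame \code{locus_name}, \code{n_terminal_clades},
#'   \code{total_score} in rank order.
#' @export
rank_loci <- function(scores) {
  if (!length(scores)) stop("need at least one locus score")
  df <- data.frame(
    locus_name = vapply(scores, `[[`, "", "locus_name"),
    n_terminal_clades = vapply(scores, `[[`, 0, "n_terminal_clades"),
    total_score = vapply(scores, `[[`, 0, "total_score"))
  df <- df[order(-df$n_terminal_clades, -df$total_score,
                 tolower(df$locus_name), method = "radix"), ]
  rownames(df) <- NULL
  df
}

#' Assemble and serialize a taxa-by-loci score report
#'
#' Cells use the printed vocabulary (a support value, \code{NR}, \code{R*},
#' \code{NT}); two summary rows, \code{TOTAL SCORE} and
#' \code{NUMBER OF TERMINAL CLADES}, are computed per locus via
#' \code{\link{score_locus}}.
#'
#' @param records_by_locus Named list of \code{\link{clade_records}}, all
#'   over the same species set.
#' @param thresholds A \code{\link{support_thresholds}}.
#' @return Data frame: first column \code{species} (taxa then the two
#'   summary rows), one column per locus.
#' @export
score_table_report <- function(records_by_locus,
                               thresholds = support_thresholds()) {
  stopifnot(length(records_by_locus) >= 1L, !is.null(names(records_by_locus)))
  species <- records_by_locus[[1]]$species
  for (rec in records_by_locus)
    if (!identical(sort(rec$species), sort(species)))
      stop("all loci must cover the same species set")
  cell <- function(rec, sp) {
    row <- rec[rec$species == sp, ]
    switch(row$status,
           supported = ,
           monophyletic_below_threshold = format_support(row$score),
           resolved_unscored = "R*",
           not_resolved = "NR",
           not_tested = "NT")
  }
  out <- data.frame(species = c(species, "TOTAL SCORE",
                                "NUMBER OF TERMINAL CLADES"),
                    stringsAsFactors = FALSE)
  for (locus in names(records_by_locus)) {
    rec <- records_by_locus[[locus]]
    sc <- score_locus(rec, thresholds, locus)
    out[[locus]] <- c(vapply(species, function(sp) cell(rec, sp), ""),
                      format_support(sc$total_score),
                      format_support(sc$n_terminal_clades))
  }
  out
}

#' @param report Data frame as produced by \code{score_table_report} (for
#'   writing), or a file path (for reading).
#' @param path File path.
#' @rdname score_table_report
#' @export
write_score_report <- function(report, path) write_tsv_strict(report, path)

#' Parse a score report back into per-locus clade records
#'
#' @rdname score_table_report
#' @export
read_score_report <- function(path, thresholds = support_thresholds()) {
  tab <- read_tsv_strict(path, colClasses = "character")
  body <- tab[!tab$species %in% c("TOTAL SCORE", "NUMBER OF TERMINAL CLADES"), ]
  loci <- setdiff(names(tab), "species")
  stats::setNames(lapply(loci, function(lc)
    parse_support_cells(body[[lc]], body$species, thresholds)), loci)
}

#' Published per-locus terminal-clade support values for the US survey
#'
#' The shipped taxa-by-loci table of RAxML bootstrap supports (1000
#' replicates, GTR) for the terminal clades of the 13 US laccate taxa under
#' ITS, tef1a, rpb1, rpb2 and the four-locus concatenated analysis, as
#' published in the national survey this package's scoring scheme comes
#' from. Cells follow the \code{\link{parse_support_cells}} vocabulary.
#'
#' @return Data frame: \code{species} plus one character column per locus.
#' @export
barcode_support_scores <- function() {
  tab <- read_tsv_strict(extdata_path("barcode_support_scores.tsv"),
                         colClasses = "character")
  assert_species(tab$species)
  tab
}
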