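#' The thirteen laccate Ganoderma taxa recognized in the United States
#'
#' Controlled vocabulary of admissible species labels: twelve *Ganoderma*
#' species plus *Tomophagus colossus*, with *G. curtisii* f.sp.
#' *meredithiae* carried as a distinct taxon (a physiological variant of
#' *G. curtisii* restricted to pines).
#'
#' @return Character vector of the 13 canonical taxon labels.
#' @export
#' @examples
#' ganoderma_species()
ganoderma_species <- function() {
  c("G. curtisii",
    "G. curtisii f.sp. meredithiae",
    "G. lucidum",
    "G. martinicense",
    "G. oregonense",
    "G. polychromum",
    "G. ravenelii",
    "G. sessile",
    "G. tsugae",
    "G. tuberculosum",
    "G. cf. weberianum",
    "G. zonatum",
    "T. colossus")
}

assert_species <- function(x) {
  bad <- setdiff(unique(x), ganoderma_species())
  if (length(bad))
    stop("inadmissible species label(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

host_groups <- function() c("hardwood", "conifer", "monocot", "cycad", "cactus")

regions <- function() {
  c("eastern_US", "western_US", "pacific_northwest", "subtropical",
    "restricted_UT_CA")
}

#' Classify a free-text context-tissue color term
#'
#' Context tissue color falls into three diagnostic classes: white,
#' pinkish-buff to cinnamon-buff (light brown, "buff"), or cinnamon brown
#' (dark brown). Terms are matched case-insensitively against a shipped,
#' editable synonym table of standard color names; an unmapped term is an
#' error rather than a guess.
#'
#' @param description Character vector of color terms (non-empty).
#' @return Character vector over \code{c("white", "buff", "dark_brown")}.
#' @export
#' @examples
#' classify_context_color(c("white", "pinkish-buff", "cinnamon brown"))
classify_context_color <- function(description) {
  if (length(description) == 0L || any(!nzchar(trimws(description))))
    stop("color description must be non-empty")
  syn <- color_synonyms()
  key <- normalize_color_term(description)
  out <- syn$class[match(key, syn$term)]
  if (anyNA(out)) {
    stop("unknown color term(s): ",
         paste(unique(description[is.na(out)]), collapse = ", "))
  }
  out
}

color_synonyms <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- read_tsv_strict(extdata_path("context_color_synonyms.tsv"))
      tab$term <- normalize_color_term(tab$term)
      # the three classes are themselves valid terms (idempotence)
      cls <- c("white", "buff", "dark_brown")
      extra <- !cls %in% tab$term
      if (any(extra))
        tab <- rbind(tab, data.frame(term = cls[extra], class = cls[extra]))
      cache <<- tab
    }
    cache
  }
})

normalize_color_term <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[–—]", "-", x)
  gsub("[[:space:]]+", " ", x)
}

#' Tally collections per species with printed-style percentages
#'
#' Summarizes collection records (or pre-aggregated counts) into per-species
#' counts and percentages of a stated total, using round-half-away-from-zero
#' so small classes reproduce published figures (e.g. 142 of 507 prints as
#' 28\%). A one-decimal mode is available for rare classes.
#'
#' @param records Data frame of collection records with a \code{species}
#'   column, or a pre-aggregated data frame with \code{species} and
#'   \code{count} columns.
#' @param total Denominator for percentages; defaults to the sum of counts.
#' @param digits Rounding precision for percentages (0 = integer, the
#'   printed default; 1 = one-decimal mode).
#' @return Data frame with columns \code{species}, \code{count},
#'   \code{percent}, ordered by decreasing count.
#' @export
tally_species <- function(records, total = NULL, digits = 0) {
  if (!is.data.frame(records) || !"species" %in% names(records))
    stop("records must be a data frame with a 'species' column")
  assert_species(records$species)
  if ("count" %in% names(records)) {
    counts <- records[, c("species", "count")]
  } else {
    agg <- table(records$species)
    counts <- data.frame(species = names(agg), count = as.integer(agg))
  }
  if (any(counts$count < 0)) stop("counts must be non-negative")
  total <- total %||% sum(counts$count)
  if (!is.numeric(total) || total <= 0) stop("total must be positive")
  if (total < sum(counts$count))
    stop("total (", total, ") is smaller than the sum of counts (",
         sum(counts$count), ")")
  counts$percent <- round_half_away(100 * counts$count / total, digits)
  counts[order(-counts$count, counts$species), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Tally host-substrate groups among collections with known hosts
#'
#' Percentages are taken over the known-host subtotal, not the full
#' collection count, with the same rounding contract as
#' \code{\link{tally_species}}.
#'
#' @param records Data frame with a \code{host_group} column (all known), or
#'   pre-aggregated with \code{host_group} and \code{count}.
#' @param digits Rounding precision (0 or 1).
#' @return Data frame with \code{host_group}, \code{count}, \code{percent}.
#' @export
tally_host_groups <- function(records, digits = 0) {
  if (!is.data.frame(records) || !"host_group" %in% names(records) ||
      nrow(records) == 0L)
    stop("records must be a non-empty data frame with a 'host_group' column")
  if (anyNA(records$host_group))
    stop("all records must have a known host_group")
  bad <- setdiff(unique(records$host_group), host_groups())
  if (length(bad)) stop("unknown host group(s): ", paste(bad, collapse = ", "))
  if ("count" %in% names(records)) {
    counts <- records[, c("host_group", "count")]
  } else {
    agg <- table(records$host_group)
    counts <- data.frame(host_group = names(agg), count = as.integer(agg))
  }
  total <- sum(counts$count)
  if (total <= 0) stop("no records with known host")
  counts$percent <- round_half_away(100 * counts$count / total, digits)
  counts[order(-counts$count, counts$host_group), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Shipped per-species counts of the 507-collection US survey
#'
#' @return Data frame with \code{species} and \code{count} (summing to 507).
#' @export
us_collection_counts <- function() {
  tab <- read_tsv_strict(extdata_path("us_collection_counts.tsv"))
  assert_species(tab$species)
  tab
}

# ---- collection records -----------------------------------------------------

#' Read or write a collections table
#'
#' Tab-separated, UTF-8, header required; columns \code{collection_id},
#' \code{species}, \code{state}, \code{host_genus}, \code{host_group},
#' \code{herbarium}. Missing values are literal \code{NA}, never "".
#'
#' @param path File path.
#' @return \code{read_collections}: validated data frame.
#' @export
read_collections <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("collection_id", "species", "state", "host_genus", "host_group",
            "herbarium")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("collections table missing column(s): ",
                         paste(miss, collapse = ", "))
  assert_species(tab$species)
  st <- tab$state[!is.na(tab$state)]
  if (length(st) && any(!st %in% c(datasets::state.abb, "DC", "PR")))
    stop("invalid US state code(s): ",
         paste(setdiff(st, c(datasets::state.abb, "DC", "PR")), collapse = ", "))
  hg <- tab$host_group[!is.na(tab$host_group)]
  if (length(bad <- setdiff(hg, host_groups())))
    stop("unknown host group(s): ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(tab$herbarium, c("field", "FLAS", "NCSCLG"))))
    stop("unknown herbarium code(s): ", paste(bad, collapse = ", "))
  tab
}

#' @param records Data frame as returned by \code{read_collections}.
#' @rdname read_collections
#' @export
write_collections <- function(records, path) {
  assert_species(records$species)
  write_tsv_strict(records, path)
}
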