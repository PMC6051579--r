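#' Load and validate a dichotomous identification key
#'
#' The key is data, not code: a YAML file of numbered couplets, each with
#' exactly two leads, where a lead is a conjunction of predicates over
#' \code{\link{character_profile}} fields and either forwards to another
#' couplet or terminates at a taxon. Loading verifies structure: two leads
#' per couplet, no cycles, no dangling couplet references, and every taxon
#' reachable from couplet 1.
#'
#' @param path Path to a key YAML file; defaults to the shipped 12-couplet
#'   key to the laccate *Ganoderma* of the United States.
#' @return Object of class \code{ganoderma_key}.
#' @export
load_key <- function(path = extdata_path("ganoderma_us_key.yaml")) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$couplets) || !length(raw$couplets))
    stop("key file contains no couplets")
  ids <- vapply(raw$couplets, function(cp) as.integer(cp$id), integer(1))
  if (anyDuplicated(ids)) stop("duplicate couplet id(s): ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  couplets <- stats::setNames(raw$couplets, as.character(ids))
  for (cp in couplets) {
    if (length(cp$leads) != 2L)
      stop("couplet ", cp$id, " must have exactly two leads")
    for (ld in cp$leads) {
      if (is.null(ld$goto) == is.null(ld$species))
        stop("couplet ", cp$id,
             ": each lead needs exactly one of 'goto' or 'species'")
      if (!is.null(ld$species)) assert_species(ld$species)
      if (!is.null(ld$goto) && !as.character(ld$goto) %in% names(couplets))
        stop("couplet ", cp$id, ": dangling reference to couplet ", ld$goto)
      if (!length(ld$predicates))
        stop("couplet ", cp$id, ": lead has no predicates")
    }
  }
  key <- structure(list(couplets = couplets, root = min(ids)),
                   class = "ganoderma_key")
  check_acyclic(key)
  reach <- reachable_species(key, key$root)
  unreach <- setdiff(key_species(key), reach)
  if (length(unreach))
    stop("taxa unreachable from couplet ", key$root, ": ",
         paste(unreach, collapse = ", "))
  key
}

key_species <- function(key) {
  sort(unique(unlist(lapply(key$couplets, function(cp)
    unlist(lapply(cp$leads, `[[`, "species"))))))
}

check_acyclic <- function(key) {
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    id <- as.character(id)
    s <- state[[id]] %||% "white"
    if (s == "grey") stop("cycle detected through couplet ", id)
    if (s == "black") return(invisible(NULL))
    state[[id]] <- "grey"
    for (ld in key$couplets[[id]]$leads)
      if (!is.null(ld$goto)) visit(ld$goto)
    state[[id]] <- "black"
  }
  for (id in names(key$couplets)) visit(id)
  invisible(key)
}

reachable_species <- function(key, from) {
  out <- character()
  stack <- as.character(from)
  seen <- character()
  while (length(stack)) {
    id <- stack[[1]]; stack <- stack[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    for (ld in key$couplets[[id]]$leads) {
      if (!is.null(ld$species)) out <- c(out, ld$species)
      else stack <- c(stack, as.character(ld$goto))
    }
  }
  sort(unique(out))
}

#' @export
print.ganoderma_key <- function(x, ...) {
  cat("<ganoderma_key>", length(x$couplets), "couplets,",
      length(key_species(x)), "taxa\n")
  invisible(x)
}

# three-valued predicate evaluation: TRUE / FALSE / NA (undecidable)
eval_predicate <- function(pred, profile) {
  ch <- pred$character
  if (identical(ch, "pores_per_mm")) {
    lo <- profile$pores_min; hi <- profile$pores_max
    if (is.na(lo) || is.na(hi)) return(NA)
    return(lo <= pred$max && hi >= pred$min)  # interval overlap
  }
  v <- profile[[ch]]
  if (is.null(v) || is.na(v)) return(NA)
  if (!is.null(pred$ambiguous_values) && v %in% pred$ambiguous_values)
    return(NA)
  switch(pred$op,
         eq = v == pred$value,
         neq = v != pred$value,
         in_set = v %in% pred$values,
         lt = v < pred$value,
         range = v >= pred$min && v <= pred$max,
         stop("unknown predicate op: ", pred$op))
}

# conjunction with FALSE dominant over NA
lead_verdict <- function(lead, profile) {
  vals <- vapply(lead$predicates, function(p) {
    r <- eval_predicate(p, profile)
    if (is.na(r)) NA else r
  }, logical(1))
  if (any(!vals, na.rm = TRUE)) list(verdict = FALSE, missing = character())
  else if (anyNA(vals))
    list(verdict = NA,
         missing = vapply(lead$predicates[is.na(vals)], `[[`, "", "character"))
  else list(verdict = TRUE, missing = character())
}

#' Identify a specimen from its character profile
#'
#' Deterministic traversal of the key from couplet 1. At each couplet the
#' two leads are evaluated with three-valued logic: when exactly one lead is
#' true the traversal follows it; when a consulted character is missing, or
#' when neither lead can be affirmed (e.g. a spore mean outside both printed
#' ranges), both leads are followed and the result is the union of
#' candidates. The result always contains at least one taxon; a profile
#' with no informative characters returns all 13.
#'
#' @param profile A \code{\link{character_profile}}.
#' @param key A \code{\link{load_key}} result (defaults to the shipped key).
#' @return Object of class \code{identification_result} with elements
#'   \code{candidates} (taxon labels), \code{trace} (data frame of
#'   \code{couplet_id}, \code{lead} in \code{c("a","b","both")}), and
#'   \code{unresolved_characters}.
#' @export
#' @examples
#' key <- load_key()
#' identify_specimen(character_profile(context_color = "white",
#'   host_group = "conifer", region = "pacific_northwest",
#'   spore_length_mean = 12.9, spore_width_mean = 8.0), key)
identify_specimen <- function(profile, key = load_key()) {
  stopifnot(inherits(profile, "character_profile"))
  validate_profile(profile)
  candidates <- character()
  unresolved <- character()
  trace <- data.frame(couplet_id = integer(), lead = character())
  queue <- key$root
  seen <- integer()
  while (length(queue)) {
    id <- queue[[1]]; queue <- queue[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    cp <- key$couplets[[as.character(id)]]
    va <- lead_verdict(cp$leads[[1]], profile)
    vb <- lead_verdict(cp$leads[[2]], profile)
    take <- if (isTRUE(va$verdict) && isFALSE(vb$verdict)) "a"
            else if (isTRUE(vb$verdict) && isFALSE(va$verdict)) "b"
            else "both"
    unresolved <- c(unresolved, va$missing, vb$missing)
    trace <- rbind(trace, data.frame(couplet_id = as.integer(cp$id), lead = take))
    leads <- switch(take, a = cp$leads[1], b = cp$leads[2], both = cp$leads)
    for (ld in leads) {
      if (!is.null(ld$species)) candidates <- c(candidates, ld$species)
      else queue <- c(queue, as.integer(ld$goto))
    }
  }
  structure(list(
    candidates = ganoderma_species()[ganoderma_species() %in% candidates],
    trace = trace,
    unresolved_characters = sort(unique(unresolved))),
    class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat("<identification_result>\n  candidates:",
      paste(x$candidates, collapse = ", "), "\n")
  cat("  trace:", paste(sprintf("%d%s", x$trace$couplet_id,
                                ifelse(x$trace$lead == "both", "(ab)",
                                       x$trace$lead)), collapse = " -> "), "\n")
  if (length(x$unresolved_characters))
    cat("  unresolved:", paste(x$unresolved_characters, collapse = ", "), "\n")
  invisible(x)
}

# unique key path to a species: list of (couplet_id, lead_index)
key_path <- function(key, species) {
  parent <- list()
  terminal <- NULL
  for (cp in key$couplets) {
    for (i in 1:2) {
      ld <- cp$leads[[i]]
      if (!is.null(ld$goto))
        parent[[as.character(ld$goto)]] <- list(id = as.integer(cp$id), lead = i)
      else if (identical(ld$species, species))
        terminal <- list(id = as.integer(cp$id), lead = i)
    }
  }
  if (is.null(terminal)) stop("species not in key: ", species)
  path <- list(terminal)
  cur <- as.character(terminal$id)
  while (!is.null(parent[[cur]])) {
    path <- c(list(parent[[cur]]), path)
    cur <- as.character(parent[[cur]]$id)
  }
  path
}

#' Characters that separate two taxa in the key
#'
#' Finds the first couplet at which the key paths of the two taxa diverge
#' and returns the characters consulted by that couplet's two leads.
#'
#' @param species_a,species_b Taxon labels present in the key.
#' @param key A \code{ganoderma_key}.
#' @return List with \code{couplet_id} (integer, or \code{NA} for identical
#'   taxa) and \code{characters} (character vector, empty for identical
#'   taxa).
#' @export
distinguishing_characters <- function(species_a, species_b, key = load_key()) {
  assert_species(c(species_a, species_b))
  if (identical(species_a, species_b))
    return(list(couplet_id = NA_integer_, characters = character()))
  pa <- key_path(key, species_a)
  pb <- key_path(key, species_b)
  for (i in seq_len(min(length(pa), length(pb)))) {
    if (pa[[i]]$id != pb[[i]]$id || pa[[i]]$lead != pb[[i]]$lead) {
      cp <- key$couplets[[as.character(pa[[i]]$id)]]
      chars <- unique(unlist(lapply(cp$leads, function(ld)
        vapply(ld$predicates, `[[`, "", "character"))))
      return(list(couplet_id = as.integer(cp$id), characters = chars))
    }
  }
  stop("key paths of distinct taxa never diverge; invalid key")
}
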