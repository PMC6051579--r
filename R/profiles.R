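profile_fields <- function() {
  c("specimen_id", "context_color", "melanoid_deposits", "concentric_zones",
    "contextual_chlamydospores", "culture_chlamydospores", "stipe_class",
    "pores_min", "pores_max", "host_group", "region", "growth_rate_class",
    "spore_length_mean", "spore_width_mean", "pileus_notes")
}

#' Construct a morphological character profile for one specimen
#'
#' A profile records the character states consulted by the identification
#' key. Every character may be missing (\code{NA}): missing means
#' "unobserved", which the key treats differently from an observed "absent"
#' state (e.g. \code{melanoid_deposits = "absent"}).
#'
#' @param specimen_id Specimen identifier.
#' @param context_color One of \code{white}, \code{buff}, \code{dark_brown}.
#' @param melanoid_deposits,concentric_zones,contextual_chlamydospores,culture_chlamydospores
#'   \code{"present"}, \code{"absent"} or \code{NA}.
#' @param stipe_class \code{stipitate} (stipe at least as long as the pileus
#'   is wide), \code{pseudostipitate} (shorter stipe) or \code{sessile}.
#' @param pores_min,pores_max Pores/mm interval bounds (positive, ordered).
#' @param host_group One of \code{hardwood}, \code{conifer}, \code{monocot},
#'   \code{cycad}, \code{cactus}.
#' @param region One of \code{eastern_US}, \code{western_US},
#'   \code{pacific_northwest}, \code{subtropical}, \code{restricted_UT_CA}.
#' @param growth_rate_class \code{fast} (~6 mm/day on malt extract agar) or
#'   \code{slow} (<3 mm/day).
#' @param spore_length_mean,spore_width_mean Mean basidiospore dimensions in
#'   micrometres (length: base to truncated apex; width: widest point).
#' @param pileus_notes Free text.
#' @return Object of class \code{character_profile}.
#' @export
character_profile <- function(specimen_id = NA_character_,
                              context_color = NA,
                              melanoid_deposits = NA,
                              concentric_zones = NA,
                              contextual_chlamydospores = NA,
                              culture_chlamydospores = NA,
                              stipe_class = NA,
                              pores_min = NA,
                              pores_max = NA,
                              host_group = NA,
                              region = NA,
                              growth_rate_class = NA,
                              spore_length_mean = NA,
                              spore_width_mean = NA,
                              pileus_notes = NA_character_) {
  p <- list(specimen_id = as.character(specimen_id),
            context_color = as.character(context_color),
            melanoid_deposits = as.character(melanoid_deposits),
            concentric_zones = as.character(concentric_zones),
            contextual_chlamydospores = as.character(contextual_chlamydospores),
            culture_chlamydospores = as.character(culture_chlamydospores),
            stipe_class = as.character(stipe_class),
            pores_min = as.numeric(pores_min),
            pores_max = as.numeric(pores_max),
            host_group = as.character(host_group),
            region = as.character(region),
            growth_rate_class = as.character(growth_rate_class),
            spore_length_mean = as.numeric(spore_length_mean),
            spore_width_mean = as.numeric(spore_width_mean),
            pileus_notes = as.character(pileus_notes))
  validate_profile(p)
  structure(p, class = "character_profile")
}

validate_profile <- function(p) {
  chk_enum <- function(field, allowed) {
    v <- p[[field]]
    if (!is.na(v) && !v %in% allowed)
      stop("invalid ", field, ": '", v, "' (allowed: ",
           paste(allowed, collapse = ", "), ")")
  }
  chk_enum("context_color", c("white", "buff", "dark_brown"))
  for (f in c("melanoid_deposits", "concentric_zones",
              "contextual_chlamydospores", "culture_chlamydospores"))
    chk_enum(f, c("present", "absent"))
  chk_enum("stipe_class", c("stipitate", "pseudostipitate", "sessile"))
  chk_enum("host_group", host_groups())
  chk_enum("region", regions())
  chk_enum("growth_rate_class", c("fast", "slow"))
  if (!is.na(p$pores_min) && !is.na(p$pores_max)) {
    if (p$pores_min <= 0 || p$pores_max < p$pores_min)
      stop("pores/mm interval must be positive and ordered")
  } else if (xor(is.na(p$pores_min), is.na(p$pores_max))) {
    stop("pores_min and pores_max must be given together")
  }
  for (f in c("spore_length_mean", "spore_width_mean"))
    if (!is.na(p[[f]]) && p[[f]] <= 0) stop(f, " must be positive")
  invisible(p)
}

#' @export
print.character_profile <- function(x, ...) {
  cat("<character_profile>", if (!is.na(x$specimen_id)) x$specimen_id, "\n")
  for (f in setdiff(profile_fields(), c("specimen_id", "pileus_notes"))) {
    v <- x[[f]]
    if (!all(is.na(v))) cat("  ", f, ": ", paste(v, collapse = "-"), "\n", sep = "")
  }
  invisible(x)
}

#' Reference character profiles for the 13 US laccate taxa
#'
#' Loads the shipped per-taxon reference profiles (context color and
#' features, stipe class, pores/mm, host, region, growth rate where
#' diagnostic, and mean spore dimensions). Each reference profile identifies
#' exactly its own taxon through the shipped key.
#'
#' @param path Optional path to an alternative profiles YAML file.
#' @return Named list of \code{character_profile}, one per taxon.
#' @export
reference_profiles <- function(path = extdata_path("reference_profiles.yaml")) {
  raw <- yaml::read_yaml(path)
  assert_species(names(raw))
  if (!setequal(names(raw), ganoderma_species()))
    stop("reference profile set must contain all 13 taxa exactly once")
  out <- lapply(names(raw), function(sp) {
    f <- raw[[sp]]
    character_profile(
      specimen_id = sp,
      context_color = f$context_color %||% NA,
      melanoid_deposits = f$melanoid_deposits %||% NA,
      concentric_zones = f$concentric_zones %||% NA,
      contextual_chlamydospores = f$contextual_chlamydospores %||% NA,
      culture_chlamydospores = f$culture_chlamydospores %||% NA,
      stipe_class = f$stipe_class %||% NA,
      pores_min = f$pores_min %||% NA,
      pores_max = f$pores_max %||% NA,
      host_group = f$host_group %||% NA,
      region = f$region %||% NA,
      growth_rate_class = f$growth_rate_class %||% NA,
      spore_length_mean = f$spore_length_mean %||% NA,
      spore_width_mean = f$spore_width_mean %||% NA,
      pileus_notes = f$pileus_notes %||% NA)
  })
  names(out) <- names(raw)
  out[ganoderma_species()]
}
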