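#' Configuration for the synthetic multilocus study generator
#'
#' Defaults emulate the dimensions of the US laccate *Ganoderma* survey:
#' 13 species with 1–8 representatives each, four loci of 521/764/615/570
#' aligned columns (ITS, tef1a, rpb1, rpb2), species-level divergence deep
#' enough (0.15 expected substitutions/site between species vs 0.005
#' within) that planted species clades are recoverable with high bootstrap
#' support, and a designated two-tip outgroup species mirroring the two
#' *Tomophagus colossus* isolates used for rooting.
#'
#' @param n_species Number of species (>= 3).
#' @param tips_per_species Integer range \code{c(min, max)} of
#'   representatives per species.
#' @param loci Named integer vector of locus lengths (columns).
#' @param between_species_depth Expected substitutions/site separating
#'   species on the species tree.
#' @param within_species_depth Substitutions/site of the shallow within-
#'   species radiation (must be < between).
#' @param seed Master integer seed; named substreams (tree, sequences,
#'   spores, profiles) are derived from it so each component can be
#'   regenerated independently.
#' @param species_names Species labels (defaults to the 13 US taxa).
#' @param outgroup Which species is the two-tip outgroup (default the last).
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_species = 13,
                       tips_per_species = c(1, 8),
                       loci = c(ITS = 521, tef1a = 764, rpb1 = 615,
                                rpb2 = 570),
                       between_species_depth = 0.15,
                       within_species_depth = 0.005,
                       seed = 1,
                       species_names = ganoderma_species(),
                       outgroup = NULL) {
  stopifnot(n_species >= 3, length(species_names) >= n_species,
            all(loci > 0), between_species_depth > 0,
            within_species_depth > 0,
            within_species_depth < between_species_depth,
            length(tips_per_species) == 2,
            tips_per_species[1] >= 1,
            tips_per_species[2] >= tips_per_species[1])
  species_names <- species_names[seq_len(n_species)]
  structure(list(n_species = n_species,
                 tips_per_species = as.integer(tips_per_species),
                 loci = loci,
                 between_species_depth = between_species_depth,
                 within_species_depth = within_species_depth,
                 seed = as.integer(seed),
                 species_names = species_names,
                 outgroup = outgroup %||% species_names[n_species]),
            class = "sim_config")
}

sanitize_label <- function(x) gsub("_+$", "", gsub("[^A-Za-z0-9]+", "_", x))

#' Simulate a species tree with planted within-species clades
#'
#' A species-level topology is drawn by sequential random joins (uniform
#' over labelled join orders); every species-tree edge gets a length of
#' \code{between_species_depth/2} jittered by Unif(0.5, 1.5). Each species
#' is then expanded into a shallow radiation of tips (pendant length
#' \code{within_species_depth}), so every multi-tip species is monophyletic
#' on the true tree by construction. The configured outgroup species always
#' has exactly two tips.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{planted_truth}: \code{tree}
#'   (\code{ape::phylo} with branch lengths), \code{map} (data frame
#'   \code{tip_label}, \code{species}), \code{outgroup_tips},
#'   \code{config}.
#' @export
simulate_species_tree <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_species < 3 || length(config$species_names) < 3)
    stop("n_species must be >= 3")
  with_seed(substream_seed(config$seed, "tree"), {
    sp <- config$species_names
    edge_len <- function(k)
      config$between_species_depth / 2 * stats::runif(k, 0.5, 1.5)
    tip_range <- config$tips_per_species[1]:config$tips_per_species[2]
    n_tips <- if (length(tip_range) == 1L) rep(tip_range, length(sp))
              else sample(tip_range, length(sp), replace = TRUE)
    n_tips[sp == config$outgroup] <- 2L
    map <- data.frame(
      tip_label = unlist(lapply(seq_along(sp), function(i)
        paste0(sanitize_label(sp[i]), "_", seq_len(n_tips[i])))),
      species = rep(sp, n_tips))
    crown <- vapply(seq_along(sp), function(i) {
      tips <- paste0(sanitize_label(sp[i]), "_", seq_len(n_tips[i]))
      if (n_tips[i] == 1L) tips
      else sprintf("(%s)", paste(sprintf("%s:%.12g", tips,
                                         config$within_species_depth),
                                 collapse = ","))
    }, "")
    nwk <- crown
    while (length(nwk) > 1L) {
      pair <- sample.int(length(nwk), 2L)
      lens <- edge_len(2L)
      joined <- sprintf("(%s:%.12g,%s:%.12g)",
                        nwk[pair[1]], lens[1], nwk[pair[2]], lens[2])
      nwk <- c(nwk[-pair], joined)
    }
    tree <- ape::read.tree(text = paste0(nwk, ";"))
    structure(list(tree = tree, map = map,
                   outgroup_tips = map$tip_label[map$species == config$outgroup],
                   config = config),
              class = "planted_truth")
  })
}

#' Evolve an alignment along a tree under Jukes–Cantor substitution
#'
#' The root sequence is i.i.d. uniform over \code{A C G T}; along each
#' branch of length \code{t} every site substitutes independently with
#' probability \code{p(t) = 3/4 (1 - exp(-4t/3))}, to one of the three
#' other bases uniformly. No indels, no rate heterogeneity.
#'
#' @param tree \code{ape::phylo} with branch lengths.
#' @param length Number of alignment columns (> 0).
#' @param seed Integer seed.
#' @param locus_name Locus label for the returned alignment.
#' @return A \code{\link{new_alignment}} over the tree's tips.
#' @export
evolve_alignment <- function(tree, length, seed, locus_name = "locus") {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (length < 1L) stop("alignment length must be positive")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample.int(4L, length, replace = TRUE)
    # cladewise edge order guarantees parents are simulated before children
    tree <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_len <- tree$edge.length[e]
      p_sub <- 0.75 * (1 - exp(-4 * t_len / 3))
      s <- seqs[[parent]]
      hit <- which(stats::runif(length) < p_sub)
      if (length(hit))
        s[hit] <- (s[hit] - 1L + sample.int(3L, length(hit),
                                            replace = TRUE)) %% 4L + 1L
      seqs[[child]] <- s
    }
    tips <- vapply(seq_len(n_tip), function(i)
      paste(bases[seqs[[i]]], collapse = ""), "")
    names(tips) <- tree$tip.label
    new_alignment(tips, locus_name)
  })
}

#' Simulate per-spore measurements for one taxon
#'
#' Lengths and widths are drawn independently from normal distributions
#' truncated to the published per-taxon (min, max) range, with the
#' published mean and sd = (max - min)/4 (keeping about 95\% of the
#' untruncated mass inside the range).
#'
#' @param species Taxon label with an entry in \code{params}.
#' @param n Number of spores (> 0).
#' @param seed Integer seed.
#' @param params Parameter table, defaulting to the shipped
#'   \code{\link{spore_parameters}}.
#' @return Data frame \code{specimen_id}, \code{spore_id},
#'   \code{length_um}, \code{width_um}.
#' @export
simulate_spores <- function(species, n, seed, params = spore_parameters()) {
  row <- params[params$species == species, ]
  if (nrow(row) != 1L) stop("unknown species: ", species)
  if (n < 1L) stop("n must be positive")
  with_seed(seed, {
    rtrunc <- function(n, mean, lo, hi) {
      sd <- (hi - lo) / 4
      stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                                stats::pnorm(hi, mean, sd)), mean, sd)
    }
    data.frame(
      specimen_id = paste0("sim_", sanitize_label(species)),
      spore_id = paste0("s", seq_len(n)),
      length_um = rtrunc(n, row$mean_length, row$min_length, row$max_length),
      width_um = rtrunc(n, row$mean_width, row$min_width, row$max_width))
  })
}

#' Generate noisy character profiles with known true species
#'
#' Starts from the reference profile of each taxon and independently masks
#' each observable character to missing with probability \code{noise_rate},
#' emulating incompletely observed specimens. At noise 0 every profile
#' identifies exactly its own taxon through the key; increasing noise can
#' only grow candidate sets (information loss is monotone).
#'
#' @param noise_rate Masking probability in [0, 1).
#' @param seed Integer seed.
#' @param profiles Base profiles (default \code{\link{reference_profiles}}).
#' @return Named list of \code{character_profile} (names = true species).
#' @export
generate_profiles <- function(noise_rate, seed,
                              profiles = reference_profiles()) {
  stopifnot(noise_rate >= 0, noise_rate < 1)
  maskable <- c("context_color", "melanoid_deposits", "concentric_zones",
                "contextual_chlamydospores", "culture_chlamydospores",
                "stipe_class", "pores", "host_group", "region",
                "growth_rate_class", "spores")
  with_seed(substream_seed(seed, "profiles"), {
    lapply(profiles, function(p) {
      drop <- maskable[stats::runif(length(maskable)) < noise_rate]
      if ("pores" %in% drop) p$pores_min <- p$pores_max <- NA_real_
      if ("spores" %in% drop)
        p$spore_length_mean <- p$spore_width_mean <- NA_real_
      for (f in setdiff(drop, c("pores", "spores"))) p[[f]] <- NA_character_
      p
    })
  })
}

#' Generate every synthetic input of a study (alignments, map, spores,
#' profiles)
#'
#' One call to produce the full planted-truth bundle: a species tree, one
#' evolved alignment per configured locus (each from its own derived
#' substream), the tip-to-species map, per-taxon spore measurements and
#' noiseless character profiles.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_spores Spores simulated per taxon with parameters available.
#' @return List of class \code{synthetic_study}: \code{truth},
#'   \code{alignments} (named list), \code{spores} (data frame with a
#'   \code{species} column), \code{profiles}.
#' @export
simulate_study <- function(config = sim_config(), n_spores = 30) {
  truth <- simulate_species_tree(config)
  alignments <- lapply(names(config$loci), function(locus)
    evolve_alignment(truth$tree, config$loci[[locus]],
                     substream_seed(config$seed, paste0("seq_", locus)),
                     locus))
  names(alignments) <- names(config$loci)
  params <- spore_parameters()
  sp_ok <- intersect(config$species_names, params$species)
  spores <- do.call(rbind, lapply(sp_ok, function(sp) {
    d <- simulate_spores(sp, n_spores,
                         substream_seed(config$seed, paste0("spore_", sp)))
    d$species <- sp
    d
  }))
  profiles <- generate_profiles(0, config$seed,
                                reference_profiles()[
                                  intersect(config$species_names,
                                            ganoderma_species())])
  structure(list(truth = truth, alignments = alignments, spores = spores,
                 profiles = profiles, config = config),
            class = "synthetic_study")
}
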