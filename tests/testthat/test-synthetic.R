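test_that("simulated species trees plant monophyletic species and a 2-tip outgroup", {
  cfg <- sim_config(seed = 11)
  truth <- simulate_species_tree(cfg)
  expect_s3_class(truth$tree, "phylo")
  expect_equal(nrow(truth$map), length(truth$tree$tip.label))
  expect_length(truth$outgroup_tips, 2)
  expect_equal(unique(truth$map$species[truth$map$tip_label %in%
                                          truth$outgroup_tips]),
               "T. colossus")
  for (sp in unique(truth$map$species)) {
    tips <- truth$map$tip_label[truth$map$species == sp]
    expect_true(ganokey:::is_monophyletic_unrooted(truth$tree, tips),
                info = sp)
  }
  # determinism
  truth2 <- simulate_species_tree(cfg)
  expect_equal(ape::write.tree(truth$tree), ape::write.tree(truth2$tree))
  expect_equal(truth$map, truth2$map)
  expect_error(simulate_species_tree(sim_config(n_species = 2)), "n_species")
})

test_that("three species with one tip each give the unique 3-taxon topology", {
  cfg <- sim_config(n_species = 3, tips_per_species = c(1, 1), seed = 2,
                    species_names = c("G. curtisii", "G. sessile",
                                      "T. colossus"))
  truth <- simulate_species_tree(cfg)
  # outgroup always gets 2 tips, the others 1: 4 tips total
  expect_equal(sort(table(truth$map$species), decreasing = TRUE)[[1]], 2)
  expect_equal(nrow(truth$map), 4)
})

test_that("sequence evolution matches the Jukes-Cantor closed form", {
  # two tips at total distance t = 0.3: expected p = (3/4)(1 - e^(-0.4))
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  L <- 100000
  aln <- evolve_alignment(tr, L, seed = 17)
  p_hat <- pairwise_distance(aln$seqs[["a"]], aln$seqs[["b"]], "p")
  p_exp <- 0.75 * (1 - exp(-0.4))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_hat - p_exp), 3 * se)

  # zero branch lengths: all sequences identical
  tr0 <- ape::read.tree(text = "(a:0,b:0,c:0);")
  aln0 <- evolve_alignment(tr0, 500, seed = 18)
  expect_equal(length(unique(aln0$seqs)), 1L)

  expect_equal(evolve_alignment(tr, 100, seed = 19)$seqs,
               evolve_alignment(tr, 100, seed = 19)$seqs)
  expect_error(evolve_alignment(tr, 0, seed = 19), "positive")
})

test_that("simulated spores stay in range and converge to the configured mean", {
  draws <- simulate_spores("G. curtisii", 10000, seed = 21)
  params <- spore_parameters()
  row <- params[params$species == "G. curtisii", ]
  expect_true(all(draws$length_um >= row$min_length &
                    draws$length_um <= row$max_length))
  expect_lt(abs(mean(draws$length_um) - row$mean_length),
            0.02 * row$mean_length)
  expect_lt(abs(mean(draws$width_um) - row$mean_width),
            0.02 * row$mean_width)
  expect_equal(simulate_spores("G. zonatum", 5, seed = 1),
               simulate_spores("G. zonatum", 5, seed = 1))
  expect_error(simulate_spores("G. zonatum", 0, seed = 1), "positive")
  expect_error(simulate_spores("nope", 5, seed = 1), "unknown species")
})

test_that("profile noise is deterministic and grows candidate sets", {
  key <- load_key()
  clean <- generate_profiles(0, seed = 31)
  expect_length(clean, 13)
  for (sp in names(clean))
    expect_identical(identify_specimen(clean[[sp]], key)$candidates, sp)

  expect_equal(generate_profiles(0.6, seed = 32),
               generate_profiles(0.6, seed = 32))

  # masking only loses information: candidate sets at high noise contain
  # the true taxon and are no smaller on average than at zero noise
  noisy <- generate_profiles(0.9, seed = 33)
  sizes <- vapply(names(noisy), function(sp) {
    cand <- identify_specimen(noisy[[sp]], key)$candidates
    expect_true(sp %in% cand)
    length(cand)
  }, 0L)
  expect_gte(mean(sizes), 1)
  expect_gt(max(sizes), 1)
})

test_that("substreams decouple the generator components", {
  cfg <- sim_config(seed = 5, n_species = 5)
  s1 <- simulate_study(cfg, n_spores = 5)
  s2 <- simulate_study(cfg, n_spores = 5)
  expect_equal(ape::write.tree(s1$truth$tree), ape::write.tree(s2$truth$tree))
  expect_equal(s1$alignments$ITS$seqs, s2$alignments$ITS$seqs)
  expect_equal(s1$spores, s2$spores)
  # different loci draw from different substreams
  expect_false(identical(substr(s1$alignments$ITS$seqs[[1]], 1, 100),
                         substr(s1$alignments$rpb1$seqs[[1]], 1, 100)))
})
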