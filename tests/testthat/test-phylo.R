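# ---- distances --------------------------------------------------------------

test_that("pairwise distances match closed forms and pairwise deletion rules", {
  expect_equal(pairwise_distance("ACGTACGT", "ACGTACGT", "p"), 0)
  expect_equal(pairwise_distance("ACGTACGT", "ACGTACGT", "JC69"), 0)
  expect_equal(pairwise_distance("ACGTACGT", "ACGTACGT", "K2P"), 0)

  # p = 0.3 -> JC69 = -0.75 log(0.6) = 0.3831 (4 d.p.)
  a <- strrep("A", 10)
  b <- paste0(strrep("C", 3), strrep("A", 7))
  expect_equal(pairwise_distance(a, b, "p"), 0.3)
  expect_equal(round(pairwise_distance(a, b, "JC69"), 4), 0.3831)

  # K2P closed form, computed independently here as the oracle:
  # 100 columns, 10 transitions (A<->G), 5 transversions (A<->C)
  sa <- strrep("A", 100)
  sb <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  P <- 0.10; Q <- 0.05
  expected <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(pairwise_distance(sa, sb, "K2P"), expected)

  # gap/N/? columns are deleted pairwise
  expect_equal(pairwise_distance("AC-T?", "ACNTA", "p"), 0)
  expect_error(pairwise_distance("----", "AAAA"), "no comparable")
  expect_error(pairwise_distance(strrep("A", 4), strrep("C", 4), "JC69"),
               "saturation")
  expect_error(pairwise_distance("AC", "ACG"), "equal length")
})

test_that("JC69 is monotone in p and ~p for small p", {
  p <- seq(0.01, 0.70, by = 0.01)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
  # at p = 1e-4 the correction is O(p^2)
  a <- strrep("A", 10000)
  b <- paste0("C", strrep("A", 9999))
  d_small <- pairwise_distance(a, b, "JC69")
  expect_equal(d_small, 1e-4, tolerance = 1e-3)
})

test_that("the vectorized distance matrix agrees with per-pair calls and ape", {
  set.seed(5)
  truth <- simulate_species_tree(sim_config(n_species = 5, seed = 5))
  aln <- evolve_alignment(truth$tree, 300, seed = 6)
  for (model in c("p", "JC69", "K2P")) {
    D <- dist_matrix(aln, model)
    labs <- rownames(D)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(D[i, j],
                   pairwise_distance(aln$seqs[[labs[i]]],
                                     aln$seqs[[labs[j]]], model))
    }
  }
  # independent cross-check against ape::dist.dna
  m <- do.call(rbind, strsplit(tolower(aln$seqs), ""))
  bin <- ape::as.DNAbin(m)
  expect_equal(dist_matrix(aln, "JC69")[rownames(m), rownames(m)],
               as.matrix(ape::dist.dna(bin, model = "JC69",
                                       pairwise.deletion = TRUE)),
               tolerance = 1e-12)
  expect_equal(dist_matrix(aln, "K2P")[rownames(m), rownames(m)],
               as.matrix(ape::dist.dna(bin, model = "K80",
                                       pairwise.deletion = TRUE)),
               tolerance = 1e-12)
})

# ---- neighbor joining -------------------------------------------------------

test_that("NJ recovers topology and branch lengths from additive matrices", {
  tr <- random_additive_tree(5, seed = 41)
  D <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(D)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), nj), 0)
  back <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
  expect_equal(back, D, tolerance = 1e-9)
})

test_that("NJ matches ape::nj topologies on noisy matrices", {
  set.seed(43)
  for (i in 1:10) {
    tr <- random_additive_tree(sample(4:10, 1), seed = 43 + i)
    D <- ape::cophenetic.phylo(tr)
    noise <- matrix(runif(length(D), 0, 0.02), nrow(D))
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    Dn <- D + noise
    expect_equal(phangorn::RF.dist(nj_tree(Dn), ape::nj(Dn)), 0)
  }
})

test_that("equal minimal Q values join the lexicographically smallest pair", {
  labs <- c("d", "c", "b", "a")
  D <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(D) <- 0
  tree <- nj_tree(D)  # fully tied: every pair has the same Q
  expect_true(ganokey:::is_monophyletic_unrooted(tree, c("a", "b")))
})

test_that("negative branch estimates are clamped with deficit transfer", {
  # a near-star matrix with one inconsistent entry forces a negative estimate
  labs <- c("a", "b", "c", "d")
  D <- matrix(c(0, 0.1, 1, 1,
                0.1, 0, 1, 1,
                1, 1, 0, 0.05,
                1, 1, 0.05, 0), 4, 4, dimnames = list(labs, labs))
  tree <- nj_tree(D)
  expect_true(all(tree$edge.length >= 0))
  # the joined pair's mutual distance is preserved through clamping
  cp <- ape::cophenetic.phylo(tree)
  expect_equal(cp["a", "b"], 0.1, tolerance = 1e-9)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  asym <- D; asym[1, 2] <- 0.4
  expect_error(nj_tree(asym), "symmetric")
})

# ---- bootstrap --------------------------------------------------------------

test_that("bootstrap supports are reproducible and taxon-order invariant", {
  truth <- simulate_species_tree(sim_config(n_species = 6, seed = 61))
  aln <- evolve_alignment(truth$tree, 400, seed = 62)
  t1 <- bootstrap_support(aln, n_reps = 25, seed = 99)
  t2 <- bootstrap_support(aln, n_reps = 25, seed = 99)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # permuted input order
  perm <- aln
  perm$seqs <- perm$seqs[rev(seq_along(perm$seqs))]
  t3 <- bootstrap_support(perm, n_reps = 25, seed = 99)
  expect_equal(ape::write.tree(t1), ape::write.tree(t3))
  # different seed still reproducible structure-wise
  expect_equal(attr(t1, "n_reps"), 25)
})

test_that("a single bootstrap replicate yields supports of 0 or 100", {
  truth <- simulate_species_tree(sim_config(n_species = 5, seed = 63))
  aln <- evolve_alignment(truth$tree, 200, seed = 64)
  tr <- bootstrap_support(aln, n_reps = 1, seed = 7)
  supp <- ganokey:::node_support(tr)
  expect_true(all(supp[!is.na(supp)] %in% c(0, 100)))
})

test_that("deeply separated clades get near-total support", {
  cfg <- sim_config(n_species = 4, tips_per_species = c(3, 3),
                    loci = c(L = 1000), seed = 65,
                    species_names = c("G. curtisii", "G. sessile",
                                      "G. tsugae", "T. colossus"))
  study <- simulate_study(cfg)
  tr <- bootstrap_support(study$alignments$L, n_reps = 100, seed = 66)
  for (sp in unique(study$truth$map$species)) {
    tips <- study$truth$map$tip_label[study$truth$map$species == sp]
    supp <- ganokey:::clade_support(tr, tips)
    expect_gte(supp, 95)
  }
})

# ---- rooting and congruence -------------------------------------------------

test_that("outgroup rooting places the root on the outgroup branch", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  rooted <- root_with_outgroup(tr, "e")
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("a", "b", "c", "d")))

  truth <- simulate_species_tree(sim_config(n_species = 6, seed = 67))
  rooted <- root_with_outgroup(truth$tree, truth$outgroup_tips)
  ingroup <- setdiff(truth$tree$tip.label, truth$outgroup_tips)
  expect_true(ape::is.monophyletic(rooted, ingroup))

  expect_error(root_with_outgroup(tr, c("a", "c")), "not monophyletic")
  expect_error(root_with_outgroup(tr, "zz"), "absent")
})

test_that("congruence screening flags only well-supported incompatibility", {
  t1 <- quartet_tree("((A:1,B:1)100:1,C:1,D:1);")
  t2 <- quartet_tree("((A:1,C:1)100:1,B:1,D:1);")
  t3 <- quartet_tree("((A:1,C:1)40:1,B:1,D:1);")

  expect_equal(nrow(congruence_report(list(t1, t1))), 0)
  conflict <- congruence_report(list(t1, t2), support_floor = 75)
  expect_equal(nrow(conflict), 1)
  expect_equal(conflict$support_a, 100)
  # one side below the floor -> no reportable conflict
  expect_equal(nrow(congruence_report(list(t1, t3), support_floor = 75)), 0)
  expect_error(congruence_report(list(t1)), "at least two")
})

test_that("per-locus trees from one synthetic study are congruent", {
  study <- simulate_study(sim_config(n_species = 7, seed = 71,
                                     loci = c(A = 400, B = 400)))
  trees <- lapply(names(study$alignments), function(lc)
    bootstrap_support(study$alignments[[lc]], n_reps = 50,
                      seed = 710 + match(lc, names(study$alignments))))
  expect_equal(nrow(congruence_report(trees, support_floor = 75)), 0)
})

test_that("support trees survive Newick round-trips in both dialects", {
  tr <- quartet_tree("((A:1,B:1)97:1,(C:1,D:1)88:1);")
  for (dialect in c("label", "comment")) {
    path <- withr::local_tempfile(fileext = ".nwk")
    write_support_tree(tr, path, dialect)
    back <- read_support_tree(path, dialect)
    expect_equal(back$node.label, tr$node.label)
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
  }
})
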