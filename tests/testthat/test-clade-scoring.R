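floor75 <- support_thresholds(ml_bs_floor = 75)

test_that("clade assessment classifies constructed trees correctly", {
  # species X: 3 tips in a clade with support 90; Y: 2 tips supported 60;
  # Z: single tip; W: mapped but absent from the tree
  tr <- ape::read.tree(
    text = "(((X1:1,X2:1,X3:1)90:1,(Y1:1,Y2:1)60:1)95:1,Z1:1,O1:1);")
  map <- data.frame(
    tip_label = c("X1", "X2", "X3", "Y1", "Y2", "Z1", "O1"),
    species = c(rep("G. curtisii", 3), rep("G. sessile", 2),
                "G. tsugae", "T. colossus"))
  rec <- assess_terminal_clades(tr, map, floor75)
  stat <- setNames(rec$status, rec$species)
  expect_equal(stat[["G. curtisii"]], "supported")
  expect_equal(rec$score[rec$species == "G. curtisii"], 90)
  expect_equal(stat[["G. sessile"]], "monophyletic_below_threshold")
  expect_equal(stat[["G. tsugae"]], "resolved_unscored")

  map2 <- rbind(map, data.frame(tip_label = "none", species = "G. zonatum"))
  rec2 <- assess_terminal_clades(tr, map2, floor75)
  expect_equal(rec2$status[rec2$species == "G. zonatum"], "not_tested")

  # non-monophyletic species
  map3 <- map
  map3$species[map3$tip_label == "X3"] <- "G. sessile"
  rec3 <- assess_terminal_clades(tr, map3, floor75)
  expect_equal(rec3$status[rec3$species == "G. sessile"], "not_resolved")

  expect_error(assess_terminal_clades(tr, map[-1, ], floor75), "X1")
})

test_that("monophyly decisions match brute-force bipartition enumeration", {
  set.seed(83)
  for (n in 4:8) {
    tr <- ape::rtree(n)
    tr$tip.label <- letters[seq_len(n)]
    tr <- ape::unroot(tr)
    tipsets <- unlist(lapply(2:(n - 1), function(k)
      combn(tr$tip.label, k, simplify = FALSE)), recursive = FALSE)
    for (S in tipsets) {
      expect_equal(ganokey:::is_monophyletic_unrooted(tr, S),
                   oracle_monophyletic(tr, S),
                   info = paste(n, paste(S, collapse = "")))
    }
  }
})

test_that("species straddling the root still score via the bipartition test", {
  # rooted display places O1+O2 basal; A's tips sit on both sides of the
  # root-adjacent edge in the rooted drawing but form one unrooted split
  tr <- ape::read.tree(text = "((A1:1,A2:1)88:1,(B1:1,B2:1)91:1);")
  map <- data.frame(tip_label = c("A1", "A2", "B1", "B2"),
                    species = rep(c("G. curtisii", "G. sessile"), each = 2))
  rec <- assess_terminal_clades(tr, map, floor75)
  expect_true(all(rec$status == "supported"))
})

test_that("score_locus reproduces the published locus scores", {
  tab <- barcode_support_scores()
  expected <- list(ITS = c(8, 761), tef1a = c(12, 970), rpb1 = c(11, 955),
                   rpb2 = c(8, 564), concat = c(12, 1141))
  for (locus in names(expected)) {
    rec <- parse_support_cells(tab[[locus]], tab$species, floor75)
    sc <- score_locus(rec, floor75, locus)
    expect_equal(sc$n_terminal_clades, expected[[locus]][1], info = locus)
    expect_equal(sc$total_score, expected[[locus]][2], info = locus)
  }
})

test_that("score_locus degenerate and linearity cases", {
  empty <- clade_records(character(), character())
  sc <- score_locus(empty, floor75)
  expect_equal(sc$n_terminal_clades, 0)
  expect_equal(sc$total_score, 0)

  five <- clade_records(ganoderma_species()[1:5], rep("supported", 5),
                        rep(100, 5))
  sc5 <- score_locus(five, floor75)
  expect_equal(sc5$n_terminal_clades, 5)
  expect_equal(sc5$total_score, 500)

  dup <- clade_records(rep("G. sessile", 2), rep("supported", 2), c(90, 91))
  expect_error(score_locus(dup, floor75), "duplicate")
})

test_that("score_locus is permutation invariant and additive over subsets", {
  tab <- barcode_support_scores()
  rec <- parse_support_cells(tab$ITS, tab$species, floor75)
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(score_locus(shuf, floor75)$total_score,
               score_locus(rec, floor75)$total_score)
  half <- seq_len(6)
  a <- score_locus(rec[half, ], floor75)
  b <- score_locus(rec[-half, ], floor75)
  whole <- score_locus(rec, floor75)
  expect_equal(a$total_score + b$total_score, whole$total_score)
  expect_equal(a$n_terminal_clades + b$n_terminal_clades,
               whole$n_terminal_clades)
})

test_that("raising the support floor never increases either score", {
  tab <- barcode_support_scores()
  for (locus in c("ITS", "tef1a", "rpb1", "rpb2", "concat")) {
    rec <- parse_support_cells(tab[[locus]], tab$species, floor75)
    prev <- score_locus(rec, support_thresholds(0), locus)
    for (f in c(25, 50, 75, 90, 100)) {
      cur <- score_locus(rec, support_thresholds(f), locus)
      expect_lte(cur$n_terminal_clades, prev$n_terminal_clades)
      expect_lte(cur$total_score, prev$total_score)
      prev <- cur
    }
  }
})

test_that("locus ranking follows clade count, then score, then name", {
  tab <- barcode_support_scores()
  scores <- lapply(c("ITS", "tef1a", "rpb1", "rpb2", "concat"), function(lc)
    score_locus(parse_support_cells(tab[[lc]], tab$species, floor75),
                floor75, lc))
  ranked <- rank_loci(scores)
  expect_equal(ranked$locus_name,
               c("concat", "tef1a", "rpb1", "ITS", "rpb2"))
  expect_equal(rank_loci(scores[1])$locus_name, "ITS")
  # full tie resolves alphabetically (case-insensitive)
  tie <- list(score_locus(clade_records("G. sessile", "supported", 90),
                          floor75, "beta"),
              score_locus(clade_records("G. sessile", "supported", 90),
                          floor75, "Alpha"))
  expect_equal(rank_loci(tie)$locus_name, c("Alpha", "beta"))
})

test_that("score reports round-trip through TSV with published cells", {
  tab <- barcode_support_scores()
  recs <- lapply(c(ITS = "ITS", rpb2 = "rpb2"), function(lc)
    parse_support_cells(tab[[lc]], tab$species, floor75))
  report <- score_table_report(recs, floor75)
  expect_equal(report$ITS[report$species == "TOTAL SCORE"], "761")
  expect_equal(report$ITS[report$species == "NUMBER OF TERMINAL CLADES"], "8")
  expect_equal(report$rpb2[report$species == "TOTAL SCORE"], "564")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_report(report, path)
  back <- read_score_report(path, floor75)
  for (lc in names(recs))
    expect_equal(as.data.frame(back[[lc]]), as.data.frame(recs[[lc]]))

  all_nt <- clade_records(ganoderma_species(), rep("not_tested", 13))
  sc <- score_locus(all_nt, floor75)
  expect_equal(c(sc$n_terminal_clades, sc$total_score), c(0, 0))
})
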