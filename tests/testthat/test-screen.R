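# Marker-based screening: coding density, genetic-code choice, taxon calls,
# contamination counts, dereplication.

test_that("coding density counts overlapping intervals once", {
  expect_equal(coding_density(cds_interval_set(11, cbind(0, 900), 1000)), 0.9)
  # union of (0,50) and (25,75) covers 75 bp (expected value frozen from
  # enumerating covered positions)
  expect_equal(
    coding_density(cds_interval_set(1, rbind(c(0, 50), c(25, 75)), 100)), 0.75)
  expect_equal(
    coding_density(cds_interval_set(4, matrix(numeric(0), ncol = 2), 100)), 0)
})

test_that("coding density is invariant under reordering and splitting", {
  iv <- rbind(c(0, 100), c(150, 300), c(400, 450))
  base <- coding_density(cds_interval_set(1, iv, 500))
  expect_equal(coding_density(cds_interval_set(1, iv[c(3, 1, 2), ], 500)), base)
  split <- rbind(c(0, 50), c(50, 100), c(150, 200), c(200, 300), c(400, 450))
  expect_equal(coding_density(cds_interval_set(1, split, 500)), base)
})

test_that("interval sets are validated", {
  expect_error(cds_interval_set(11, cbind(0, 10), 0), "positive")
  expect_error(cds_interval_set(11, cbind(50, 40), 100), "start < end")
  expect_error(cds_interval_set(2, cbind(0, 10), 100), "genetic_code")
})

test_that("genetic code with the highest coding density wins, ties to lowest code", {
  mk <- function(code, frac) cds_interval_set(code, cbind(0, frac * 1000), 1000)
  expect_equal(pick_genetic_code(list(mk(1, 0.80), mk(4, 0.92),
                                      mk(6, 0.70), mk(11, 0.85))), 4L)
  expect_equal(pick_genetic_code(list(mk(1, 0.9), mk(11, 0.9))), 1L)
  expect_equal(pick_genetic_code(list(mk(11, 0.5))), 11L)
  expect_error(pick_genetic_code(list()), "no candidate")
  expect_error(pick_genetic_code(list(mk(1, 0.5),
                                      cds_interval_set(4, cbind(0, 10), 50))),
               "same genome")
})

test_that("NCLDV call needs more than one distinct GVOG passing the cutoff", {
  expect_true(classify_ncldv(data.frame(marker_id = c("PolB", "A32"),
                                        evalue = c(1e-20, 1e-15))))
  # repeated hits to the same marker do not count twice
  expect_false(classify_ncldv(data.frame(marker_id = c("PolB", "PolB"),
                                         evalue = c(1e-20, 1e-12))))
  expect_false(classify_ncldv(data.frame(marker_id = c("PolB", "A32"),
                                         evalue = c(1e-5, 1e-6))))
  # the cutoff is inclusive
  expect_true(classify_ncldv(data.frame(marker_id = c("PolB", "A32"),
                                        evalue = c(1e-10, 1e-10))))
  expect_false(classify_ncldv(data.frame(marker_id = character(0),
                                         evalue = numeric(0))))
  expect_error(classify_ncldv(data.frame(marker_id = "NotAMarker", evalue = 1e-20)),
               "GVOG7")
})

test_that("a single passing Mirusviricota marker suffices", {
  expect_true(classify_mirus(data.frame(marker_id = "Portal", evalue = 1e-30)))
  expect_false(classify_mirus(data.frame(marker_id = character(0),
                                         evalue = numeric(0))))
  expect_false(classify_mirus(data.frame(marker_id = "TFIIS", evalue = 1e-9)))
  expect_true(classify_mirus(data.frame(marker_id = "TFIIS", evalue = 1e-10)))
})

test_that("taxon calls are monotone in added hits and in the cutoff", {
  set.seed(11)
  gvog <- giant_virus_marker_sets()$GVOG7
  for (i in 1:25) {
    hits <- data.frame(marker_id = sample(gvog, 4, replace = TRUE),
                       evalue = 10^runif(4, -15, -5))
    extra <- data.frame(marker_id = sample(gvog, 2), evalue = 10^runif(2, -15, -5))
    before <- classify_ncldv(hits)
    after <- classify_ncldv(rbind(hits, extra))
    expect_true(!before || after)  # adding hits never un-classifies
    # lowering the cutoff never adds classifications
    strict <- classify_ncldv(hits, evalue_max = 1e-12)
    expect_true(!strict || before)
  }
})

test_that("cellular marker counting flags only above the threshold", {
  none <- cellular_marker_copies(data.frame(marker_id = character(0),
                                            evalue = numeric(0)))
  expect_equal(none$total, 0L)
  expect_false(none$flagged)
  six <- cellular_marker_copies(
    data.frame(marker_id = rep(c("CM01", "CM02", "CM03"), 2),
               evalue = rep(1e-20, 6)))
  expect_equal(six$total, 6L)
  expect_true(six$flagged)
  two <- cellular_marker_copies(data.frame(marker_id = c("CM01", "CM09"),
                                           evalue = c(1e-20, 1e-20)))
  expect_equal(two$total, 2L)
  expect_false(two$flagged)
})

test_that("dereplication clusters by single linkage at 95/85 and picks the longest", {
  genomes <- tibble::tibble(genome_id = c("A", "B", "C"),
                            length_bp = c(100e3, 200e3, 150e3))
  edges <- tibble::tibble(genome_a = "A", genome_b = "B",
                          ani_pct = 96, af_pct = 90)
  res <- dereplicate(genomes, edges)
  expect_equal(res$representative_id[match(c("A", "B"), res$genome_id)],
               c("B", "B"))
  expect_equal(res$representative_id[res$genome_id == "C"], "C")

  # AF below threshold: no edge
  res2 <- dereplicate(genomes, tibble::tibble(genome_a = "A", genome_b = "B",
                                              ani_pct = 96, af_pct = 80))
  expect_equal(res2$representative_id, c("A", "B", "C"))

  # chain A-B, B-C merges all three even though A-C fails the threshold
  chain <- tibble::tibble(genome_a = c("A", "B", "A"), genome_b = c("B", "C", "C"),
                          ani_pct = c(96, 96, 90), af_pct = c(90, 90, 90))
  res3 <- dereplicate(genomes, chain)
  expect_equal(unique(res3$representative_id), "B")

  expect_error(dereplicate(genomes, tibble::tibble(genome_a = "A", genome_b = "Z",
                                                   ani_pct = 99, af_pct = 99)),
               "unknown genome")
})

test_that("dereplication output is a partition with self-mapped representatives", {
  set.seed(5)
  ids <- sprintf("G%02d", 1:12)
  genomes <- tibble::tibble(genome_id = ids,
                            length_bp = sample(1e5:1e6, 12))
  pairs <- t(utils::combn(ids, 2))
  keep <- runif(nrow(pairs)) < 0.2
  edges <- tibble::tibble(genome_a = pairs[keep, 1], genome_b = pairs[keep, 2],
                          ani_pct = runif(sum(keep), 90, 100),
                          af_pct = runif(sum(keep), 80, 100))
  res <- dereplicate(genomes, edges)
  expect_setequal(res$genome_id, ids)
  expect_equal(anyDuplicated(res$genome_id), 0L)
  reps <- unique(res$representative_id)
  # every representative maps to itself
  expect_equal(res$representative_id[match(reps, res$genome_id)], reps)
})

test_that("screen_genomes combines the rules, with keep/drop overrides", {
  hits <- tibble::tibble(
    genome_id = c("g1", "g1", "g2", "g3", "g3", "g4"),
    marker_id = c("PolB", "VLTF3", "Portal", "PolB", "A32", "SFII"),
    evalue = c(1e-20, 1e-12, 1e-11, 1e-20, 1e-9, 1e-20),
    marker_set = c("GVOG7", "GVOG7", "MIRUS5", "GVOG7", "GVOG7", "GVOG7"))
  out <- screen_genomes(hits)
  expect_equal(out$taxon[match(c("g1", "g2", "g3", "g4"), out$genome_id)],
               c("NCLDV", "Mirus", "none", "none"))
  dropped <- screen_genomes(hits, drop = "g1")
  expect_equal(dropped$taxon[dropped$genome_id == "g1"], "none")
  shielded <- screen_genomes(hits, keep = "g1", drop = "g1")
  expect_equal(shielded$taxon[shielded$genome_id == "g1"], "NCLDV")
})
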