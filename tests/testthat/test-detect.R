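# Presence calling, detection matrices, temperature classes, endemicity and
# the temperature-detection correlation.

test_that("depth summaries report breadth at threshold and mean depth", {
  s <- summarize_depth(c(3, 3, 3, 3, 3, 3, 3, 0, 0, 0))
  expect_equal(s$breadth, 0.7)
  expect_equal(s$mean_depth, 2.1)
  z <- summarize_depth(rep(0, 5))
  expect_equal(z$breadth, 0)
  expect_equal(z$mean_depth, 0)
  s2 <- summarize_depth(c(1, 2, 2, 3))
  expect_equal(s2$breadth, 0.75)
  expect_equal(s2$mean_depth, 2)
  expect_equal(s2$breadth_covered, 1)
  expect_error(summarize_depth(numeric(0)), "empty")
  expect_error(summarize_depth(c(1, -1)), "non-negative")
})

test_that("long-format depth tables treat missing positions as zero depth", {
  tab <- tibble::tibble(genome_id = "G", sample_id = "S",
                        pos = c(1, 2, 3, 7), depth = c(2, 2, 1, 5))
  s <- depth_summaries(tab, c(G = 10))
  expect_equal(s$breadth, 0.3)           # 3 of 10 positions at >= 2
  expect_equal(s$mean_depth, 1.0)        # 10 total depth over length 10
  expect_equal(s$breadth_covered, 0.4)
  expect_equal(s$mean_depth_covered, 2.5)
  expect_error(depth_summaries(tab, c(H = 10)), "unknown length")
  expect_error(depth_summaries(tibble::tibble(genome_id = "G", sample_id = "S",
                                              pos = 11, depth = 1), c(G = 10)),
               "beyond")
})

test_that("presence boundary at 70% breadth is inclusive", {
  s <- tibble::tibble(breadth = c(0.69, 0.70, 0.71, 1.0),
                      breadth_covered = 1, mean_depth_covered = 5)
  expect_equal(is_present(s), c(FALSE, TRUE, TRUE, TRUE))
  # alternative reading: 70% covered at all, mean over covered >= 2
  alt <- tibble::tibble(breadth = 0, breadth_covered = c(0.8, 0.8, 0.6),
                        mean_depth_covered = c(2, 1.5, 5))
  expect_equal(is_present(alt, method = "mean_covered"),
               c(TRUE, FALSE, FALSE))
})

test_that("presence is monotone in breadth and in the depth threshold", {
  set.seed(21)
  for (i in 1:20) {
    depths <- rpois(200, 2)
    s2 <- summarize_depth(depths, min_depth = 2)
    s3 <- summarize_depth(depths, min_depth = 3)
    expect_lte(s3$breadth, s2$breadth)  # raising min_depth cannot add presence
    expect_equal(is_present(s2), s2$breadth >= 0.70)
  }
})

test_that("eligibility keeps pico genomes and strictly screens co-assemblies", {
  genomes <- tibble::tibble(
    genome_id = c("p1", "c1", "c2", "f1"),
    size_fraction = c("pico", "coassembly", "coassembly", "femto"))
  sig <- c(c1 = 0.71, c2 = 0.70)
  kept <- eligibility_filter(genomes, sig)
  expect_setequal(kept$genome_id, c("p1", "c1"))  # 0.70 exactly is dropped
  expect_error(eligibility_filter(genomes[1:2, ], pico_signal = NULL),
               "without a pico-fraction signal")
})

test_that("temperature classes follow the 2/10/18 degree boundaries", {
  m <- toy_detection_matrix(
    list(s1 = c("g1", "g2"), s2 = "g1", s3 = "g2", s4 = character(0)),
    c("g1", "g2", "g3"))
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         temperature_C = c(0.5, 1.9, 12, 20))
  prof <- temperature_profile(m, meta)
  g1 <- prof[prof$genome_id == "g1", ]
  expect_true(g1$restricted_low && g1$below_mid_only)
  expect_false(g1$detected_above_high)
  g2 <- prof[prof$genome_id == "g2", ]  # detected at 0.5 and 12
  expect_false(g2$restricted_low || g2$below_mid_only)
  expect_false(g2$detected_above_high)
  g3 <- prof[prof$genome_id == "g3", ]
  expect_true(g3$never_detected)
  expect_true(is.na(g3$max_detected_C))
  # restricted_low implies below_mid_only on arbitrary profiles
  expect_true(all(!prof$restricted_low | prof$below_mid_only))
})

test_that("endemicity fractions and per-sample ratios match hand computation", {
  genomes <- c("a1", "a2", "a3", "t1")
  m <- toy_detection_matrix(
    list(ant1 = c("a1", "a2", "a3"), ant2 = "a1", tem1 = c("a3", "t1")),
    genomes)
  meta <- tibble::tibble(sample_id = c("ant1", "ant2", "tem1"),
                         source = c("Antarctic", "Antarctic", "Temperate"))
  src <- c(a1 = "Antarctic", a2 = "Antarctic", a3 = "Antarctic",
           t1 = "Temperate")
  e <- endemicity_summary(m, meta, src)
  ant <- e$per_source[e$per_source$source == "Antarctic", ]
  expect_equal(ant$fraction_unique, 2 / 3)  # a3 is also seen in tem1
  expect_equal(e$per_sample$ratio[e$per_sample$sample_id == "ant1"], 2 / 3)
  expect_equal(e$per_sample$ratio[e$per_sample$sample_id == "tem1"], 1 / 2)
  # unique + shared counts add up per source
  expect_equal(ant$n_unique + 1, ant$n_genomes)
})

test_that("all genomes detected only at home give endemicity one", {
  m <- toy_detection_matrix(list(ant1 = "a1", arc1 = "b1"), c("a1", "b1"))
  meta <- tibble::tibble(sample_id = c("ant1", "arc1"),
                         source = c("Antarctic", "Arctic"))
  e <- endemicity_summary(m, meta, c(a1 = "Antarctic", b1 = "Arctic"))
  expect_true(all(e$per_source$fraction_unique == 1))
  expect_true(all(e$per_sample$ratio == 1))
})

test_that("strictly decreasing counts give rho -1 with exact p 2/n!", {
  m <- matrix(FALSE, 5, 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:5)))
  for (j in 1:5) m[seq_len(6 - j), j] <- TRUE  # counts 5,4,3,2,1
  meta <- tibble::tibble(sample_id = paste0("s", 1:5), temperature_C = 1:5)
  res <- temp_detection_correlation(m, meta)
  expect_equal(res$rho, -1)
  expect_equal(res$method, "exact")
  # only the identity and full reversal reach |rho| = 1 among the 120
  # permutations (frozen from enumerating them)
  expect_equal(res$p, 2 / 120)
})

test_that("degenerate constant inputs give rho 0 and p 1", {
  m <- matrix(TRUE, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:4), temperature_C = 1:4)
  res <- temp_detection_correlation(m, meta)
  expect_equal(res$rho, 0)
  expect_equal(res$p, 1)
  expect_error(
    temp_detection_correlation(m[, 1:2], meta[1:2, ]), "at least 3")
})

test_that("Monte Carlo permutation p converges to the exhaustive value", {
  set.seed(9)
  m <- matrix(runif(36) < 0.5, 6, 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:6)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:6),
                         temperature_C = c(0, 2, 5, 11, 19, 27))
  ex <- temp_detection_correlation(m, meta, exact = TRUE)
  mc <- temp_detection_correlation(m, meta, exact = FALSE, n_perm = 20000,
                                   seed = 4)
  expect_equal(mc$rho, ex$rho)
  expect_lt(abs(mc$p - ex$p), 0.02)
})
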