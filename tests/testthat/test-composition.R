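# Amino-acid composition, physicochemical properties, rank tests, and the
# cold-vs-temperate comparison.

test_that("amino-acid frequencies exclude ambiguity codes and stops", {
  f <- aa_frequencies("MMMM")
  expect_equal(unname(f["M"]), 1)
  expect_equal(sum(f), 1)
  f2 <- aa_frequencies("ACDX")
  expect_equal(unname(f2[c("A", "C", "D")]), rep(1 / 3, 3))
  f3 <- aa_frequencies("TTLL")
  expect_equal(unname(f3[c("T", "L")]), c(0.5, 0.5))
  # terminal stop is stripped, lowercase tolerated
  expect_equal(aa_frequencies("acd*"), aa_frequencies("ACD"))
  expect_error(aa_frequencies("XXXX"), "no countable")
  expect_error(aa_frequencies("AC1D"), "invalid residue")
})

test_that("GRAVY equals the mean Kyte-Doolittle hydropathy", {
  # frozen from the hydropathy table: A = 1.8; mean(R,K,D,E) = -3.85;
  # mean(A,I) = 3.15
  expect_equal(gravy("A"), 1.8)
  expect_equal(gravy("RKDE"), -3.85)
  expect_equal(gravy("AI"), 3.15)
})

test_that("aliphatic index follows the mole-percent formula", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("VVVV"), 290)
  expect_equal(aliphatic_index("GGGG"), 0)
  # mixed case: 50% A + 50% L -> 50 + 3.9 * 50
  expect_equal(aliphatic_index("AL"), 50 + 3.9 * 50)
})

test_that("residue-class fractions use the configured sets", {
  rc <- residue_class_fractions("DDEE")
  expect_equal(unname(rc), c(1, 1, 0))
  rc2 <- residue_class_fractions("STNQ")
  expect_equal(unname(rc2), c(0, 0, 1))
  rc3 <- residue_class_fractions("DK")
  expect_equal(unname(rc3[c("frac_acidic", "frac_charged")]), c(0.5, 1))
  expect_error(
    residue_class_fractions("DK", classes = list(
      acidic = c("D", "E", "S"), charged = c("D", "E", "K"),
      polar_uncharged = c("S", "T"))),
    "overlap")
})

test_that("profiles satisfy the compositional identities", {
  set.seed(31)
  seqs <- vapply(1:40, function(i)
    paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"),
                 sample(50:200, 1), replace = TRUE), collapse = ""),
    character(1))
  prof <- composition_profiles(tibble::tibble(protein_id = paste0("p", 1:40),
                                              sequence = seqs))
  freq <- as.matrix(prof[, paste0("freq_", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])])
  expect_equal(unname(rowSums(freq)), rep(1, 40))
  # acidic + basic = charged
  basic <- rowSums(freq[, c("freq_K", "freq_R", "freq_H")])
  expect_equal(prof$frac_acidic + basic, prof$frac_charged)
  # properties are permutation invariant
  shuffled <- vapply(strsplit(seqs, ""), function(ch)
    paste(sample(ch), collapse = ""), character(1))
  prof2 <- composition_profiles(tibble::tibble(protein_id = paste0("p", 1:40),
                                               sequence = shuffled))
  expect_equal(prof$gravy, prof2$gravy)
  expect_equal(prof$aliphatic_index, prof2$aliphatic_index)
})

test_that("orthogroups are kept only when all ecosystems are represented", {
  meta <- tibble::tibble(
    protein_id = paste0("p", 1:8),
    environment = c("Antarctic", "Arctic", "Patagonia", "Temperate",
                    "Antarctic", "Arctic", "Temperate", "Temperate"))
  ogs <- tibble::tibble(
    og_id = c(rep("OG1", 4), rep("OG2", 4)),
    protein_id = paste0("p", 1:8))
  expect_equal(select_common_orthogroups(ogs, meta), "OG1")  # OG2 lacks Patagonia
  expect_equal(select_common_orthogroups(ogs[0, ], meta), character(0))
  bad <- meta
  bad$environment[1] <- "Tropics"
  expect_error(select_common_orthogroups(ogs, bad), "unknown environment")
})

test_that("Mann-Whitney matches frozen exact examples", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 1 / 3)   # 2 * P(U <= 0) with 6 arrangements
  expect_true(mw$exact)
  mw2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw2$u, 0)
  expect_equal(mw2$p, 0.1)    # 2/20 arrangements as extreme
  # identical groups: no evidence of a difference
  mw3 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(mw3$p, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with brute-force enumeration", {
  set.seed(17)
  for (rep in 1:10) {
    nx <- sample(1:6, 1)
    ny <- sample(1:(8 - nx), 1)
    x <- rnorm(nx)
    y <- rnorm(ny)
    got <- mann_whitney_u(x, y)
    want <- bf_mann_whitney(x, y)
    expect_equal(got$u, want$u)
    expect_equal(got$p, want$p)
  }
})

test_that("Shapiro-Wilk wrapper matches the reference and detects skew", {
  set.seed(41)
  x <- rnorm(30)
  expect_equal(shapiro_wilk(x)$p, stats::shapiro.test(x)$p.value)
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  # exponential samples of n = 50 are reliably rejected
  rejected <- vapply(1:40, function(i) {
    shapiro_wilk(rexp(50))$p < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("a planted threonine/leucine shift is detected with correct signs", {
  cfg <- synth_config(seed = 99,
                      n_genomes_per_env = c(Antarctic = 20, Arctic = 0,
                                            Patagonia = 0, Temperate = 20))
  prof <- composition_profiles(gen_proteomes(cfg)$proteins)
  res <- compare_cold_vs_temperate(prof, cold_envs = "Antarctic")
  expect_equal(nrow(res), 25)
  expect_true(all(res$p_adj >= res$p_raw))
  tt <- res[res$metric == "freq_T", ]
  ll <- res[res$metric == "freq_L", ]
  expect_gt(tt$delta_mean, 0)
  expect_lt(ll$delta_mean, 0)
  expect_lt(tt$p_adj, 0.05)
  expect_lt(ll$p_adj, 0.05)
  expect_error(compare_cold_vs_temperate(prof, cold_envs = "Arctic"),
               "empty group")
})

test_that("orthogroup-mean mode aggregates before testing", {
  cfg <- synth_config(seed = 77,
                      n_genomes_per_env = c(Antarctic = 6, Arctic = 0,
                                            Patagonia = 0, Temperate = 6))
  gp <- gen_proteomes(cfg)
  prof <- composition_profiles(gp$proteins)
  res <- compare_cold_vs_temperate(prof, cold_envs = "Antarctic",
                                   unit = "orthogroup",
                                   orthogroups = gp$orthogroups)
  # one observation per (orthogroup, group): n = number of orthogroups
  expect_true(all(res$n_cold == cfg$n_orthogroups))
  expect_true(all(res$n_temp == cfg$n_orthogroups))
})
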