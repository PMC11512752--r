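# Amino-acid composition and physicochemical properties of viral proteins,
# shared-orthogroup selection, and the cold-vs-temperate comparison.

# Integer codes of the residue alphabet, for fast counting via utf8ToInt().
aa_code_map <- function() {
  map <- integer(128)
  map[utf8ToInt(paste(AA20, collapse = ""))] <- seq_along(AA20)
  map[utf8ToInt("XBZU*")] <- -1L   # tolerated, excluded from counts
  map
}

# counts of the 20 standard residues in one sequence; terminal stops are
# stripped first, internal ambiguity codes and stops are skipped
count_residues <- function(sequence, map = aa_code_map()) {
  s <- toupper(sub("\\*+$", "", sequence))
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  v <- utf8ToInt(s)
  if (any(v < 1L | v > 127L)) stop("non-ASCII character in sequence", call. = FALSE)
  idx <- map[v]
  if (any(idx == 0L)) {
    bad <- unique(intToUtf8(v[idx == 0L], multiple = TRUE))
    stop(sprintf("invalid residue(s) in sequence: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  tabulate(idx[idx > 0L], nbins = 20L)
}

#' Amino-acid frequencies of a protein sequence
#'
#' Frequencies of the 20 standard residues among countable positions.
#' Ambiguity codes (X, B, Z), selenocysteine (U) and stops are excluded from
#' both numerator and denominator; a terminal stop is stripped.
#'
#' @param sequence Protein sequence (single string, upper or lower case).
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' aa_frequencies("ACDX")[c("A", "C", "D")]
aa_frequencies <- function(sequence) {
  n <- count_residues(sequence)
  if (sum(n) == 0L) stop("sequence has no countable residues", call. = FALSE)
  stats::setNames(n / sum(n), AA20)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the countable residues of a protein.
#' Lower values indicate a more hydrophilic protein.
#'
#' @inheritParams aa_frequencies
#' @return Numeric scalar.
#' @export
#' @examples
#' gravy("AI")  # mean of 1.8 and 4.5
gravy <- function(sequence) {
  f <- aa_frequencies(sequence)
  sum(f * kyte_doolittle()[AA20])
}

#' Aliphatic index
#'
#' Ikai's aliphatic index: `X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` where
#' `X` is the mole percent of the residue among countable positions. Higher
#' values indicate more aliphatic side-chain volume, a classical
#' thermostability proxy.
#'
#' @inheritParams aa_frequencies
#' @return Non-negative numeric scalar.
#' @export
#' @examples
#' aliphatic_index("VVVV")  # 290
aliphatic_index <- function(sequence) {
  f <- aa_frequencies(sequence) * 100
  unname(f["A"] + 2.9 * f["V"] + 3.9 * (f["I"] + f["L"]))
}

#' Residue-class content of a protein
#'
#' Fractions of acidic, charged and polar-uncharged residues among countable
#' positions. Defaults ([default_residue_classes()]): acidic D,E; charged
#' D,E,K,R,H; polar uncharged S,T,N,Q,C,Y. The sets are configurable; the
#' acidic and polar-uncharged sets must not overlap.
#'
#' @inheritParams aa_frequencies
#' @param classes Named list with elements `acidic`, `charged`,
#'   `polar_uncharged`.
#' @return Named numeric vector `frac_acidic`, `frac_charged`,
#'   `frac_polar_uncharged`.
#' @export
residue_class_fractions <- function(sequence, classes = default_residue_classes()) {
  if (length(intersect(classes$acidic, classes$polar_uncharged)) > 0L) {
    stop("acidic and polar_uncharged residue sets overlap", call. = FALSE)
  }
  f <- aa_frequencies(sequence)
  c(frac_acidic = sum(f[classes$acidic]),
    frac_charged = sum(f[classes$charged]),
    frac_polar_uncharged = sum(f[classes$polar_uncharged]))
}

#' Composition profiles for a set of proteins
#'
#' Computes, per protein, the 20 residue frequencies and five physicochemical
#' scalars (GRAVY, aliphatic index, acidic / charged / polar-uncharged
#' content). This is the per-protein observation table fed to
#' [compare_cold_vs_temperate()].
#'
#' @param proteins Data frame with columns `protein_id`, `sequence` and any
#'   others to carry through (e.g. `genome_id`).
#' @param classes Residue classes, see [residue_class_fractions()].
#' @return Tibble: carried-through columns, `n_countable`, `freq_A` ..
#'   `freq_Y`, `gravy`, `aliphatic_index`, `frac_acidic`, `frac_charged`,
#'   `frac_polar_uncharged`.
#' @export
composition_profiles <- function(proteins, classes = default_residue_classes()) {
  assert_cols(proteins, c("protein_id", "sequence"), "protein table")
  if (length(intersect(classes$acidic, classes$polar_uncharged)) > 0L) {
    stop("acidic and polar_uncharged residue sets overlap", call. = FALSE)
  }
  map <- aa_code_map()
  counts <- t(vapply(proteins$sequence, count_residues, integer(20L),
                     map = map, USE.NAMES = FALSE))
  tot <- rowSums(counts)
  if (any(tot == 0L)) {
    stop(sprintf("protein(s) with no countable residues: %s",
                 paste(proteins$protein_id[tot == 0L], collapse = ", ")),
         call. = FALSE)
  }
  freq <- counts / tot
  colnames(freq) <- AA20
  kd <- kyte_doolittle()[AA20]
  out <- tibble::as_tibble(proteins[, setdiff(names(proteins), "sequence"),
                                    drop = FALSE])
  out$n_countable <- as.integer(tot)
  freq_df <- tibble::as_tibble(as.data.frame(freq))
  names(freq_df) <- paste0("freq_", AA20)
  out <- dplyr::bind_cols(out, freq_df)
  out$gravy <- as.numeric(freq %*% kd)
  out$aliphatic_index <- 100 * (freq[, "A"] + 2.9 * freq[, "V"] +
                                  3.9 * (freq[, "I"] + freq[, "L"]))
  out$frac_acidic <- rowSums(freq[, classes$acidic, drop = FALSE])
  out$frac_charged <- rowSums(freq[, classes$charged, drop = FALSE])
  out$frac_polar_uncharged <- rowSums(freq[, classes$polar_uncharged, drop = FALSE])
  out
}

#' Select orthogroups shared by all ecosystems
#'
#' Keeps the orthogroups that contain at least one protein from every
#' required ecosystem. Restricting the composition comparison to these
#' shared families avoids confounding compositional shifts with lineage
#' content differences.
#'
#' @param orthogroups Data frame with columns `og_id`, `protein_id`.
#' @param protein_meta Data frame with columns `protein_id`, `environment`.
#' @param required_envs Ecosystem labels that must all be represented
#'   (default all four).
#' @return Character vector of retained `og_id`s.
#' @export
select_common_orthogroups <- function(orthogroups, protein_meta,
                                      required_envs = gv_environments()) {
  assert_cols(orthogroups, c("og_id", "protein_id"), "orthogroup table")
  assert_cols(protein_meta, c("protein_id", "environment"), "protein metadata")
  assert_envs(protein_meta$environment)
  assert_envs(required_envs, "required environment")
  if (nrow(orthogroups) == 0L) return(character(0))
  missing <- setdiff(orthogroups$protein_id, protein_meta$protein_id)
  if (length(missing) > 0L) {
    stop(sprintf("orthogroup member(s) without metadata: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  env <- protein_meta$environment[match(orthogroups$protein_id,
                                        protein_meta$protein_id)]
  cover <- tapply(env, orthogroups$og_id,
                  function(e) all(required_envs %in% e))
  sort(names(cover)[cover])
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups with average ranks for
#' ties. The p-value is exact (enumeration of the null U distribution) when
#' the combined sample size is at most `exact_max` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. Backed by [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_max Combined-size threshold for the exact path (default 12).
#' @return List with `u` (U statistic of `x`), `p` (two-sided p-value) and
#'   `exact` (logical).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # u = 0, p = 1/3
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty",
                                             call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= exact_max) && !ties
  ht <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                           alternative = "two.sided")
  list(u = unname(ht$statistic), p = ht$p.value, exact = use_exact)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()]; used as the pre-test before
#' the rank-based group comparison. Samples larger than 5000 are reduced to
#' a seeded random subsample of 5000 (the test is defined for 3..5000
#' observations).
#'
#' @param x Numeric vector with at least 3 values.
#' @param subsample_seed Seed used only when `length(x) > 5000`.
#' @return List with `w` (statistic) and `p`.
#' @export
shapiro_wilk <- function(x, subsample_seed = 1) {
  if (length(x) < 3L) stop("Shapiro-Wilk requires at least 3 observations",
                           call. = FALSE)
  if (length(x) > 5000L) {
    x <- withr::with_seed(subsample_seed, sample(x, 5000L))
  }
  ht <- stats::shapiro.test(x)
  list(w = unname(ht$statistic), p = ht$p.value)
}

composition_metrics <- function() {
  c(paste0("freq_", AA20), "gravy", "aliphatic_index",
    "frac_acidic", "frac_charged", "frac_polar_uncharged")
}

#' Compare composition of cold versus temperate proteins
#'
#' For each cold ecosystem and each of the 25 composition metrics (20
#' residue frequencies + 5 physicochemical properties), compares proteins
#' from that ecosystem against temperate proteins: mean difference
#' (cold - temperate), Mann-Whitney U with two-sided p, Shapiro-Wilk
#' normality p per group, and Benjamini-Hochberg adjusted p across the 25
#' metrics within each cold ecosystem. The unit of observation is the
#' protein by default; `unit = "orthogroup"` first averages each metric
#' within (orthogroup, group).
#'
#' @param profiles Output of [composition_profiles()] with an `environment`
#'   column (and `protein_id`; plus `og_id` via `orthogroups` when
#'   `unit = "orthogroup"`).
#' @param cold_envs Cold ecosystems to compare (default all three).
#' @param temperate_env Label of the reference pool.
#' @param unit `"protein"` (default) or `"orthogroup"`.
#' @param orthogroups Orthogroup membership (`og_id`, `protein_id`);
#'   required for `unit = "orthogroup"`.
#' @return Tibble with columns `cold_env`, `metric`, `n_cold`, `n_temp`,
#'   `delta_mean`, `u_stat`, `p_raw`, `p_adj`, `normality_cold_p`,
#'   `normality_temp_p`.
#' @export
compare_cold_vs_temperate <- function(profiles,
                                      cold_envs = cold_environments(),
                                      temperate_env = "Temperate",
                                      unit = c("protein", "orthogroup"),
                                      orthogroups = NULL) {
  unit <- match.arg(unit)
  assert_cols(profiles, c("environment"), "composition profiles")
  assert_envs(profiles$environment)
  metrics <- intersect(composition_metrics(), names(profiles))
  if (length(metrics) == 0L) stop("profiles carry no composition metrics",
                                  call. = FALSE)
  if (unit == "orthogroup") {
    if (is.null(orthogroups)) stop("unit = 'orthogroup' needs an orthogroup table",
                                   call. = FALSE)
    assert_cols(orthogroups, c("og_id", "protein_id"), "orthogroup table")
    profiles <- dplyr::inner_join(profiles, orthogroups, by = "protein_id") |>
      dplyr::group_by(.data$og_id, .data$environment) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(metrics), mean),
                       .groups = "drop")
  }
  res <- list()
  for (ce in cold_envs) {
    cold <- profiles[profiles$environment == ce, , drop = FALSE]
    temp <- profiles[profiles$environment == temperate_env, , drop = FALSE]
    if (nrow(cold) == 0L || nrow(temp) == 0L) {
      stop(sprintf("empty group for comparison %s vs %s", ce, temperate_env),
           call. = FALSE)
    }
    rows <- lapply(metrics, function(mt) {
      x <- cold[[mt]]; y <- temp[[mt]]
      mw <- mann_whitney_u(x, y)
      tibble::tibble(
        cold_env = ce, metric = mt,
        n_cold = length(x), n_temp = length(y),
        delta_mean = mean(x) - mean(y),
        u_stat = mw$u, p_raw = mw$p,
        normality_cold_p = if (length(x) >= 3) shapiro_wilk(x)$p else NA_real_,
        normality_temp_p = if (length(y) >= 3) shapiro_wilk(y)$p else NA_real_
      )
    })
    block <- dplyr::bind_rows(rows)
    block$p_adj <- stats::p.adjust(block$p_raw, method = "BH")
    res[[ce]] <- block
  }
  out <- dplyr::bind_rows(res)
  out[, c("cold_env", "metric", "n_cold", "n_temp", "delta_mean", "u_stat",
          "p_raw", "p_adj", "normality_cold_p", "normality_temp_p")]
}
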