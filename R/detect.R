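# Presence calling from read-depth profiles, detection matrices, temperature
# distribution classes, endemicity, and the temperature-detection correlation.

#' Summarise a per-base depth profile
#'
#' Computes breadth of coverage at a per-position depth threshold and mean
#' depth over the whole genome. Presence in a sample is later called from
#' these summaries ([is_present()]): the default rule asks for depth >= 2
#' along at least 70% of the genome.
#'
#' @param depths Integer/numeric vector of per-base depths covering the whole
#'   genome (length = genome length; positions without mapped reads are 0).
#' @param min_depth Per-position depth threshold (default 2).
#' @return Tibble with one row: `breadth` (fraction of positions with
#'   depth at or above `min_depth`), `breadth_covered` (fraction with depth
#'   of at least 1), `mean_depth` (over all positions), and
#'   `mean_depth_covered` (over covered positions; 0 when nothing is
#'   covered).
#' @export
#' @examples
#' summarize_depth(c(3, 3, 3, 3, 3, 3, 3, 0, 0, 0))
summarize_depth <- function(depths, min_depth = 2) {
  if (length(depths) == 0L) stop("empty depth vector", call. = FALSE)
  if (any(is.na(depths)) || any(depths < 0)) {
    stop("depths must be non-negative and non-missing", call. = FALSE)
  }
  covered <- depths >= 1
  tibble::tibble(
    breadth = mean(depths >= min_depth),
    breadth_covered = mean(covered),
    mean_depth = mean(depths),
    mean_depth_covered = if (any(covered)) mean(depths[covered]) else 0
  )
}

#' Summarise long-format depth tables per genome and sample
#'
#' Positions absent from the table are taken as depth 0, so breadth and mean
#' depth are computed against the full genome length.
#'
#' @param depth_table Data frame with columns `genome_id`, `sample_id`,
#'   `pos` (1-based), `depth`. Zero-depth rows may be omitted.
#' @param genome_lengths Named numeric vector of genome lengths (bp).
#' @param min_depth Per-position depth threshold.
#' @return Tibble with columns `genome_id`, `sample_id` and the four
#'   [summarize_depth()] summaries.
#' @export
depth_summaries <- function(depth_table, genome_lengths, min_depth = 2) {
  assert_cols(depth_table, c("genome_id", "sample_id", "pos", "depth"),
              "depth table")
  unknown <- setdiff(unique(depth_table$genome_id), names(genome_lengths))
  if (length(unknown) > 0L) {
    stop(sprintf("depth table references genome(s) of unknown length: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(depth_table$depth < 0)) stop("negative depth", call. = FALSE)
  grp <- depth_table |>
    dplyr::group_by(.data$genome_id, .data$sample_id) |>
    dplyr::summarise(
      n_at_min = sum(.data$depth >= min_depth),
      n_cov = sum(.data$depth >= 1),
      total = sum(.data$depth),
      max_pos = max(.data$pos),
      .groups = "drop")
  len <- unname(genome_lengths[grp$genome_id])
  if (any(grp$max_pos > len)) {
    stop("depth table has positions beyond the genome length", call. = FALSE)
  }
  tibble::tibble(
    genome_id = grp$genome_id,
    sample_id = grp$sample_id,
    breadth = grp$n_at_min / len,
    breadth_covered = grp$n_cov / len,
    mean_depth = grp$total / len,
    mean_depth_covered = ifelse(grp$n_cov > 0, grp$total / grp$n_cov, 0)
  )
}

#' Call presence of a genome in a sample from its depth summary
#'
#' The default reading of the presence rule is per-position: depth >= 2 over
#' at least 70% of the genome (`method = "per_position"`, boundary
#' inclusive). An alternative reading -- at least 70% of the genome covered
#' at all, with mean depth over the covered part >= `min_depth` -- is
#' available as `method = "mean_covered"`.
#'
#' @param s Depth summary tibble/data frame from [summarize_depth()] or
#'   [depth_summaries()] (any number of rows; vectorised).
#' @param min_breadth Breadth threshold, default 0.70.
#' @param method `"per_position"` (default) or `"mean_covered"`.
#' @param min_depth Used by the `"mean_covered"` reading only.
#' @return Logical vector, one element per row of `s`.
#' @export
is_present <- function(s, min_breadth = 0.70,
                       method = c("per_position", "mean_covered"),
                       min_depth = 2) {
  method <- match.arg(method)
  if (method == "per_position") {
    assert_cols(s, "breadth", "depth summary")
    s$breadth >= min_breadth
  } else {
    assert_cols(s, c("breadth_covered", "mean_depth_covered"), "depth summary")
    s$breadth_covered >= min_breadth & s$mean_depth_covered >= min_depth
  }
}

#' Filter genomes eligible for pico-fraction detection
#'
#' To avoid false negatives when detecting genomes in pico-size-fraction
#' metagenomes, only genomes assembled from the pico fraction are used
#' directly; genomes from co-assemblies qualify only when more than
#' `min_signal` of their metagenomic signal lies in the pico-like fraction
#' (strict inequality). Genomes from other fractions are excluded.
#'
#' @param genomes Data frame with columns `genome_id`, `size_fraction`
#'   (values among `"pico"`, `"femto"`, `"large"`, `"coassembly"`).
#' @param pico_signal Named numeric vector, fraction of signal in the pico
#'   fraction; required for every co-assembly genome.
#' @param min_signal Strict lower bound for co-assemblies (default 0.70).
#' @return The eligible subset of `genomes` (same columns).
#' @export
eligibility_filter <- function(genomes, pico_signal = NULL, min_signal = 0.70) {
  assert_cols(genomes, c("genome_id", "size_fraction"), "genome table")
  co <- genomes$size_fraction == "coassembly"
  missing_sig <- genomes$genome_id[co][!genomes$genome_id[co] %in% names(pico_signal)]
  if (length(missing_sig) > 0L) {
    stop(sprintf("co-assembly genome(s) without a pico-fraction signal: %s",
                 paste(missing_sig, collapse = ", ")), call. = FALSE)
  }
  keep <- genomes$size_fraction == "pico"
  keep[co] <- pico_signal[genomes$genome_id[co]] > min_signal
  genomes[keep, , drop = FALSE]
}

#' Build a genome-by-sample detection matrix
#'
#' @param summaries Output of [depth_summaries()].
#' @param genomes,samples Character vectors fixing row and column order;
#'   defaults to the ids present in `summaries`. Pairs absent from
#'   `summaries` are treated as absent.
#' @param ... Passed to [is_present()].
#' @return Logical matrix (genomes x samples) with dimnames.
#' @export
detection_matrix <- function(summaries, genomes = NULL, samples = NULL, ...) {
  assert_cols(summaries, c("genome_id", "sample_id"), "depth summaries")
  if (is.null(genomes)) genomes <- sort(unique(summaries$genome_id))
  if (is.null(samples)) samples <- sort(unique(summaries$sample_id))
  m <- matrix(FALSE, length(genomes), length(samples),
              dimnames = list(genomes, samples))
  pres <- is_present(summaries, ...)
  keep <- summaries$genome_id %in% genomes & summaries$sample_id %in% samples
  m[cbind(summaries$genome_id[keep], summaries$sample_id[keep])] <- pres[keep]
  m
}

#' Temperature-distribution profile of each genome
#'
#' Classifies each genome's detections against three temperature boundaries
#' (defaults 2, 10 and 18 degrees C): `restricted_low` -- detected, and the
#' warmest detection is below `t_low`; `below_mid_only` -- detected only
#' below `t_mid`; `detected_above_high` -- any detection above `t_high`;
#' `never_detected` -- no detection anywhere. `restricted_low` implies
#' `below_mid_only`.
#'
#' @param m Detection matrix from [detection_matrix()].
#' @param meta Data frame with columns `sample_id`, `temperature_C` covering
#'   every column of `m`.
#' @param t_low,t_mid,t_high Class boundaries in degrees C.
#' @return Tibble with `genome_id`, `n_detections`, `min_detected_C`,
#'   `max_detected_C` (NA when never detected) and the four logical classes.
#' @export
temperature_profile <- function(m, meta, t_low = 2, t_mid = 10, t_high = 18) {
  assert_cols(meta, c("sample_id", "temperature_C"), "sample metadata")
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing) > 0L) {
    stop(sprintf("samples missing from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  temp <- meta$temperature_C[match(colnames(m), meta$sample_id)]
  out <- lapply(seq_len(nrow(m)), function(i) {
    t_det <- temp[m[i, ]]
    detected <- length(t_det) > 0L
    tibble::tibble(
      genome_id = rownames(m)[i],
      n_detections = length(t_det),
      min_detected_C = if (detected) min(t_det) else NA_real_,
      max_detected_C = if (detected) max(t_det) else NA_real_,
      restricted_low = detected && max(t_det) < t_low,
      below_mid_only = detected && max(t_det) < t_mid,
      detected_above_high = detected && any(t_det > t_high),
      never_detected = !detected
    )
  })
  dplyr::bind_rows(out)
}

#' Endemicity of genomes with respect to their source region
#'
#' A genome is "unique" (endemic) when every sample it is detected in comes
#' from its own source region. Genomes never detected anywhere are excluded
#' from the denominators by default.
#'
#' @param m Detection matrix.
#' @param meta Sample metadata with columns `sample_id`, `source`.
#' @param genome_sources Named character vector mapping genome ids to their
#'   source region.
#' @param include_undetected Count never-detected genomes in the per-source
#'   denominator (default `FALSE`).
#' @return List with `per_source` (source, n_detected, n_unique,
#'   fraction_unique) and `per_sample` (sample_id, source, n_detected,
#'   n_unique, ratio = unique/total detections in the sample).
#' @export
endemicity_summary <- function(m, meta, genome_sources,
                               include_undetected = FALSE) {
  assert_cols(meta, c("sample_id", "source"), "sample metadata")
  assert_envs(meta$source, "sample source")
  missing <- setdiff(rownames(m), names(genome_sources))
  if (length(missing) > 0L) {
    stop(sprintf("genomes without a source label: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sample_src <- meta$source[match(colnames(m), meta$sample_id)]
  g_src <- unname(genome_sources[rownames(m)])
  assert_envs(g_src, "genome source")
  detected <- rowSums(m) > 0
  unique_home <- vapply(seq_len(nrow(m)), function(i) {
    det <- m[i, ]
    any(det) && all(sample_src[det] == g_src[i])
  }, logical(1))

  denom <- if (include_undetected) rep(TRUE, nrow(m)) else detected
  per_source <- tibble::tibble(source = sort(unique(g_src))) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_genomes = sum(g_src == .data$source & denom),
      n_unique = sum(unique_home & g_src == .data$source),
      fraction_unique = ifelse(.data$n_genomes > 0,
                               .data$n_unique / .data$n_genomes, NA_real_)) |>
    dplyr::ungroup()

  n_det <- unname(colSums(m))
  n_uni <- unname(colSums(m & unique_home))
  per_sample <- tibble::tibble(
    sample_id = colnames(m),
    source = sample_src,
    n_detected = n_det,
    n_unique = n_uni,
    ratio = ifelse(n_det > 0, n_uni / n_det, NA_real_)
  )
  list(per_source = per_source, per_sample = per_sample)
}

# all permutations of 1..n as an n! x n matrix (used for exact permutation
# p-values; n is capped by the caller)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Correlation between sample temperature and detection count
#'
#' Spearman rank correlation (average ranks for ties) between each sample's
#' temperature and the number of genomes detected in it, with a two-sided
#' permutation p-value obtained by shuffling temperatures across samples.
#' With 7 or fewer samples all permutations are enumerated (the p-value is
#' then exact); otherwise `n_perm` seeded random permutations are used with
#' the add-one estimator. Degenerate inputs (constant counts or constant
#' temperatures) are reported as `rho = 0`, `p = 1`.
#'
#' @param m Detection matrix.
#' @param meta Sample metadata with `sample_id`, `temperature_C`.
#' @param n_perm Number of random permutations when not exhaustive.
#' @param seed Integer seed for the random permutations.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` enumerates when the number of samples is <= 7.
#' @return List with `rho`, `p`, `method` (`"exact"`/`"monte_carlo"`) and
#'   `n_perm_used`.
#' @export
temp_detection_correlation <- function(m, meta, n_perm = 10000, seed = 1,
                                       exact = NULL) {
  assert_cols(meta, c("sample_id", "temperature_C"), "sample metadata")
  counts <- colSums(m)
  n <- length(counts)
  if (n < 3L) stop("need at least 3 samples for the correlation", call. = FALSE)
  temp <- meta$temperature_C[match(colnames(m), meta$sample_id)]
  if (any(is.na(temp))) stop("samples missing from metadata", call. = FALSE)
  if (stats::sd(counts) == 0 || stats::sd(temp) == 0) {
    return(list(rho = 0, p = 1, method = "degenerate", n_perm_used = 0L))
  }
  rho <- stats::cor(temp, counts, method = "spearman")
  if (is.null(exact)) exact <- n <= 7L
  if (exact) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(idx)
      stats::cor(temp[idx], counts, method = "spearman"))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact", n_perm_used = nrow(perms))
  } else {
    withr::with_seed(seed, {
      extreme <- sum(vapply(seq_len(n_perm), function(i) {
        abs(stats::cor(sample(temp), counts, method = "spearman")) >=
          abs(rho) - 1e-12
      }, logical(1)))
    })
    list(rho = rho, p = (extreme + 1) / (n_perm + 1),
         method = "monte_carlo", n_perm_used = as.integer(n_perm))
  }
}
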