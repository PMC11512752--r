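# KEGG-ortholog prevalence ratios: cold-exclusive and cold-overrepresented
# gene functions, with functional-category breakdowns.

#' Prevalence of a KO in a genome set
#'
#' @param ko_table Data frame with columns `genome_id`, `ko_id` (one row per
#'   genome-KO presence; duplicates are collapsed).
#' @param genomes Character vector of genome ids defining the pool.
#' @param ko KO identifier.
#' @return Fraction of the pool's genomes carrying `ko`.
#' @export
ko_prevalence <- function(ko_table, genomes, ko) {
  assert_cols(ko_table, c("genome_id", "ko_id"), "KO table")
  if (length(genomes) == 0L) stop("empty genome set", call. = FALSE)
  hit <- unique(ko_table$genome_id[ko_table$ko_id == ko])
  sum(genomes %in% hit) / length(genomes)
}

#' KO prevalence ratio
#'
#' `prev_cold / (prev_cold + prev_temp)`: 1.0 means the KO occurs only in
#' cold-environment genomes; 0.75 corresponds to a KO exactly three times
#' more prevalent in cold than in temperate genomes. Undefined (`NA`) when
#' both prevalences are zero.
#'
#' @param prev_cold,prev_temp Prevalences in `[0, 1]` (vectorised).
#' @return Numeric vector of ratios in `[0, 1]` (or `NA`).
#' @export
#' @examples
#' ko_ratio(0.3, 0.1)  # 0.75
ko_ratio <- function(prev_cold, prev_temp) {
  if (any(prev_cold < 0 | prev_cold > 1 | prev_temp < 0 | prev_temp > 1,
          na.rm = TRUE)) {
    stop("prevalences must be in [0, 1]", call. = FALSE)
  }
  denom <- prev_cold + prev_temp
  ifelse(denom > 0, prev_cold / denom, NA_real_)
}

#' Classify KOs as cold-exclusive or cold-overrepresented
#'
#' Genomes are pooled into a cold pool (Antarctic, Arctic and Patagonia by
#' default) and a temperate pool. Each KO's prevalence is computed per pool
#' and the ratio `prev_cold / (prev_cold + prev_temp)` classifies it:
#' `cold_exclusive` when absent from the temperate pool (ratio 1.0),
#' `cold_overrepresented` when at least `fold` times more prevalent in the
#' cold pool (ratio >= `fold/(fold+1)`, i.e. 0.75 for the default 3-fold,
#' boundary inclusive), otherwise `neither`. To exclude KOs present only
#' sporadically, a KO observed in fewer than `min_genomes_per_env` genomes
#' of a pool where it occurs at all is `filtered`
#' (`filter_scope = "pool"`); `filter_scope = "ecosystem"` applies the same
#' rule per individual ecosystem instead.
#'
#' @param ko_table Data frame with columns `genome_id`, `ko_id`.
#' @param genome_env Data frame with columns `genome_id`, `environment`
#'   covering every genome of the study (genomes without any KO count in
#'   the denominators).
#' @param min_genomes_per_env Minimum genomes carrying the KO per pool (or
#'   ecosystem) where it occurs; default 2.
#' @param fold Fold-prevalence threshold, default 3.
#' @param cold_envs Ecosystems pooled as "cold"; pass a single label (e.g.
#'   `"Antarctic"`) for a per-ecosystem comparison.
#' @param filter_scope `"pool"` (default) or `"ecosystem"`.
#' @return Tibble with `ko_id`, `n_cold_genomes`, `n_temp_genomes`,
#'   `prev_cold`, `prev_temp`, `ratio`, `class`.
#' @export
classify_kos <- function(ko_table, genome_env, min_genomes_per_env = 2,
                         fold = 3, cold_envs = cold_environments(),
                         filter_scope = c("pool", "ecosystem")) {
  filter_scope <- match.arg(filter_scope)
  assert_cols(ko_table, c("genome_id", "ko_id"), "KO table")
  assert_cols(genome_env, c("genome_id", "environment"), "genome metadata")
  assert_envs(genome_env$environment)
  assert_envs(cold_envs, "cold environment")
  unknown <- setdiff(unique(ko_table$genome_id), genome_env$genome_id)
  if (length(unknown) > 0L) {
    stop(sprintf("KO table references unknown genome(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  ko_table <- dplyr::distinct(ko_table[, c("genome_id", "ko_id")])
  env <- genome_env$environment[match(ko_table$genome_id, genome_env$genome_id)]
  pool <- ifelse(env %in% cold_envs, "cold",
                 ifelse(env == "Temperate", "temp", NA))
  cold_genomes <- genome_env$genome_id[genome_env$environment %in% cold_envs]
  temp_genomes <- genome_env$genome_id[genome_env$environment == "Temperate"]
  if (length(cold_genomes) == 0L || length(temp_genomes) == 0L) {
    stop("need at least one cold and one temperate genome", call. = FALSE)
  }
  keep <- !is.na(pool)
  tab <- ko_table[keep, ]
  tab$pool <- pool[keep]
  tab$env <- env[keep]

  counts <- tab |>
    dplyr::group_by(.data$ko_id) |>
    dplyr::summarise(
      n_cold_genomes = dplyr::n_distinct(.data$genome_id[.data$pool == "cold"]),
      n_temp_genomes = dplyr::n_distinct(.data$genome_id[.data$pool == "temp"]),
      .groups = "drop")
  counts$prev_cold <- counts$n_cold_genomes / length(cold_genomes)
  counts$prev_temp <- counts$n_temp_genomes / length(temp_genomes)
  # ratio from integer counts: algebraically equal to
  # prev_cold / (prev_cold + prev_temp) but exact at boundaries like 0.75
  num <- counts$n_cold_genomes * length(temp_genomes)
  den <- num + counts$n_temp_genomes * length(cold_genomes)
  counts$ratio <- ifelse(den > 0, num / den, NA_real_)

  if (filter_scope == "pool") {
    filtered <- (counts$n_cold_genomes > 0 &
                   counts$n_cold_genomes < min_genomes_per_env) |
      (counts$n_temp_genomes > 0 & counts$n_temp_genomes < min_genomes_per_env)
  } else {
    per_env <- tab |>
      dplyr::group_by(.data$ko_id, .data$env) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$genome_id), .groups = "drop")
    low <- per_env |>
      dplyr::group_by(.data$ko_id) |>
      dplyr::summarise(any_low = any(.data$n < min_genomes_per_env),
                       .groups = "drop")
    filtered <- low$any_low[match(counts$ko_id, low$ko_id)]
  }

  thr <- fold / (fold + 1)
  cls <- rep("neither", nrow(counts))
  cls[!is.na(counts$ratio) & counts$ratio == 1] <- "cold_exclusive"
  cls[!is.na(counts$ratio) & counts$ratio >= thr & counts$ratio < 1] <-
    "cold_overrepresented"
  cls[filtered] <- "filtered"
  counts$class <- cls
  counts[order(counts$ko_id), ]
}

#' Functional-category breakdown of selected KOs
#'
#' Among KOs classed `cold_exclusive` or `cold_overrepresented`, tallies the
#' fraction per top-level functional category (and per sub-category when the
#' map provides one). KOs missing from the map are reported as
#' `"unmapped"`.
#'
#' @param classified Output of [classify_kos()].
#' @param ko_categories Data frame with columns `ko_id`, `top_category` and
#'   optionally `sub_category`.
#' @return List with tibbles `top` (`top_category`, `n`, `fraction`) and
#'   `sub` (`top_category`, `sub_category`, `n`, `fraction`; `NULL` when no
#'   sub-categories were supplied).
#' @export
category_breakdown <- function(classified, ko_categories) {
  assert_cols(classified, c("ko_id", "class"), "KO classification")
  assert_cols(ko_categories, c("ko_id", "top_category"), "KO category map")
  sel <- classified[classified$class %in%
                      c("cold_exclusive", "cold_overrepresented"), ]
  if (nrow(sel) == 0L) {
    return(list(top = tibble::tibble(top_category = character(0),
                                     n = integer(0), fraction = numeric(0)),
                sub = NULL))
  }
  idx <- match(sel$ko_id, ko_categories$ko_id)
  top <- ifelse(is.na(idx), "unmapped", ko_categories$top_category[idx])
  top_tab <- tibble::as_tibble(as.data.frame(table(top),
                                             stringsAsFactors = FALSE))
  names(top_tab) <- c("top_category", "n")
  top_tab$fraction <- top_tab$n / nrow(sel)
  top_tab <- top_tab[order(-top_tab$n, top_tab$top_category), ]

  sub_tab <- NULL
  if ("sub_category" %in% names(ko_categories)) {
    sub <- ifelse(is.na(idx), "unmapped", ko_categories$sub_category[idx])
    sub_tab <- tibble::as_tibble(as.data.frame(table(top, sub),
                                               stringsAsFactors = FALSE))
    names(sub_tab) <- c("top_category", "sub_category", "n")
    sub_tab <- sub_tab[sub_tab$n > 0, ]
    sub_tab$fraction <- sub_tab$n / nrow(sel)
    sub_tab <- sub_tab[order(-sub_tab$n, sub_tab$sub_category), ]
  }
  list(top = top_tab, sub = sub_tab)
}
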