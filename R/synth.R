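# Synthetic-data generators: proteomes with a planted compositional shift,
# KO tables with planted enrichment, depth profiles with known breadth,
# marker-hit tables with known taxon classes, and sample metadata spanning
# the study's temperature range. Everything is reproducible under the
# configured seed and emitted in the formats the analysis modules consume.

#' Default planted cold-adaptation shift
#'
#' A compositional shift applied to cold-environment proteomes: +0.01
#' threonine, -0.01 leucine (a signature repeatedly reported in
#' psychrophilic proteomes). Sums to zero.
#'
#' @return Named 20-vector.
#' @export
default_cold_shift <- function() {
  s <- stats::setNames(rep(0, 20), AA20)
  s["T"] <- 0.01
  s["L"] <- -0.01
  s
}

#' Configuration for the synthetic generators
#'
#' Defaults describe a scaled-down study: three cold ecosystems (8 Antarctic,
#' 6 Arctic, 6 Patagonian genomes; 20 cold genomes in total) against 30
#' temperate genomes; 10 proteins per genome of length ~ N(300, 60) floored
#' at 50 residues; temperate proteins drawn i.i.d. from Swiss-Prot
#' background frequencies and cold proteins from background + `shift`;
#' orthogroups built so each spans all four ecosystems; sample temperatures
#' spanning -1.4 to 30 degrees C.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_genomes_per_env Named integer vector over the four ecosystems.
#' @param proteins_per_genome Proteins per genome (>= `n_orthogroups`).
#' @param protein_length Named vector `c(mean =, sd =)`.
#' @param baseline_freqs 20-vector of residue frequencies summing to 1.
#' @param shift 20-vector summing to 0, added to `baseline_freqs` for
#'   genomes from cold ecosystems.
#' @param n_orthogroups Number of orthogroups the proteins are spread over.
#' @param n_background_kos Background KOs present at `background_prev` in
#'   both pools.
#' @param background_prev Named vector `c(cold =, temp =)` of background
#'   prevalences.
#' @param n_exclusive_kos,exclusive_n_cold Planted cold-exclusive KOs and
#'   the number of cold genomes carrying each (>= 2, 0 temperate).
#' @param n_overrep_kos,overrep_frac_temp Planted cold-overrepresented KOs;
#'   each present in `round(overrep_frac_temp * n_temp)` temperate and
#'   `round(fold * overrep_frac_temp * n_cold)` cold genomes.
#' @param fold Planted fold-enrichment (default 3).
#' @param n_samples_per_source Named integer vector of sample counts.
#' @param temp_range Sampled temperature span in degrees C.
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_genomes_per_env = c(Antarctic = 8, Arctic = 6,
                                               Patagonia = 6, Temperate = 30),
                         proteins_per_genome = 10,
                         protein_length = c(mean = 300, sd = 60),
                         baseline_freqs = swissprot_background(),
                         shift = default_cold_shift(),
                         n_orthogroups = 10,
                         n_background_kos = 40,
                         background_prev = c(cold = 0.5, temp = 0.5),
                         n_exclusive_kos = 3, exclusive_n_cold = 4,
                         n_overrep_kos = 3, overrep_frac_temp = 0.1,
                         fold = 3,
                         n_samples_per_source = c(Antarctic = 6, Arctic = 5,
                                                  Patagonia = 5, Temperate = 8),
                         temp_range = c(-1.4, 30)) {
  assert_envs(names(n_genomes_per_env))
  baseline_freqs <- baseline_freqs[AA20]
  shift <- shift[AA20]
  if (any(is.na(baseline_freqs)) || abs(sum(baseline_freqs) - 1) > 1e-9) {
    stop("baseline_freqs must be a 20-vector over the standard residues summing to 1",
         call. = FALSE)
  }
  if (any(is.na(shift)) || abs(sum(shift)) > 1e-9) {
    stop("shift must be a 20-vector summing to 0", call. = FALSE)
  }
  if (any(baseline_freqs + shift < 0) || any(baseline_freqs + shift > 1)) {
    stop("baseline_freqs + shift must remain a valid probability vector",
         call. = FALSE)
  }
  if (proteins_per_genome < n_orthogroups) {
    stop("proteins_per_genome must be >= n_orthogroups so every genome spans every orthogroup",
         call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_genomes_per_env = n_genomes_per_env,
    proteins_per_genome = as.integer(proteins_per_genome),
    protein_length = protein_length,
    baseline_freqs = baseline_freqs,
    shift = shift,
    n_orthogroups = as.integer(n_orthogroups),
    n_background_kos = as.integer(n_background_kos),
    background_prev = background_prev,
    n_exclusive_kos = as.integer(n_exclusive_kos),
    exclusive_n_cold = as.integer(exclusive_n_cold),
    n_overrep_kos = as.integer(n_overrep_kos),
    overrep_frac_temp = overrep_frac_temp,
    fold = fold,
    n_samples_per_source = n_samples_per_source,
    temp_range = temp_range
  ), class = "synth_config")
}

env_prefix <- function(env) {
  c(Antarctic = "ANT", Arctic = "ARC", Patagonia = "PAT", Temperate = "TEM")[env]
}

#' Synthetic genome collection
#'
#' One genome record per configured genome: id, ecosystem, pico size
#' fraction, and a length drawn uniformly between 80 kb and 1.2 Mb (the
#' usual span of giant-virus MAGs).
#'
#' @param cfg A [synth_config()].
#' @return Tibble `genome_id`, `environment`, `size_fraction`, `length_bp`.
#' @export
gen_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  envs <- rep(names(cfg$n_genomes_per_env), cfg$n_genomes_per_env)
  ids <- unlist(lapply(names(cfg$n_genomes_per_env), function(e) {
    sprintf("%s_MAG_%02d", env_prefix(e), seq_len(cfg$n_genomes_per_env[[e]]))
  }))
  withr::with_seed(cfg$seed, {
    len <- round(stats::runif(length(ids), 8e4, 1.2e6))
  })
  tibble::tibble(genome_id = ids, environment = envs,
                 size_fraction = "pico", length_bp = len)
}

#' Synthetic proteomes with a planted compositional shift
#'
#' Residues are sampled i.i.d. from the baseline frequencies (temperate
#' genomes) or baseline + shift (cold genomes). Proteins are assigned to
#' orthogroups cyclically within each genome, so every orthogroup contains
#' proteins from all four ecosystems and [select_common_orthogroups()]
#' retains exactly `n_orthogroups` groups.
#'
#' @param cfg A [synth_config()].
#' @return List with tibbles `genomes`, `proteins` (`protein_id`,
#'   `genome_id`, `environment`, `sequence`), and `orthogroups` (`og_id`,
#'   `protein_id`).
#' @export
gen_proteomes <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  genomes <- gen_genomes(cfg)
  cold <- genomes$environment %in% cold_environments()
  freq_cold <- cfg$baseline_freqs + cfg$shift
  n_prot <- nrow(genomes) * cfg$proteins_per_genome
  genome_of <- rep(genomes$genome_id, each = cfg$proteins_per_genome)
  env_of <- rep(genomes$environment, each = cfg$proteins_per_genome)
  is_cold <- rep(cold, each = cfg$proteins_per_genome)
  prot_index <- rep(seq_len(cfg$proteins_per_genome), nrow(genomes))
  ids <- sprintf("%s_p%03d", genome_of, prot_index)
  withr::with_seed(cfg$seed + 1L, {
    lens <- pmax(50L, round(stats::rnorm(n_prot, cfg$protein_length[["mean"]],
                                         cfg$protein_length[["sd"]])))
    seqs <- vapply(seq_len(n_prot), function(i) {
      p <- if (is_cold[i]) freq_cold else cfg$baseline_freqs
      paste(sample(AA20, lens[i], replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  proteins <- tibble::tibble(protein_id = ids, genome_id = genome_of,
                             environment = env_of, sequence = seqs)
  orthogroups <- tibble::tibble(
    og_id = sprintf("OG%04d", ((prot_index - 1L) %% cfg$n_orthogroups) + 1L),
    protein_id = ids)
  list(genomes = genomes, proteins = proteins,
       orthogroups = orthogroups[order(orthogroups$og_id,
                                       orthogroups$protein_id), ])
}

#' Synthetic KO table with planted enrichment
#'
#' Builds a genome-level KO presence table over the configured genome pools.
#' Planted cold-exclusive KOs occur in `exclusive_n_cold` cold genomes and
#' no temperate genome; planted overrepresented KOs occur at exactly
#' `fold`-times-higher prevalence in the cold pool (counts are exact by
#' construction -- carrier genomes are chosen by seeded sampling but their
#' number is fixed). Background KOs occur at `background_prev` in both
#' pools; with `exact_counts = TRUE` (default) their per-pool counts are
#' fixed at `round(prev * pool size)`, with `FALSE` each genome carries the
#' KO independently (Bernoulli).
#'
#' @param cfg A [synth_config()].
#' @param genomes Optional genome table (defaults to [gen_genomes()]).
#' @param exact_counts Deterministic per-pool carrier counts (default TRUE).
#' @return List with `table` (tibble `genome_id`, `ko_id`), `truth` (tibble
#'   `ko_id`, `class_true`), and `genomes`.
#' @export
gen_ko_table <- function(cfg, genomes = NULL, exact_counts = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(genomes)) genomes <- gen_genomes(cfg)
  if (any(cfg$background_prev < 0 | cfg$background_prev > 1)) {
    stop("background prevalences must be in [0, 1]", call. = FALSE)
  }
  cold_ids <- genomes$genome_id[genomes$environment %in% cold_environments()]
  temp_ids <- genomes$genome_id[genomes$environment == "Temperate"]
  n_cold <- length(cold_ids); n_temp <- length(temp_ids)
  if (cfg$exclusive_n_cold < 2L) {
    stop("planted exclusive KOs need >= 2 cold carrier genomes", call. = FALSE)
  }
  over_temp <- round(cfg$overrep_frac_temp * n_temp)
  over_cold <- round(cfg$fold * cfg$overrep_frac_temp * n_cold)
  if (over_temp < 2L || over_cold > n_cold) {
    stop("overrepresented-KO construction infeasible for these pool sizes",
         call. = FALSE)
  }
  rows <- list()
  truth <- list()
  withr::with_seed(cfg$seed + 2L, {
    pick <- function(pool, n) sample(pool, n)
    for (i in seq_len(cfg$n_exclusive_kos)) {
      ko <- sprintf("KEXCL%02d", i)
      rows[[ko]] <- tibble::tibble(genome_id = pick(cold_ids, cfg$exclusive_n_cold),
                                   ko_id = ko)
      truth[[ko]] <- "cold_exclusive"
    }
    for (i in seq_len(cfg$n_overrep_kos)) {
      ko <- sprintf("KOVER%02d", i)
      rows[[ko]] <- tibble::tibble(
        genome_id = c(pick(cold_ids, over_cold), pick(temp_ids, over_temp)),
        ko_id = ko)
      truth[[ko]] <- "cold_overrepresented"
    }
    for (i in seq_len(cfg$n_background_kos)) {
      ko <- sprintf("KBACK%02d", i)
      if (exact_counts) {
        carriers <- c(pick(cold_ids, round(cfg$background_prev[["cold"]] * n_cold)),
                      pick(temp_ids, round(cfg$background_prev[["temp"]] * n_temp)))
      } else {
        carriers <- c(
          cold_ids[stats::runif(n_cold) < cfg$background_prev[["cold"]]],
          temp_ids[stats::runif(n_temp) < cfg$background_prev[["temp"]]])
      }
      if (length(carriers) > 0L) {
        rows[[ko]] <- tibble::tibble(genome_id = carriers, ko_id = ko)
      }
      truth[[ko]] <- "neither"
    }
  })
  list(table = dplyr::bind_rows(rows)[, c("genome_id", "ko_id")],
       truth = tibble::tibble(ko_id = names(truth),
                              class_true = unlist(truth, use.names = FALSE)),
       genomes = genomes)
}

#' Synthetic per-base depth profiles with known breadth
#'
#' For each requested (genome, sample) pair, builds a depth vector in which
#' exactly `round(breadth * length)` positions (chosen by seeded shuffle)
#' have depth >= 2 and the remainder alternate between 0 and 1, so
#' [summarize_depth()] recovers the target breadth exactly whenever
#' `breadth * length` is an integer. Depth at covered positions is a
#' constant chosen to approximate `mean_depth` over the whole genome.
#'
#' @param targets Tibble with columns `genome_id`, `sample_id`, `breadth`
#'   (in `[0, 1]`), `mean_depth`.
#' @param genome_lengths Named vector of genome lengths.
#' @param seed Integer seed.
#' @return Long tibble `genome_id`, `sample_id`, `pos` (1-based), `depth`,
#'   with zero-depth positions omitted (as in real depth files).
#' @export
gen_depth_profiles <- function(targets, genome_lengths, seed = 1) {
  assert_cols(targets, c("genome_id", "sample_id", "breadth", "mean_depth"),
              "depth targets")
  if (any(targets$breadth < 0 | targets$breadth > 1)) {
    stop("breadth must be in [0, 1]", call. = FALSE)
  }
  unknown <- setdiff(targets$genome_id, names(genome_lengths))
  if (length(unknown) > 0L) {
    stop(sprintf("no length for genome(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  out <- vector("list", nrow(targets))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(targets))) {
      L <- as.integer(genome_lengths[[targets$genome_id[i]]])
      n_cov <- round(targets$breadth[i] * L)
      depth <- integer(L)
      if (n_cov < L) {
        rest <- L - n_cov
        depth[] <- rep_len(c(0L, 1L), L)
      }
      pos_cov <- if (n_cov > 0) sample.int(L, n_cov) else integer(0)
      if (n_cov > 0) {
        d_cov <- max(2, round((targets$mean_depth[i] * L -
                                 sum(depth[-pos_cov])) / n_cov))
        depth[pos_cov] <- d_cov
      }
      nz <- which(depth > 0L)
      out[[i]] <- tibble::tibble(genome_id = targets$genome_id[i],
                                 sample_id = targets$sample_id[i],
                                 pos = nz, depth = depth[nz])
    }
  })
  dplyr::bind_rows(out)
}

#' Synthetic marker-hit table with known taxon classes
#'
#' Emits, for each genome of the collection, marker hits that exercise the
#' screening decision boundaries: NCLDV genomes carry 2-4 distinct GVOG
#' markers passing the cutoff; Mirusviricota genomes carry one passing
#' morphogenesis or informational marker; "near miss" genomes carry either
#' a single passing GVOG, or markers only at E-values just above the cutoff
#' (1e-9); all genomes receive a few cellular-marker hits. E-values
#' straddle the 1e-10 cutoff, including hits at exactly 1e-10.
#'
#' @param cfg A [synth_config()].
#' @param genomes Optional genome table; defaults to [gen_genomes()]. Taxon
#'   truth is assigned round-robin: NCLDV, NCLDV, Mirus, none.
#' @return List with `hits` (tibble `genome_id`, `marker_id`, `evalue`,
#'   `score`, `marker_set`) and `truth` (tibble `genome_id`, `taxon_true`).
#' @export
gen_marker_hits <- function(cfg, genomes = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(genomes)) genomes <- gen_genomes(cfg)
  sets <- giant_virus_marker_sets()
  taxon <- rep(c("NCLDV", "NCLDV", "Mirus", "none"),
               length.out = nrow(genomes))
  rows <- list()
  withr::with_seed(cfg$seed + 3L, {
    for (i in seq_len(nrow(genomes))) {
      g <- genomes$genome_id[i]
      h <- switch(
        taxon[i],
        NCLDV = {
          k <- sample(2:4, 1)
          ev <- c(10^stats::runif(k - 1L, -20, -11), 1e-10)[seq_len(k)]
          tibble::tibble(genome_id = g,
                         marker_id = sample(sets$GVOG7, k),
                         evalue = ev, marker_set = "GVOG7")
        },
        Mirus = {
          ms <- sample(c("MIRUS5", "MIRUS4"), 1)
          tibble::tibble(genome_id = g,
                         marker_id = sample(sets[[ms]], 1),
                         evalue = sample(c(1e-10, 1e-30), 1),
                         marker_set = ms)
        },
        none = {
          # single strong GVOG plus sub-threshold hits: must classify neither
          tibble::tibble(
            genome_id = g,
            marker_id = c(sample(sets$GVOG7, 2), sample(sets$MIRUS5, 1)),
            evalue = c(1e-20, 1e-9, 1e-9),
            marker_set = c("GVOG7", "GVOG7", "MIRUS5"))
        })
      cell <- tibble::tibble(genome_id = g,
                             marker_id = sample(sets$CELL56, 2),
                             evalue = 10^stats::runif(2, -15, -3),
                             marker_set = "CELL56")
      rows[[g]] <- dplyr::bind_rows(h, cell)
    }
  })
  hits <- dplyr::bind_rows(rows)
  hits$score <- round(-log10(hits$evalue) * 2, 1)
  list(hits = hits[, c("genome_id", "marker_id", "evalue", "score", "marker_set")],
       truth = tibble::tibble(genome_id = genomes$genome_id, taxon_true = taxon))
}

#' Synthetic sample metadata
#'
#' One row per sample with source region, pico size fraction, and a
#' temperature drawn from a realistic span per source (Antarctic/Arctic
#' -1.4 to 5, Patagonia 1 to 12, Temperate 12 to `max(temp_range)` degrees
#' C), jointly spanning the configured range.
#'
#' @param cfg A [synth_config()].
#' @return Tibble `sample_id`, `source`, `size_fraction`, `temperature_C`.
#' @export
gen_sample_meta <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  src <- rep(names(cfg$n_samples_per_source), cfg$n_samples_per_source)
  ids <- unlist(lapply(names(cfg$n_samples_per_source), function(s) {
    sprintf("%s_S%02d", env_prefix(s), seq_len(cfg$n_samples_per_source[[s]]))
  }))
  lo <- cfg$temp_range[1]; hi <- cfg$temp_range[2]
  range_of <- list(Antarctic = c(lo, 5), Arctic = c(lo, 5),
                   Patagonia = c(max(lo, 1), 12), Temperate = c(12, hi))
  withr::with_seed(cfg$seed + 4L, {
    temp <- vapply(src, function(s)
      stats::runif(1, range_of[[s]][1], range_of[[s]][2]), numeric(1))
  })
  # pin the extremes so the collection spans the configured range
  temp[1] <- lo
  temp[length(temp)] <- hi
  tibble::tibble(sample_id = ids, source = src, size_fraction = "pico",
                 temperature_C = unname(temp))
}
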