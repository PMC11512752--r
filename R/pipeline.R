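# End-to-end pipeline: configuration handling, the synthetic input bundle
# writer, and run_pipeline() chaining screening, detection, composition and
# KO enrichment into one reproducible run with a manifest.

pipeline_defaults <- function() {
  list(evalue_max = 1e-10, min_depth = 2, min_breadth = 0.70,
       ani_min = 95, af_min = 85, fold = 3, min_genomes_per_env = 2,
       flag_threshold = 5, min_signal = 0.70, seed = 1)
}

known_config_keys <- function() {
  c(names(pipeline_defaults()),
    "genome_meta", "sample_meta", "marker_hits", "depth_dir", "proteins",
    "protein_genome_map", "orthogroups", "ko_table", "ko_categories",
    "ani_table", "out_dir")
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML (or plain list) with input paths
#' (`genome_meta`, `sample_meta`, `marker_hits` -- a named list of path +
#' marker_set entries --, `depth_dir`, `proteins`, `protein_genome_map`,
#' `orthogroups`, `ko_table`, optionally `ko_categories` and `ani_table`),
#' an `out_dir`, and thresholds (`evalue_max`, `min_depth`, `min_breadth`,
#' `ani_min`, `af_min`, `fold`, `min_genomes_per_env`, `flag_threshold`,
#' `min_signal`, `seed`). Unknown keys are rejected; omitted thresholds take
#' the standard defaults.
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config),
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  unknown <- setdiff(names(config), known_config_keys())
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  required <- c("genome_meta", "sample_meta", "marker_hits", "depth_dir",
                "proteins", "protein_genome_map", "orthogroups", "ko_table",
                "out_dir")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0L) {
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  stopifnot(cfg$min_breadth >= 0, cfg$min_breadth <= 1, cfg$min_depth >= 0,
            cfg$evalue_max >= 0, cfg$ani_min >= 0, cfg$ani_min <= 100,
            cfg$af_min >= 0, cfg$af_min <= 100, cfg$fold > 0)
  cfg
}

#' Write a complete synthetic input bundle
#'
#' Generates every input the pipeline consumes (genome and sample metadata,
#' marker hits, per-sample depth tables, protein FASTA with genome map,
#' orthogroups, KO table with a small category map) from a [synth_config()]
#' and writes them under `dir` in the formats the readers expect. Depth
#' targets cover the cold-environment genomes (the detection catalog of a
#' cold-biased survey): each is present (breadth 0.9) in the samples of its
#' own source region and absent elsewhere (breadth 0.3), except that one
#' Antarctic genome is also planted in one temperate sample so endemicity
#' is not trivially 1. Detection counts therefore decline with temperature,
#' as in the emulated study design.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths plus the underlying `truth`
#'   objects, invisibly.
#' @export
write_synth_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "depth"), showWarnings = FALSE)
  prot <- gen_proteomes(cfg)
  genomes <- prot$genomes
  samples <- gen_sample_meta(cfg)
  mk <- gen_marker_hits(cfg, genomes)
  ko <- gen_ko_table(cfg, genomes)

  # depth targets: the detection catalog holds the cold-environment genomes
  # (as in a cold-biased MAG survey); each is present at home, absent
  # elsewhere, with one Antarctic genome planted in a temperate sample.
  # Temperate genomes carry no read signal, so warm samples detect almost
  # nothing and detection counts fall with temperature.
  cold_set <- genomes$genome_id[genomes$environment %in% cold_environments()]
  pairs <- expand.grid(genome_id = cold_set,
                       sample_id = samples$sample_id,
                       stringsAsFactors = FALSE)
  g_src <- genomes$environment[match(pairs$genome_id, genomes$genome_id)]
  s_src <- samples$source[match(pairs$sample_id, samples$sample_id)]
  pairs$breadth <- ifelse(g_src == s_src, 0.9, 0.3)
  abroad <- which(g_src == "Antarctic" & s_src == "Temperate")[1]
  if (!is.na(abroad)) pairs$breadth[abroad] <- 0.9
  pairs$mean_depth <- ifelse(pairs$breadth >= 0.7, 5, 1)
  # modest genome lengths keep the depth tables small; detection only needs
  # the breadth fraction, not the real MAG length
  depth_len <- stats::setNames(rep(1000L, nrow(genomes)), genomes$genome_id)
  depths <- gen_depth_profiles(pairs, depth_len, seed = cfg$seed + 5L)

  paths <- list(
    genome_meta = file.path(dir, "genomes_meta.tsv"),
    sample_meta = file.path(dir, "samples.tsv"),
    marker_hits = file.path(dir, "marker_hits.tsv"),
    proteins = file.path(dir, "proteins.faa"),
    protein_genome_map = file.path(dir, "protein_genome_map.tsv"),
    orthogroups = file.path(dir, "orthogroups.tsv"),
    ko_table = file.path(dir, "ko_table.tsv"),
    ko_categories = file.path(dir, "ko_categories.tsv"),
    depth_dir = file.path(dir, "depth")
  )
  gm <- genomes
  gm$detection_length_bp <- unname(depth_len[gm$genome_id])
  readr::write_tsv(gm, paths$genome_meta)
  readr::write_tsv(samples, paths$sample_meta)
  readr::write_tsv(mk$hits, paths$marker_hits)
  write_proteins(prot$proteins, paths$proteins)
  readr::write_tsv(prot$proteins[, c("protein_id", "genome_id")],
                   paths$protein_genome_map)
  readr::write_tsv(prot$orthogroups, paths$orthogroups)
  readr::write_tsv(ko$table, paths$ko_table)
  cats <- tibble::tibble(
    ko_id = ko$truth$ko_id,
    top_category = ifelse(grepl("^KEXCL", ko$truth$ko_id),
                          "Genetic Information Processing",
                          ifelse(grepl("^KOVER", ko$truth$ko_id),
                                 "Metabolism", "Other")),
    sub_category = ifelse(grepl("^KEXCL", ko$truth$ko_id), "Chaperones",
                          ifelse(grepl("^KOVER", ko$truth$ko_id),
                                 "Lipid metabolism", "Other")))
  readr::write_tsv(cats, paths$ko_categories)
  for (s in unique(depths$sample_id)) {
    d <- depths[depths$sample_id == s, c("genome_id", "pos", "depth")]
    readr::write_tsv(d, file.path(paths$depth_dir, paste0(s, ".tsv")))
  }
  invisible(c(paths, list(truth = list(marker = mk$truth, ko = ko$truth,
                                       depth_targets = pairs))))
}

file_hash <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Chains the four stages over file inputs: (1) marker screening and, when
#' an ANI table is supplied, dereplication; (2) depth-based presence calls,
#' detection matrix, temperature profiles, endemicity, and the
#' temperature-detection correlation; (3) shared-orthogroup composition
#' comparison; (4) KO prevalence-ratio classification and category
#' breakdown. Stage outputs are written as TSVs under `out_dir` together
#' with a `manifest.json` recording the config hash, seed, row counts and
#' output file checksums. Re-running an identical config reproduces
#' identical outputs.
#'
#' @param config Path to a YAML config or a named list; see
#'   [load_run_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf("[cryosig %s] ", format(Sys.time(), "%H:%M:%S")),
                                   sprintf(...))

  genomes <- read_genome_meta(cfg$genome_meta)
  samples <- read_sample_meta(cfg$sample_meta)

  # --- stage 1: marker screening ------------------------------------------
  log_msg("screening %d genomes", nrow(genomes))
  hits <- if (is.character(cfg$marker_hits)) {
    read_marker_hits(cfg$marker_hits)
  } else {
    dplyr::bind_rows(lapply(cfg$marker_hits, function(h)
      read_marker_hits(h$path, h$marker_set)))
  }
  unknown <- setdiff(unique(hits$genome_id), genomes$genome_id)
  if (length(unknown) > 0L) {
    stop(sprintf("marker hits reference genome(s) missing from metadata: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  screened <- screen_genomes(hits, evalue_max = cfg$evalue_max,
                             flag_threshold = cfg$flag_threshold)
  readr::write_tsv(screened, file.path(cfg$out_dir, "screened.tsv"))
  derep <- NULL
  if (!is.null(cfg$ani_table)) {
    edges <- read_ani_table(cfg$ani_table)
    stopifnot("length_bp" %in% names(genomes))
    derep <- dereplicate(genomes, edges, cfg$ani_min, cfg$af_min)
    readr::write_tsv(derep, file.path(cfg$out_dir, "phylotypes.tsv"))
  }

  # --- stage 2: detection --------------------------------------------------
  log_msg("calling presence from depth profiles")
  depth <- read_depth_dir(cfg$depth_dir)
  unknown <- setdiff(unique(depth$genome_id), genomes$genome_id)
  if (length(unknown) > 0L) {
    stop(sprintf("depth tables reference genome(s) missing from metadata: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  len_col <- if ("detection_length_bp" %in% names(genomes))
    "detection_length_bp" else "length_bp"
  glen <- stats::setNames(genomes[[len_col]], genomes$genome_id)
  summaries <- depth_summaries(depth, glen, min_depth = cfg$min_depth)
  m <- detection_matrix(summaries, genomes = genomes$genome_id,
                        samples = samples$sample_id,
                        min_breadth = cfg$min_breadth)
  long <- write_detection_matrix(
    m, samples,
    path_wide = file.path(cfg$out_dir, "detection_matrix.tsv"),
    path_long = file.path(cfg$out_dir, "detection_long.tsv"))
  profiles_t <- temperature_profile(m, samples)
  readr::write_tsv(profiles_t, file.path(cfg$out_dir, "temperature_profiles.tsv"))
  g_src <- stats::setNames(genomes$environment, genomes$genome_id)
  endem <- endemicity_summary(m, samples, g_src)
  readr::write_tsv(endem$per_source, file.path(cfg$out_dir, "endemicity_by_source.tsv"))
  readr::write_tsv(endem$per_sample, file.path(cfg$out_dir, "endemicity_by_sample.tsv"))
  corr <- temp_detection_correlation(m, samples, seed = cfg$seed)

  # --- stage 3: composition ------------------------------------------------
  log_msg("comparing protein composition in shared orthogroups")
  proteins <- read_proteins(cfg$proteins, cfg$protein_genome_map)
  unknown <- setdiff(unique(proteins$genome_id), genomes$genome_id)
  if (length(unknown) > 0L) {
    stop(sprintf("proteins reference genome(s) missing from metadata: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  proteins$environment <- genomes$environment[match(proteins$genome_id,
                                                    genomes$genome_id)]
  ogs <- read_orthogroups(cfg$orthogroups)
  common <- select_common_orthogroups(
    ogs, proteins[, c("protein_id", "environment")])
  member <- ogs$protein_id[ogs$og_id %in% common]
  prof <- composition_profiles(proteins[proteins$protein_id %in% member, ])
  comparison <- compare_cold_vs_temperate(prof)
  readr::write_tsv(comparison, file.path(cfg$out_dir, "composition_comparison.tsv"))

  # --- stage 4: KO enrichment ---------------------------------------------
  log_msg("classifying KO prevalence ratios")
  ko <- read_ko_table(cfg$ko_table)
  ko_classes <- classify_kos(ko, genomes,
                             min_genomes_per_env = cfg$min_genomes_per_env,
                             fold = cfg$fold)
  readr::write_tsv(ko_classes, file.path(cfg$out_dir, "ko_classes.tsv"))
  breakdown <- NULL
  if (!is.null(cfg$ko_categories)) {
    breakdown <- category_breakdown(ko_classes, read_ko_categories(cfg$ko_categories))
    readr::write_tsv(breakdown$top, file.path(cfg$out_dir, "ko_categories_top.tsv"))
    if (!is.null(breakdown$sub)) {
      readr::write_tsv(breakdown$sub, file.path(cfg$out_dir, "ko_categories_sub.tsv"))
    }
  }

  # --- manifest ------------------------------------------------------------
  outputs <- list.files(cfg$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_genomes = nrow(genomes),
    n_samples = nrow(samples),
    n_screened_viral = sum(screened$taxon != "none"),
    n_phylotypes = if (is.null(derep)) NA else length(unique(derep$representative_id)),
    n_detections = sum(m),
    n_common_orthogroups = length(common),
    n_proteins_compared = nrow(prof),
    n_kos = nrow(ko_classes),
    n_cold_exclusive = sum(ko_classes$class == "cold_exclusive"),
    n_cold_overrepresented = sum(ko_classes$class == "cold_overrepresented"),
    temp_detection_rho = corr$rho,
    temp_detection_p = corr$p,
    output_md5 = as.list(file_hash(outputs))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("done; outputs in %s", cfg$out_dir)
  invisible(list(screened = screened, dereplication = derep,
                 detection = m, detection_long = long,
                 temperature_profiles = profiles_t, endemicity = endem,
                 correlation = corr, composition = comparison,
                 ko_classes = ko_classes, ko_breakdown = breakdown,
                 manifest = manifest))
}
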