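# Readers and writers for the plain-text formats the pipeline consumes:
# HMMER tblout / TSV marker hits, per-base depth tables, orthogroup tables
# (2-column TSV or the "OG: member member ..." dialect), KO tables, protein
# FASTA, and genome/sample metadata.

read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a marker-hit table
#'
#' Accepts either the HMMER3 `--tblout` format (whitespace-delimited, `#`
#' comment lines; the target name is taken as the genome id, the query name
#' as the marker id, with the full-sequence E-value and score) or a plain
#' TSV with header columns `genome_id`, `marker_id`, `evalue`, `score`
#' (optionally `marker_set`).
#'
#' @param path File path.
#' @param marker_set Marker set the file was searched against (`"GVOG7"`,
#'   `"MIRUS5"`, `"MIRUS4"`, `"CELL56"`); required for tblout input and for
#'   TSV input lacking a `marker_set` column.
#' @return Tibble `genome_id`, `marker_id`, `evalue`, `score`, `marker_set`.
#' @export
read_marker_hits <- function(path, marker_set = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  is_tblout <- length(body) > 0L &&
    length(strsplit(trimws(body[1]), "\\s+")[[1]]) >= 18L
  if (is_tblout) {
    if (is.null(marker_set)) {
      stop("marker_set must be given for HMMER tblout input", call. = FALSE)
    }
    fields <- strsplit(trimws(body), "\\s+")
    out <- tibble::tibble(
      genome_id = vapply(fields, `[`, character(1), 1L),
      marker_id = vapply(fields, `[`, character(1), 3L),
      evalue = as.numeric(vapply(fields, `[`, character(1), 5L)),
      score = as.numeric(vapply(fields, `[`, character(1), 6L)),
      marker_set = marker_set
    )
  } else {
    out <- read_tsv_quiet(path)
    assert_cols(out, c("genome_id", "marker_id", "evalue", "score"),
                sprintf("marker hit table %s", path))
    if (!"marker_set" %in% names(out)) {
      if (is.null(marker_set)) {
        stop("marker_set must be given when the TSV lacks a marker_set column",
             call. = FALSE)
      }
      out$marker_set <- marker_set
    }
  }
  if (any(is.na(out$evalue)) || any(out$evalue < 0)) {
    stop(sprintf("invalid E-values in %s", path), call. = FALSE)
  }
  out
}

#' Read a per-base depth table
#'
#' Three-column TSV as emitted by `samtools depth`-style tools: reference
#' name, 1-based position, depth. A header is optional (detected by a
#' non-numeric second field on the first line). Positions absent from the
#' file are depth 0.
#'
#' @param path File path.
#' @param sample_id Sample the table belongs to (defaults to the file name
#'   without extension).
#' @return Tibble `genome_id`, `sample_id`, `pos`, `depth`.
#' @export
read_depth_table <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t")[[1]][2])))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          col.names = c("genome_id", "pos", "depth"),
                          colClasses = c("character", "integer", "numeric"))
  tibble::tibble(genome_id = df$genome_id, sample_id = sample_id,
                 pos = df$pos, depth = df$depth)
}

#' Read all depth tables in a directory
#'
#' Each `*.tsv` file is one sample, named after the file.
#'
#' @param dir Directory of depth TSVs.
#' @return Combined tibble as in [read_depth_table()].
#' @export
read_depth_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stop(sprintf("no depth tables in %s", dir), call. = FALSE)
  dplyr::bind_rows(lapply(files, read_depth_table))
}

#' Read an orthogroup membership table
#'
#' Accepts a 2-column TSV with header `og_id`, `protein_id`, or the
#' colon-separated dialect (`OG0001: prot1 prot2 ...`) written by
#' orthogroup-inference tools.
#'
#' @param path File path.
#' @return Tibble `og_id`, `protein_id`.
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl(":", first, fixed = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, ":", fixed = TRUE)
    ogs <- trimws(vapply(parts, `[`, character(1), 1L))
    members <- strsplit(trimws(vapply(parts, `[`, character(1), 2L)), "\\s+")
    tibble::tibble(og_id = rep(ogs, lengths(members)),
                   protein_id = unlist(members))
  } else {
    out <- read_tsv_quiet(path)
    assert_cols(out, c("og_id", "protein_id"), sprintf("orthogroup table %s", path))
    out[, c("og_id", "protein_id")]
  }
}

#' Read a KO annotation table
#'
#' Accepts a 2-column TSV (`genome_id`, `ko_id`) or a 3-column TSV
#' (`protein_id`, `ko_id`, `genome_id`); identified by the header.
#'
#' @param path File path.
#' @return Tibble `genome_id`, `ko_id` (unique pairs).
#' @export
read_ko_table <- function(path) {
  out <- read_tsv_quiet(path)
  if (all(c("genome_id", "ko_id") %in% names(out))) {
    out <- out[, c("genome_id", "ko_id")]
  } else if (all(c("protein_id", "ko_id", "genome_id") %in% names(out))) {
    out <- out[, c("genome_id", "ko_id")]
  } else {
    stop(sprintf("KO table %s needs columns (genome_id, ko_id) or (protein_id, ko_id, genome_id)",
                 path), call. = FALSE)
  }
  dplyr::distinct(out)
}

#' Read a KO functional-category map
#'
#' TSV with columns `ko_id`, `top_category` and optionally `sub_category`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_ko_categories <- function(path) {
  out <- read_tsv_quiet(path)
  assert_cols(out, c("ko_id", "top_category"), sprintf("KO category map %s", path))
  out
}

#' Read protein sequences from FASTA
#'
#' @param path Protein FASTA path.
#' @param genome_map Optional path to a 2-column TSV (`protein_id`,
#'   `genome_id`) assigning proteins to genomes.
#' @return Tibble `protein_id`, `sequence` (plus `genome_id` when a map is
#'   given; unmapped proteins error).
#' @export
read_proteins <- function(path, genome_map = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  out <- tibble::tibble(protein_id = sub("\\s.*$", "", names(aa)),
                        sequence = unname(as.character(aa)))
  if (!is.null(genome_map)) {
    map <- read_tsv_quiet(genome_map)
    assert_cols(map, c("protein_id", "genome_id"), "protein-genome map")
    idx <- match(out$protein_id, map$protein_id)
    if (any(is.na(idx))) {
      stop(sprintf("protein(s) missing from the genome map: %s",
                   paste(utils::head(out$protein_id[is.na(idx)], 5),
                         collapse = ", ")), call. = FALSE)
    }
    out$genome_id <- map$genome_id[idx]
  }
  out
}

#' Write protein sequences to FASTA
#'
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  assert_cols(proteins, c("protein_id", "sequence"), "protein table")
  aa <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                proteins$protein_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read genome metadata
#'
#' TSV with columns `genome_id`, `environment` and optionally
#' `size_fraction`, `length_bp`, `taxon`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_genome_meta <- function(path) {
  out <- read_tsv_quiet(path)
  assert_cols(out, c("genome_id", "environment"), sprintf("genome metadata %s", path))
  assert_envs(out$environment)
  out
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `temperature_C`, `source` and optionally
#' `size_fraction`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_sample_meta <- function(path) {
  out <- read_tsv_quiet(path)
  assert_cols(out, c("sample_id", "temperature_C", "source"),
              sprintf("sample metadata %s", path))
  assert_envs(out$source, "sample source")
  out
}

#' Read an ANI/AF table
#'
#' Four-column TSV: query genome, reference genome, ANI percent, aligned
#' fraction percent. Header optional; columns are taken positionally when
#' the expected names are absent.
#'
#' @param path File path.
#' @return Tibble `genome_a`, `genome_b`, `ani_pct`, `af_pct`.
#' @export
read_ani_table <- function(path) {
  out <- read_tsv_quiet(path)
  want <- c("genome_a", "genome_b", "ani_pct", "af_pct")
  if (!all(want %in% names(out))) {
    if (ncol(out) < 4L) stop(sprintf("ANI table %s needs 4 columns", path),
                             call. = FALSE)
    out <- out[, 1:4]
    names(out) <- want
  }
  out[, want]
}

#' Read CDS intervals from GFF3 for genetic-code selection
#'
#' Extracts CDS feature intervals (only seqid/start/end are used) and
#' converts the 1-based inclusive GFF coordinates to the 0-based half-open
#' intervals used internally. Requires the rtracklayer package.
#'
#' @param path GFF3 path.
#' @param genetic_code Genetic code the predictions were made under.
#' @param genome_lengths Named vector of genome lengths.
#' @return Named list of [cds_interval_set()] objects, one per seqid.
#' @export
read_cds_gff <- function(path, genetic_code, genome_lengths) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gff <- rtracklayer::readGFF(path, columns = c("seqid", "start", "end", "type"))
  gff <- as.data.frame(gff)
  gff <- gff[gff$type == "CDS", , drop = FALSE]
  lapply(split(gff, droplevels(factor(gff$seqid))), function(g) {
    gl <- genome_lengths[[as.character(g$seqid[1])]]
    if (is.null(gl)) stop(sprintf("no length for genome %s", g$seqid[1]),
                          call. = FALSE)
    cds_interval_set(genetic_code, cbind(g$start - 1L, g$end), gl)
  })
}

#' Write a detection matrix
#'
#' Writes both the wide 0/1 matrix and a long format (genome, sample,
#' present, temperature).
#'
#' @param m Detection matrix.
#' @param meta Sample metadata.
#' @param path_wide,path_long Output paths (either may be `NULL`).
#' @return Invisibly, the long-format tibble.
#' @export
write_detection_matrix <- function(m, meta, path_wide = NULL, path_long = NULL) {
  wide <- tibble::as_tibble(as.data.frame(m * 1L), rownames = "genome_id")
  if (!is.null(path_wide)) readr::write_tsv(wide, path_wide)
  long <- tibble::tibble(
    genome_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    present = as.integer(m),
    temperature_C = rep(meta$temperature_C[match(colnames(m), meta$sample_id)],
                        each = nrow(m)))
  if (!is.null(path_long)) readr::write_tsv(long, path_long)
  invisible(long)
}
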