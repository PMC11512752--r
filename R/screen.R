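# Marker-based screening of candidate giant-virus MAGs: genetic-code choice
# by coding density, NCLDV / Mirusviricota classification from marker-hit
# tables, cellular-marker contamination counts, and ANI/AF dereplication.

#' Construct a CDS interval set for one genetic-code candidate
#'
#' Holds the coding intervals predicted on a genome under one genetic code.
#' Intervals are 0-based half-open `[start, end)`; GFF-style 1-based inclusive
#' coordinates are converted at the I/O layer ([read_cds_gff()]).
#'
#' @param genetic_code One of 1, 4, 6, 11 (the codes tried during gene
#'   prediction on viral bins).
#' @param intervals Two-column matrix or data frame of `start`, `end`
#'   (0-based half-open). May have zero rows.
#' @param genome_length Genome length in bp (> 0).
#' @return Object of class `cds_intervals`.
#' @export
#' @examples
#' cds <- cds_interval_set(11, cbind(0, 900), 1000)
#' coding_density(cds)
cds_interval_set <- function(genetic_code, intervals, genome_length) {
  if (!genetic_code %in% c(1, 4, 6, 11)) {
    stop("genetic_code must be one of 1, 4, 6, 11", call. = FALSE)
  }
  if (length(genome_length) != 1L || is.na(genome_length) || genome_length <= 0) {
    stop("genome_length must be a single positive number", call. = FALSE)
  }
  intervals <- as.matrix(intervals)
  if (nrow(intervals) > 0L) {
    if (ncol(intervals) < 2L) stop("intervals needs columns start, end", call. = FALSE)
    intervals <- intervals[, 1:2, drop = FALSE]
    storage.mode(intervals) <- "double"
    bad <- intervals[, 1] < 0 | intervals[, 1] >= intervals[, 2] |
      intervals[, 2] > genome_length
    if (any(bad)) {
      stop(sprintf("%d interval(s) violate 0 <= start < end <= genome_length",
                   sum(bad)), call. = FALSE)
    }
  } else {
    intervals <- matrix(numeric(0), ncol = 2)
  }
  colnames(intervals) <- c("start", "end")
  structure(list(genetic_code = as.integer(genetic_code),
                 intervals = intervals,
                 genome_length = as.numeric(genome_length)),
            class = "cds_intervals")
}

#' Coding density of a CDS interval set
#'
#' Fraction of genome positions covered by at least one coding interval;
#' overlapping intervals are counted once.
#'
#' @param cds A [cds_interval_set()].
#' @return Fraction in `[0, 1]`.
#' @export
coding_density <- function(cds) {
  stopifnot(inherits(cds, "cds_intervals"))
  iv <- cds$intervals
  if (nrow(iv) == 0L) return(0)
  o <- order(iv[, 1], iv[, 2])
  s <- iv[o, 1]; e <- iv[o, 2]
  covered <- 0
  cur_s <- s[1]; cur_e <- e[1]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      if (s[i] <= cur_e) {
        cur_e <- max(cur_e, e[i])
      } else {
        covered <- covered + (cur_e - cur_s)
        cur_s <- s[i]; cur_e <- e[i]
      }
    }
  }
  covered <- covered + (cur_e - cur_s)
  as.numeric(covered / cds$genome_length)
}

#' Pick the genetic code with the highest coding density
#'
#' Mirrors the gene-prediction step in which codes 1, 4, 6 and 11 are tried
#' on each viral bin and the one yielding the highest coding density wins.
#' Ties are broken by the lowest code number.
#'
#' @param candidates List of [cds_interval_set()] objects for one genome;
#'   all must share the same `genome_length`.
#' @return The winning genetic code (integer).
#' @export
pick_genetic_code <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidate interval sets supplied", call. = FALSE)
  stopifnot(all(vapply(candidates, inherits, logical(1), "cds_intervals")))
  lens <- vapply(candidates, function(x) x$genome_length, numeric(1))
  if (length(unique(lens)) != 1L) {
    stop("all candidates must describe the same genome (equal genome_length)",
         call. = FALSE)
  }
  codes <- vapply(candidates, function(x) x$genetic_code, integer(1))
  dens <- vapply(candidates, coding_density, numeric(1))
  best <- which(dens == max(dens))
  codes[best][which.min(codes[best])]
}

normalize_hits <- function(hits, set_filter = NULL) {
  assert_cols(hits, c("marker_id", "evalue"), "marker hit table")
  if (!is.null(set_filter) && "marker_set" %in% names(hits)) {
    hits <- hits[hits$marker_set %in% set_filter, , drop = FALSE]
  }
  if (any(hits$evalue < 0, na.rm = TRUE)) stop("E-values must be >= 0", call. = FALSE)
  hits
}

#' Classify a genome as Nucleocytoviricota from GVOG marker hits
#'
#' A genome is called NCLDV when hits to more than one distinct marker of the
#' seven-gene GVOG set (SFII, RNAPL, PolB, TFIIB, TopoII, A32, VLTF3) pass
#' the E-value cutoff.
#'
#' @param hits Data frame of hits for one genome with columns `marker_id`,
#'   `evalue` (and optionally `marker_set`, which is then filtered to
#'   `"GVOG7"`).
#' @param evalue_max Inclusive E-value cutoff (default `1e-10`).
#' @return `TRUE`/`FALSE`.
#' @export
#' @examples
#' classify_ncldv(data.frame(marker_id = c("PolB", "A32"),
#'                           evalue = c(1e-20, 1e-15)))
classify_ncldv <- function(hits, evalue_max = 1e-10) {
  hits <- normalize_hits(hits, "GVOG7")
  ok <- hits$evalue <= evalue_max
  unknown <- setdiff(unique(hits$marker_id), giant_virus_marker_sets()$GVOG7)
  if (length(unknown) > 0L) {
    stop(sprintf("marker id(s) not in the GVOG7 set: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  length(unique(hits$marker_id[ok])) >= 2L
}

#' Classify a genome as Mirusviricota from marker hits
#'
#' A single passing hit against either the five-gene morphogenesis module
#' (HK97-fold MCP, Triplex1/2, Maturation, Portal) or the four informational
#' markers (RNAPL, RNAPS, PolB, TFIIS) suffices.
#'
#' @inheritParams classify_ncldv
#' @return `TRUE`/`FALSE`.
#' @export
classify_mirus <- function(hits, evalue_max = 1e-10) {
  hits <- normalize_hits(hits, c("MIRUS5", "MIRUS4"))
  sets <- giant_virus_marker_sets()
  unknown <- setdiff(unique(hits$marker_id), c(sets$MIRUS5, sets$MIRUS4))
  if (length(unknown) > 0L) {
    stop(sprintf("marker id(s) not in the Mirusviricota sets: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  any(hits$evalue <= evalue_max)
}

#' Count cellular-marker hits in a genome
#'
#' Screens a genome's hits against the 56 cellular single-copy markers used
#' to gauge contamination. The flag threshold is configurable because only a
#' "low copy number" is expected of a clean viral genome.
#'
#' @param hits Data frame with columns `marker_id`, `evalue` (optionally
#'   `marker_set`, filtered to `"CELL56"`).
#' @param evalue_max Inclusive E-value cutoff.
#' @param flag_threshold Total passing hits above which the genome is
#'   flagged as possibly contaminated (default 5).
#' @return List with `counts` (named integer vector per marker), `total`,
#'   and `flagged`.
#' @export
cellular_marker_copies <- function(hits, evalue_max = 1e-10, flag_threshold = 5) {
  hits <- normalize_hits(hits, "CELL56")
  ok <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  counts <- if (nrow(ok) == 0L) integer(0) else table(ok$marker_id)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  list(counts = counts, total = total, flagged = total > flag_threshold)
}

#' Dereplicate genomes into species-level phylotypes
#'
#' Builds a graph whose edges are genome pairs with ANI >= `ani_min` and
#' alignment fraction >= `af_min` (both inclusive; the standard species rank
#' thresholds are 95% ANI over 85% AF), takes single-linkage clusters as
#' connected components, and elects the longest genome of each cluster as
#' representative (ties by lexicographically smallest id).
#'
#' @param genomes Data frame with columns `genome_id`, `length_bp`.
#' @param edges Data frame with columns `genome_a`, `genome_b`, `ani_pct`,
#'   `af_pct`. Self-edges are ignored; edges naming unknown genomes error.
#' @param ani_min,af_min Thresholds in percent.
#' @return Tibble with columns `genome_id`, `representative_id`, `cluster`.
#' @export
dereplicate <- function(genomes, edges, ani_min = 95, af_min = 85) {
  assert_cols(genomes, c("genome_id", "length_bp"), "genome table")
  if (anyDuplicated(genomes$genome_id)) stop("duplicate genome_id", call. = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(genome_a = character(0), genome_b = character(0),
                        ani_pct = numeric(0), af_pct = numeric(0))
  }
  assert_cols(edges, c("genome_a", "genome_b", "ani_pct", "af_pct"), "ANI table")
  unknown <- setdiff(unique(c(edges$genome_a, edges$genome_b)), genomes$genome_id)
  if (length(unknown) > 0L) {
    stop(sprintf("ANI edge references unknown genome(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  edges <- edges[edges$genome_a != edges$genome_b &
                   edges$ani_pct >= ani_min & edges$af_pct >= af_min, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("genome_a", "genome_b")], directed = FALSE,
    vertices = genomes$genome_id)
  comp <- igraph::components(g)$membership
  comp <- comp[genomes$genome_id]
  reps <- vapply(split(seq_len(nrow(genomes)), comp), function(idx) {
    sub <- genomes[idx, ]
    sub <- sub[order(-sub$length_bp, sub$genome_id), ]
    sub$genome_id[1]
  }, character(1))
  tibble::tibble(genome_id = genomes$genome_id,
                 representative_id = unname(reps[as.character(comp)]),
                 cluster = as.integer(comp))
}

#' Screen a collection of genomes with the viral marker rules
#'
#' Applies [classify_ncldv()] and [classify_mirus()] genome-by-genome to a
#' combined hit table and counts cellular-marker hits. A genome positive for
#' both rules is labelled NCLDV (the GVOG rule takes precedence). An optional
#' `keep`/`drop` list stands in for the phylogeny-based confirmation step of
#' a full analysis (tree inference is out of scope here): dropped genomes are
#' demoted to `"none"`, kept genomes are retained regardless of markers.
#'
#' @param hits Data frame with columns `genome_id`, `marker_id`, `evalue`,
#'   `marker_set` (one of `"GVOG7"`, `"MIRUS5"`, `"MIRUS4"`, `"CELL56"`).
#' @param evalue_max Inclusive E-value cutoff applied to all sets.
#' @param flag_threshold Passed to [cellular_marker_copies()].
#' @param keep,drop Optional character vectors of genome ids.
#' @return Tibble with one row per genome: marker counts, the two class
#'   calls, `taxon` (`"NCLDV"`, `"Mirus"` or `"none"`), cellular totals and
#'   the contamination flag.
#' @export
screen_genomes <- function(hits, evalue_max = 1e-10, flag_threshold = 5,
                           keep = NULL, drop = NULL) {
  assert_cols(hits, c("genome_id", "marker_id", "evalue", "marker_set"),
              "marker hit table")
  res <- lapply(split(hits, hits$genome_id), function(h) {
    gv <- h[h$marker_set == "GVOG7", , drop = FALSE]
    mi <- h[h$marker_set %in% c("MIRUS5", "MIRUS4"), , drop = FALSE]
    ce <- h[h$marker_set == "CELL56", , drop = FALSE]
    is_ncldv <- classify_ncldv(gv, evalue_max)
    is_mirus <- classify_mirus(mi, evalue_max)
    cell <- cellular_marker_copies(ce, evalue_max, flag_threshold)
    tibble::tibble(
      genome_id = h$genome_id[1],
      n_gvog_markers = length(unique(gv$marker_id[gv$evalue <= evalue_max])),
      n_mirus_hits = sum(mi$evalue <= evalue_max),
      is_ncldv = is_ncldv,
      is_mirus = is_mirus,
      n_cellular = cell$total,
      contamination_flagged = cell$flagged
    )
  })
  out <- dplyr::bind_rows(res)
  out$taxon <- ifelse(out$is_ncldv, "NCLDV", ifelse(out$is_mirus, "Mirus", "none"))
  if (!is.null(drop)) out$taxon[out$genome_id %in% drop] <- "none"
  if (!is.null(keep)) {
    # keep shields a genome from drop but cannot invent marker evidence
    shield <- out$genome_id %in% keep
    out$taxon[shield & out$is_ncldv] <- "NCLDV"
    out$taxon[shield & !out$is_ncldv & out$is_mirus] <- "Mirus"
  }
  out[order(out$genome_id), ]
}
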