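# Shared constants: alphabets, hydropathy table, marker sets, ecosystem labels.

# The 20 standard residues, alphabetical by one-letter code. Column order of
# every frequency matrix in the package.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residues tolerated in input sequences but excluded from every numerator and
# denominator: ambiguity codes, selenocysteine, stops.
AA_EXCLUDED <- c("X", "B", "Z", "U", "*")

#' Kyte-Doolittle hydropathy values
#'
#' The per-residue hydropathy scale used for the grand average of hydropathy
#' (GRAVY). Positive values are hydrophobic.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
#' @examples
#' kyte_doolittle()[c("A", "I")]
kyte_doolittle <- function() {
  c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
    G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
    M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)
}

#' Default residue classes for composition summaries
#'
#' Acidic = D,E; charged = acidic plus the basic residues K,R,H; polar
#' uncharged = S,T,N,Q,C,Y. Histidine is counted as charged here; all three
#' sets can be overridden in [residue_class_fractions()].
#'
#' @return Named list of character vectors `acidic`, `charged`,
#'   `polar_uncharged`.
#' @export
default_residue_classes <- function() {
  list(acidic          = c("D", "E"),
       charged         = c("D", "E", "K", "R", "H"),
       polar_uncharged = c("S", "T", "N", "Q", "C", "Y"))
}

#' Marker-gene sets used for giant-virus screening
#'
#' `GVOG7` are the seven Nucleocytoviricota orthologous groups (a genome with
#' hits to more than one of them is called NCLDV); `MIRUS5` the five
#' Mirusviricota morphogenesis markers and `MIRUS4` the four informational
#' markers (one hit to either set calls Mirusviricota); `CELL56` is a set of
#' 56 cellular single-copy markers used to gauge contamination (identifiers
#' are placeholders -- any id is accepted for this set).
#'
#' @return Named list of character vectors.
#' @export
#' @examples
#' giant_virus_marker_sets()$GVOG7
giant_virus_marker_sets <- function() {
  list(
    GVOG7  = c("SFII", "RNAPL", "PolB", "TFIIB", "TopoII", "A32", "VLTF3"),
    MIRUS5 = c("HK97-MCP", "Triplex1", "Triplex2", "Maturation", "Portal"),
    MIRUS4 = c("RNAPL", "RNAPS", "PolB", "TFIIS"),
    CELL56 = sprintf("CM%02d", 1:56)
  )
}

#' Marine ecosystem labels
#'
#' The four source ecosystems compared throughout: three cold (Antarctic,
#' Arctic, Patagonia) and one temperate pool.
#'
#' @return Character vector of the four labels.
#' @export
gv_environments <- function() c("Antarctic", "Arctic", "Patagonia", "Temperate")

#' @rdname gv_environments
#' @export
cold_environments <- function() c("Antarctic", "Arctic", "Patagonia")

# Background amino-acid frequencies (Swiss-Prot averages), normalised to 1.
# Default composition of synthetic temperate proteomes.
swissprot_background <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86,
         G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
         M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
         S = 6.64, T = 5.35, V = 6.86, W = 1.10, Y = 2.92)
  f / sum(f)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

assert_envs <- function(x, what = "environment") {
  bad <- setdiff(unique(x), gv_environments())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s label(s): %s (expected one of %s)", what,
                 paste(bad, collapse = ", "),
                 paste(gv_environments(), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
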