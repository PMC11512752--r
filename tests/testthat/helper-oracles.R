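# Independent oracles and small fixture builders used across the suite.

# Brute-force Mann-Whitney: enumerate every assignment of group labels to
# the observed values and compute the two-sided tail probability of U
# directly from the enumerated null distribution.
bf_mann_whitney <- function(x, y) {
  vals <- c(x, y)
  m <- length(x)
  r <- rank(vals)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  combos <- utils::combn(length(vals), m)
  u_all <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(m))
  p <- min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
  list(u = u_obs, p = p)
}

# Exhaustive permutation p for the Spearman temperature-detection test,
# enumerating permutations by filtering the full index grid (a different
# algorithm from the package's recursive generator).
oracle_spearman_perm_p <- function(temp, counts) {
  n <- length(temp)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  distinct <- apply(grid, 1, function(r) length(unique(r)) == n)
  grid <- grid[distinct, , drop = FALSE]
  rho_obs <- stats::cor(temp, counts, method = "spearman")
  rhos <- apply(grid, 1, function(idx)
    stats::cor(temp[idx], counts, method = "spearman"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Toy genome metadata: n_cold cold genomes (Antarctic) and n_temp temperate.
toy_genome_env <- function(n_cold = 20, n_temp = 30, cold_env = "Antarctic") {
  tibble::tibble(
    genome_id = c(sprintf("C%02d", seq_len(n_cold)),
                  sprintf("T%02d", seq_len(n_temp))),
    environment = c(rep(cold_env, n_cold), rep("Temperate", n_temp)))
}

# KO presence table: the KO is carried by the first n_in_cold cold genomes
# and the first n_in_temp temperate genomes.
toy_ko_table <- function(ko, n_in_cold, n_in_temp, n_cold = 20, n_temp = 30) {
  tibble::tibble(
    genome_id = c(sprintf("C%02d", seq_len(n_in_cold)),
                  sprintf("T%02d", seq_len(n_in_temp))),
    ko_id = ko)
}

# Detection matrix from a named list sample -> detected genome ids.
toy_detection_matrix <- function(detections, genomes) {
  m <- matrix(FALSE, length(genomes), length(detections),
              dimnames = list(genomes, names(detections)))
  for (s in names(detections)) m[detections[[s]], s] <- TRUE
  m
}
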