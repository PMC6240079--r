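# Builders for small in-code fixtures. flux_row() gives one canonical
# forest GPP record; override any field to construct a path of interest.

flux_row <- function(record_id = "r1", study_id = "s1", ecosystem = "forest",
                     climate = "temperate", flux_class = "gpp",
                     material_origin = "none", driver = "none",
                     donor_ecosystem = "none", value = 100,
                     mass_basis = "carbon",
                     spatial_basis = "per_m2_recipient",
                     time_basis = "per_year", ...) {
  tibble::tibble(record_id = record_id, study_id = study_id,
                 ecosystem = ecosystem, climate = climate,
                 flux_class = flux_class, material_origin = material_origin,
                 driver = driver, donor_ecosystem = donor_ecosystem,
                 value = value, mass_basis = mass_basis,
                 spatial_basis = spatial_basis, time_basis = time_basis, ...)
}

flux_fixture <- function(..., strict = TRUE) {
  rows <- dplyr::bind_rows(...)
  rows$record_id <- make.unique(rows$record_id, sep = "_")
  as_flux_table(rows, strict = strict)
}

# Independent brute-force Kruskal-Wallis: explicit pooled ranking, explicit
# tie correction, no calls into the package or stats::kruskal.test.
brute_force_kw <- function(samples) {
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Hand evaluation of the rank-sum critical-difference inequality for the
# post-hoc comparisons, independent of the package implementation.
hand_rank_significance <- function(samples, alpha = 0.05) {
  k <- length(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  n <- length(x)
  mean_ranks <- tapply(rank(x), g, mean)
  ns <- lengths(samples)
  out <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      crit <- qnorm(1 - alpha / (k * (k - 1))) *
        sqrt(n * (n + 1) / 12 * (1 / ns[i] + 1 / ns[j]))
      out[i, j] <- out[j, i] <- abs(mean_ranks[i] - mean_ranks[j]) >= crit
    }
  }
  out
}
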