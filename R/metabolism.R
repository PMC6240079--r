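# Ecosystem metabolism: the three accounting identities linking gross
# primary production, respiration and production terms,
#   NEP = GPP - Re,   NEP = NPP - Rh,   NPP = GPP - Ra,
# plus the statistical treatment of NEP samples: one-sample t tests against
# zero, the normal-model probability of positive NEP, Bartlett's variance
# homogeneity check, Kruskal-Wallis across ecosystems, and Siegel-Castellan
# rank-sum post-hoc comparisons compressed into letter groups.

#' Close a metabolism triplet
#'
#' Given any subset of GPP, ecosystem respiration (`r_e`), NEP, NPP,
#' autotrophic (`r_a`) and heterotrophic (`r_h`) respiration, fills every
#' member derivable from the identities `NEP = GPP - Re`, `NEP = NPP - Rh`
#' and `NPP = GPP - Ra`, iterating until no further member can be derived.
#' Over-determined inputs are checked: any identity whose three members are
#' all known must hold to relative tolerance `tol`, else the result is
#' flagged inconsistent with its worst residual.
#'
#' @param gpp,r_e,nep,npp,r_a,r_h Known fluxes in gC m-2 yr-1, `NA` if
#'   unreported.
#' @param tol Relative tolerance for consistency of complete identities.
#' @return A one-row tibble with the six fluxes, `derived` (list-column of
#'   member names that were filled in), `consistent` and `max_residual`.
#' @examples
#' close_flux_triplet(gpp = 100, r_e = 40)            # NEP = 60
#' close_flux_triplet(npp = 70, r_h = 30, gpp = 100)  # NEP = 40, Ra = 30
#' @export
close_flux_triplet <- function(gpp = NA_real_, r_e = NA_real_,
                               nep = NA_real_, npp = NA_real_,
                               r_a = NA_real_, r_h = NA_real_, tol = 1e-6) {
  v <- c(gpp = gpp, r_e = r_e, nep = nep, npp = npp, r_a = r_a, r_h = r_h)
  known0 <- names(v)[is.finite(v)]
  # each identity as (lhs, a, b): lhs = a - b
  identities <- list(c("nep", "gpp", "r_e"),
                     c("nep", "npp", "r_h"),
                     c("npp", "gpp", "r_a"))
  repeat {
    changed <- FALSE
    for (id in identities) {
      lhs <- id[1]; a <- id[2]; b <- id[3]
      kn <- is.finite(v[c(lhs, a, b)])
      if (sum(kn) == 2) {
        if (!kn[1]) v[lhs] <- v[a] - v[b]
        else if (!kn[2]) v[a] <- v[lhs] + v[b]
        else v[b] <- v[a] - v[lhs]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  max_res <- 0
  for (id in identities) {
    if (all(is.finite(v[id]))) {
      res <- abs(v[id[1]] - (v[id[2]] - v[id[3]]))
      scale <- max(abs(v[id]), 1)
      max_res <- max(max_res, res / scale)
    }
  }
  tibble::tibble(
    gpp = unname(v["gpp"]), r_e = unname(v["r_e"]), nep = unname(v["nep"]),
    npp = unname(v["npp"]), r_a = unname(v["r_a"]), r_h = unname(v["r_h"]),
    derived = list(setdiff(names(v)[is.finite(v)], known0)),
    consistent = max_res <= tol,
    max_residual = max_res
  )
}

#' Derive missing metabolism records within studies
#'
#' For every (study, ecosystem, climate) group of a harmonized table that
#' reports exactly one record each for two of GPP, ecosystem respiration and
#' NEP, appends the third as a derived record (`NEP = GPP - Re`). Groups
#' reporting all three are checked for consistency and flagged via a
#' warning when the identity fails.
#'
#' @param records A harmonized `flux_table`.
#' @param tol Relative tolerance for the consistency check.
#' @return `records` with derived rows appended (`record_id` suffixed
#'   `_derived`).
#' @export
close_metabolism_records <- function(records, tol = 1e-6) {
  trio <- c("gpp", "ecosystem_respiration", "nep")
  wide <- records |>
    dplyr::filter(.data$flux_class %in% trio) |>
    dplyr::group_by(.data$study_id, .data$ecosystem, .data$climate,
                    .data$flux_class) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::select("study_id", "ecosystem", "climate", "flux_class", "value") |>
    tidyr::pivot_wider(names_from = "flux_class", values_from = "value")
  for (cls in trio) if (!cls %in% names(wide)) wide[[cls]] <- NA_real_

  derive <- function(df, target, f) {
    df |>
      dplyr::filter(!is.finite(.data[[target]])) |>
      dplyr::mutate(value = f(.data$gpp, .data$ecosystem_respiration,
                              .data$nep),
                    flux_class = target) |>
      dplyr::filter(is.finite(.data$value))
  }
  new_rows <- dplyr::bind_rows(
    derive(wide, "nep", function(g, r, n) g - r),
    derive(wide, "gpp", function(g, r, n) n + r),
    derive(wide, "ecosystem_respiration", function(g, r, n) g - n)
  )
  full <- wide |>
    dplyr::filter(is.finite(.data$gpp), is.finite(.data$ecosystem_respiration),
                  is.finite(.data$nep)) |>
    dplyr::mutate(resid = abs(.data$nep -
                                (.data$gpp - .data$ecosystem_respiration)) /
                    pmax(abs(.data$gpp), 1))
  if (any(full$resid > tol)) {
    warn(paste0(sum(full$resid > tol),
                " study group(s) report inconsistent GPP/Re/NEP"))
  }
  if (nrow(new_rows) == 0) return(records)

  template <- as_flux_table(tibble::tibble(
    record_id = paste(new_rows$study_id, new_rows$ecosystem,
                      new_rows$flux_class, "derived", sep = "_"),
    study_id = new_rows$study_id, ecosystem = new_rows$ecosystem,
    climate = new_rows$climate, flux_class = new_rows$flux_class,
    material_origin = "none", driver = "none", donor_ecosystem = "none",
    value = new_rows$value, mass_basis = "carbon",
    spatial_basis = "per_m2_recipient", time_basis = "per_year"
  ))
  if ("audit" %in% names(records)) {
    template$audit <- purrr::map(seq_len(nrow(template)), ~ tibble::tibble(
      step = "metabolism_closure", factor = NA_real_,
      rule = "nep_gpp_re_identity"))
  }
  dplyr::bind_rows(records, template)
}

#' One-sample NEP t test and heterotrophy probability
#'
#' Classical two-sided one-sample Student t test of mean NEP against zero,
#' with a 95% confidence interval and `p_plus`, the probability that a
#' random NEP observation from the ecosystem is positive under a normal
#' model of the data: `pnorm(mean / sd)` with the sample standard deviation
#' (the data distribution, not the sampling distribution of the mean).
#'
#' @param values Numeric NEP sample, gC m-2 yr-1 (n >= 2).
#' @param conf_level Confidence level of the interval.
#' @return An object of class `crossflux_nep_test`; see [tidy()] for the
#'   tabular form. Zero-variance samples are flagged `degenerate` with
#'   `p_plus` 0, 0.5 or 1 by the sign of the mean.
#' @examples
#' tidy(nep_ttest(c(-114, -300, -25, -80, 10)))
#' @export
nep_ttest <- function(values, conf_level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) {
    abort("need at least 2 NEP values", class = "crossflux_insufficient_data")
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    out <- list(n = n, mean = m, sd = 0, ci_low = m, ci_high = m,
                t_stat = NA_real_, df = n - 1, p_two_sided = NA_real_,
                p_plus = 0.5 + 0.5 * sign(m), conf_level = conf_level,
                degenerate = TRUE)
    return(structure(out, class = "crossflux_nep_test"))
  }
  tt <- stats::t.test(values, mu = 0, conf.level = conf_level)
  out <- list(n = n, mean = m, sd = s,
              ci_low = unname(tt$conf.int[1]), ci_high = unname(tt$conf.int[2]),
              t_stat = unname(tt$statistic), df = unname(tt$parameter),
              p_two_sided = tt$p.value, p_plus = pnorm(m / s),
              conf_level = conf_level, degenerate = FALSE)
  structure(out, class = "crossflux_nep_test")
}

#' @export
print.crossflux_nep_test <- function(x, ...) {
  cat(sprintf(
    "NEP one-sample t test: n = %d, mean = %.2f [%.2f, %.2f], p = %s, p+ = %.3f\n",
    x$n, x$mean, x$ci_low, x$ci_high,
    if (is.na(x$p_two_sided)) "NA" else format.pval(x$p_two_sided),
    x$p_plus))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.crossflux_nep_test <- function(x, ...) {
  tibble::tibble(n = x$n, mean = x$mean, sd = x$sd, ci_low = x$ci_low,
                 ci_high = x$ci_high, t_stat = x$t_stat, df = x$df,
                 p_two_sided = x$p_two_sided, p_plus = x$p_plus,
                 degenerate = x$degenerate)
}

# Accepts either a named list of samples or (values, group) vectors and
# returns a canonical named list, dropping empty groups with a warning.
as_sample_list <- function(values, group = NULL, min_n = 1) {
  samples <- if (is.list(values)) {
    lapply(values, function(v) v[is.finite(v)])
  } else {
    v <- values[is.finite(values)]
    split(v, factor(group[is.finite(values)]))
  }
  sizes <- lengths(samples)
  if (any(sizes < min_n)) {
    warn(paste0("excluding group(s) with fewer than ", min_n, " values: ",
                paste(names(samples)[sizes < min_n], collapse = ", ")))
    samples <- samples[sizes >= min_n]
  }
  samples
}

#' Bartlett's test of NEP variance homogeneity
#'
#' Used to decide between the parametric and rank-based comparison of NEP
#' across ecosystems: heterogeneous variances justify the non-parametric
#' path. Groups with fewer than 2 values are excluded with a warning.
#'
#' @param values Either a named list of numeric samples, or a numeric
#'   vector paired with `group`.
#' @param group Grouping vector when `values` is a vector.
#' @return A tibble with `statistic`, `df` and `p_value`.
#' @export
bartlett_test <- function(values, group = NULL) {
  samples <- as_sample_list(values, group, min_n = 2)
  if (length(samples) < 2) {
    abort("need at least 2 groups with n >= 2",
          class = "crossflux_insufficient_data")
  }
  bt <- stats::bartlett.test(samples)
  tibble::tibble(statistic = unname(bt$statistic),
                 df = unname(bt$parameter), p_value = bt$p.value)
}

#' Kruskal-Wallis rank test across ecosystems
#'
#' Rank-based comparison of NEP distributions among ecosystem types, with
#' the standard tie correction; the statistic is referred to a chi-square
#' distribution with (groups - 1) degrees of freedom.
#'
#' @inheritParams bartlett_test
#' @return An object of class `crossflux_kw` carrying `chi2`, `df`,
#'   `n_total`, `p_value`, per-group sizes and mean ranks.
#' @examples
#' kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(101, 102, 103)))
#' glance(kw)
#' @export
kruskal_wallis <- function(values, group = NULL) {
  samples <- as_sample_list(values, group, min_n = 1)
  if (length(samples) < 2) {
    abort("need at least 2 non-empty groups",
          class = "crossflux_insufficient_data")
  }
  pooled <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)), levels = names(samples))
  if (length(unique(pooled)) == 1) {
    # every observation tied: no rank information, statistic is zero
    kt <- list(statistic = 0, parameter = length(samples) - 1, p.value = 1)
  } else {
    kt <- stats::kruskal.test(pooled, g)
  }
  r <- rank(pooled)
  out <- list(
    chi2 = unname(kt$statistic), df = unname(kt$parameter),
    n_total = length(pooled), p_value = kt$p.value,
    groups = tibble::tibble(
      group = names(samples), n = unname(lengths(samples)),
      mean_rank = unname(tapply(r, g, mean)))
  )
  structure(out, class = "crossflux_kw")
}

#' @export
print.crossflux_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi2(%d, n = %d) = %.2f, p = %s\n",
              x$df, x$n_total, x$chi2, format.pval(x$p_value)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.crossflux_kw <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, n_total = x$n_total,
                 p_value = x$p_value)
}

#' @exportS3Method generics::tidy
tidy.crossflux_kw <- function(x, ...) x$groups

#' Siegel-Castellan post-hoc rank comparisons with letter groups
#'
#' After a Kruskal-Wallis test, compares every pair of groups on mean ranks
#' of the pooled sample: groups i and j differ when
#' `|Ri - Rj| >= z(1 - alpha / (K (K - 1))) * sqrt(N (N + 1) / 12 * (1/ni + 1/nj))`,
#' the Siegel-Castellan critical difference at family alpha. The resulting
#' significance pattern is compressed into a compact letter display: groups
#' sharing any letter are not significantly different. Letter assignment
#' follows the insert-and-absorb algorithm, with groups processed in input
#' order for reproducibility.
#'
#' @inheritParams bartlett_test
#' @param family_alpha Family-wise alpha for the pairwise critical
#'   difference (default 0.05).
#' @return A tibble with `group`, `n`, `mean_rank` and `letters`; the
#'   pairwise table is attached as attribute `"pairs"` (with `diff`,
#'   `critical`, `significant`).
#' @examples
#' posthoc_rank_letters(list(a = 1:10, b = 1:10 + 0.5, c = 101:110))
#' @export
posthoc_rank_letters <- function(values, group = NULL, family_alpha = 0.05) {
  samples <- as_sample_list(values, group, min_n = 1)
  k <- length(samples)
  if (k == 1) {
    return(tibble::tibble(group = names(samples), n = lengths(samples),
                          mean_rank = NA_real_, letters = "a"))
  }
  pooled <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)), levels = names(samples))
  n_tot <- length(pooled)
  r <- rank(pooled)
  mean_ranks <- tapply(r, g, mean)
  ns <- lengths(samples)

  z_crit <- qnorm(1 - family_alpha / (k * (k - 1)))
  pairs <- utils::combn(k, 2)
  pair_tbl <- tibble::tibble(
    group1 = names(samples)[pairs[1, ]],
    group2 = names(samples)[pairs[2, ]],
    diff = unname(abs(mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]])),
    critical = unname(z_crit * sqrt(n_tot * (n_tot + 1) / 12 *
                                      (1 / ns[pairs[1, ]] +
                                         1 / ns[pairs[2, ]])))
  )
  pair_tbl$significant <- pair_tbl$diff >= pair_tbl$critical

  sig <- matrix(FALSE, k, k)
  sig[t(pairs)[pair_tbl$significant, , drop = FALSE]] <- TRUE
  sig <- sig | t(sig)
  letters_vec <- compact_letter_display(names(samples), sig)

  out <- tibble::tibble(group = names(samples), n = unname(ns),
                        mean_rank = unname(mean_ranks),
                        letters = unname(letters_vec))
  attr(out, "pairs") <- pair_tbl
  out
}

# Insert-and-absorb compact letter display. `sig` is a K x K logical matrix
# of significant pairs. Returns one letter-string per group.
compact_letter_display <- function(group_names, sig) {
  k <- length(group_names)
  cols <- list(seq_len(k))
  pair_idx <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(pair_idx) > 0) {
    for (p in seq_len(nrow(pair_idx))) {
      i <- pair_idx[p, 1]; j <- pair_idx[p, 2]
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns contained in another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  lab <- vapply(seq_len(k), function(gi) {
    paste0(letters[which(vapply(cols, function(col) gi %in% col, logical(1)))],
           collapse = "")
  }, character(1))
  setNames(lab, group_names)
}

#' Full NEP analysis of a harmonized table
#'
#' Runs, over the NEP records of a harmonized table pooled by ecosystem
#' type: a one-sample t test and heterotrophy probability per ecosystem
#' ([nep_ttest()]), Bartlett's variance-homogeneity check, the
#' Kruskal-Wallis comparison across ecosystems, and Siegel-Castellan
#' post-hoc letter groups.
#'
#' @param records A harmonized `flux_table` containing `nep` records.
#' @param alpha Family alpha for the post-hoc letters.
#' @return An object of class `crossflux_nep_analysis`; `tidy()` gives the
#'   per-ecosystem table (tests + letters), `glance()` the Bartlett and
#'   Kruskal-Wallis block, `autoplot()` the NEP boxplot annotated with
#'   `p_plus` and letters.
#' @export
nep_analysis <- function(records, alpha = 0.05) {
  nep <- dplyr::filter(records, .data$flux_class == "nep")
  if (nrow(nep) == 0) {
    abort("no NEP records", class = "crossflux_insufficient_data")
  }
  eco_order <- intersect(flux_vocab()$ecosystem, unique(nep$ecosystem))
  samples <- lapply(setNames(eco_order, eco_order),
                    function(e) nep$value[nep$ecosystem == e])
  tests <- purrr::map(samples, function(v) {
    if (length(v) >= 2) tidy(nep_ttest(v)) else
      tibble::tibble(n = length(v), mean = mean(v), sd = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_, t_stat = NA_real_,
                     df = NA_real_, p_two_sided = NA_real_, p_plus = NA_real_,
                     degenerate = NA)
  })
  per_eco <- dplyr::bind_rows(tests, .id = "ecosystem")
  kw <- kruskal_wallis(samples)
  letters_tbl <- posthoc_rank_letters(samples, family_alpha = alpha)
  per_eco <- dplyr::left_join(
    per_eco, dplyr::select(letters_tbl, "group", "letters"),
    by = c(ecosystem = "group"))
  bart <- tryCatch(bartlett_test(samples),
                   error = function(e) tibble::tibble(
                     statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  structure(list(per_ecosystem = per_eco, kruskal = kw, bartlett = bart,
                 letters = letters_tbl, data = nep, alpha = alpha),
            class = "crossflux_nep_analysis")
}

#' @export
print.crossflux_nep_analysis <- function(x, ...) {
  cat("NEP analysis across", nrow(x$per_ecosystem), "ecosystem types\n")
  print(x$kruskal)
  cat("Bartlett p =", format.pval(x$bartlett$p_value), "\n")
  print(dplyr::select(x$per_ecosystem, "ecosystem", "n", "mean", "ci_low",
                      "ci_high", "p_plus", "letters"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.crossflux_nep_analysis <- function(x, ...) x$per_ecosystem

#' @exportS3Method generics::glance
glance.crossflux_nep_analysis <- function(x, ...) {
  dplyr::bind_cols(glance(x$kruskal),
                   tibble::tibble(bartlett_stat = x$bartlett$statistic,
                                  bartlett_p = x$bartlett$p_value,
                                  alpha = x$alpha))
}
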