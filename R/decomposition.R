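# Exponential litter-decay model: one detritus pool decaying at first-order
# rate k. Three entry points match how decomposition is reported in the
# literature: a stock + rate (flux over a horizon), a litter-bag mass pair
# (rate from proportional mass loss), and a production/export budget (rate
# from the absolute flux).

#' Decomposition flux from a detritus stock and decay rate
#'
#' Carbon transferred from a detritus stock to decomposers over a horizon
#' `t`, under first-order decay: `D_F = D_M * (1 - exp(-k * t))`. Bounded in
#' `[0, D_M)` and saturating at the stock as `k * t` grows.
#'
#' @param d_m Detritus stock, gC per m2 (>= 0).
#' @param k First-order decay rate, per year (>= 0).
#' @param t Horizon in years (> 0); the annual canonical unit uses `t = 1`.
#' @return Decomposition flux in gC per m2 over `t`.
#' @examples
#' decomposition_flux(100, log(2), 1)  # half the stock in one half-life
#' @export
decomposition_flux <- function(d_m, k, t = 1) {
  if (any(!is.finite(k) | k < 0)) {
    abort("decay rate k must be >= 0", class = "crossflux_domain_error")
  }
  if (any(!is.finite(d_m) | d_m < 0)) {
    abort("detritus stock must be >= 0", class = "crossflux_domain_error")
  }
  check_positive(t, "t")
  # expm1 keeps the small-kt limit D_M * k * t accurate
  d_m * (-expm1(-k * t))
}

#' Decay rate from litter-bag mass loss
#'
#' Inverts the decay curve `D_t = D_t0 * exp(-k * t)` for `k`, the standard
#' reduction of a litter-bag experiment reporting the proportion of detrital
#' mass remaining after time `t`. The mass basis cancels, so no carbon
#' conversion is needed.
#'
#' @param d_t0 Initial detrital mass (> 0, any mass basis).
#' @param d_t Mass remaining at time `t` (0 < `d_t` <= `d_t0`, same basis).
#' @param t Elapsed time in years (> 0).
#' @return Decay rate `k` in per year.
#' @examples
#' k_from_massloss(100, 50, 1)  # log(2)
#' @export
k_from_massloss <- function(d_t0, d_t, t) {
  check_positive(d_t0, "initial mass")
  check_positive(t, "t")
  if (any(is.finite(d_t) & d_t == 0)) {
    abort("complete mass loss implies an infinite decay rate",
          class = "crossflux_infinite_rate_error")
  }
  if (any(!is.finite(d_t) | d_t < 0 | d_t > d_t0)) {
    abort("remaining mass must lie in (0, initial mass] (mass gain not allowed)",
          class = "crossflux_domain_error")
  }
  -log(d_t / d_t0) / t
}

#' Decay rate from a detritus production budget
#'
#' Inverts `D_F = (D_P - E) * (1 - exp(-k * t))` for `k`, used when a study
#' reports the absolute decomposition flux together with detritus production
#' `D_P` and (optionally) export `E`. When export is unknown it defaults to
#' 0, which underestimates `k` (a conservative choice).
#'
#' @param d_p Detritus production, gC per m2 per year (> 0).
#' @param e Detritus export (e.g. sedimentation), gC per m2 per year
#'   (0 <= `e` < `d_p`); default 0.
#' @param d_f Decomposition flux over `t` (0 <= `d_f` < `d_p - e`).
#' @param t Horizon in years (> 0).
#' @return Decay rate `k` in per year.
#' @examples
#' k_from_production(100, 0, 50, 1)   # log(2)
#' k_from_production(100, 20, 40, 1)  # same: 40 / (100 - 20) = 0.5
#' @export
k_from_production <- function(d_p, e = 0, d_f, t = 1) {
  check_positive(t, "t")
  avail <- d_p - e
  if (any(!is.finite(avail) | avail <= 0)) {
    abort("export must be smaller than production",
          class = "crossflux_domain_error")
  }
  if (any(!is.finite(d_f) | d_f < 0 | d_f >= avail)) {
    abort("decomposition flux must lie in [0, production - export)",
          class = "crossflux_domain_error")
  }
  -log1p(-d_f / avail) / t
}

#' Derive per-stratum decomposition fluxes from stocks and rates
#'
#' For each ecosystem x climate stratum, parameterises the detritus stock
#' `D_M` with the median of all harmonized detritus-stock records in that
#' stratum, then turns every collected decay-rate record `k` into one derived
#' decomposition-flux record via `D_M * (1 - exp(-k))` (a one-year horizon,
#' matching the annual canonical unit). Strata holding rates but no stocks
#' are skipped with a warning.
#'
#' @param records A harmonized `flux_table` containing `detritus_stock`
#'   and/or `decomposition_rate` records (other classes are ignored).
#' @param t Horizon in years (default 1).
#' @return A tibble of derived records with `flux_class =
#'   "decomposition_flux"`, canonical units, and provenance columns
#'   `source_rate_id` (the rate record), `stock_median` (the stratum `D_M`)
#'   and `n_stocks`.
#' @examples
#' tbl <- simulate_fluxes(strata = tibble::tibble(
#'   ecosystem = "forest", climate = "temperate",
#'   flux_class = c("detritus_stock", "decomposition_rate"),
#'   material_origin = "none", driver = "none", donor_ecosystem = "none",
#'   median = c(100, log(2)), sdlog = 1e-9, n = c(3, 1)
#' ), seed = 1)
#' h <- harmonize(tbl$records)
#' stratum_decomposition_fluxes(h)
#' @export
stratum_decomposition_fluxes <- function(records, t = 1) {
  stocks <- dplyr::filter(records, .data$flux_class == "detritus_stock")
  rates <- dplyr::filter(records, .data$flux_class == "decomposition_rate")
  if (nrow(rates) == 0) {
    return(tibble::tibble())
  }
  stock_medians <- stocks |>
    dplyr::group_by(.data$ecosystem, .data$climate) |>
    dplyr::summarise(stock_median = stats::median(.data$value),
                     n_stocks = dplyr::n(), .groups = "drop")
  orphan <- dplyr::anti_join(
    dplyr::distinct(rates, .data$ecosystem, .data$climate),
    stock_medians, by = c("ecosystem", "climate"))
  if (nrow(orphan) > 0) {
    warn(paste0("skipping stratum without detritus stocks: ",
                paste(orphan$ecosystem, orphan$climate, sep = "/",
                      collapse = ", ")))
  }
  derived <- rates |>
    dplyr::inner_join(stock_medians, by = c("ecosystem", "climate")) |>
    dplyr::mutate(
      source_rate_id = .data$record_id,
      record_id = paste0(.data$record_id, "_dflux"),
      flux_class = "decomposition_flux",
      value = decomposition_flux(.data$stock_median, .data$value, t),
      mass_basis = "carbon",
      time_basis = "per_year"
    )
  if ("audit" %in% names(derived)) {
    derived$audit <- purrr::map2(
      derived$audit, derived$stock_median,
      function(a, dm) dplyr::bind_rows(a, tibble::tibble(
        step = "decay_model_flux", factor = NA_real_,
        rule = sprintf("eq_exp_decay(D_M=%.6g, t=%g)", dm, t))))
  }
  tibble::as_tibble(derived)
}
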