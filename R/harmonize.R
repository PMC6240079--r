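# Unit harmonization: every raw measurement is converted to canonical areal
# carbon units -- gC m-2 yr-1 of the recipient ecosystem (gC m-2 for detritus
# stocks, yr-1 for decay rates). Steps apply in a fixed order (carbon ->
# volume-to-area -> shoreline re-expression -> annualization), each step is
# a multiplication, and each multiplier is logged in a per-record audit
# trail so every harmonized value is traceable to its raw source.

#' Convert a mass measurement to carbon units
#'
#' Multiplies a value by a carbon fraction (gC per g of the reported mass
#' basis). A carbon fraction reported by the source study always takes
#' precedence; otherwise the most specific entry of the conversion table is
#' used (`material_class`, basis), falling back to the `generic` class.
#' Carbon-basis input is returned unchanged.
#'
#' @param value Magnitude in the raw mass basis (vectorised).
#' @param mass_basis One of `carbon`, `dry_weight`, `ash_free_dry_weight`,
#'   `wet_weight` (recycled).
#' @param material_class Material class keying the conversion table
#'   (`terrestrial_plant`, `macroalga`, `invertebrate`, `vertebrate`,
#'   `mixed_detritus`, `poc_doc`, `generic`).
#' @param fractions Conversion table, see [default_carbon_fractions()].
#' @param reported_fraction Study-reported carbon content in (0, 1], or `NA`
#'   to use the table.
#' @return Value in gC.
#' @examples
#' convert_to_carbon(100, "dry_weight")                        # 50
#' convert_to_carbon(100, "ash_free_dry_weight",
#'                   reported_fraction = 0.42)                 # 42
#' @export
convert_to_carbon <- function(value, mass_basis, material_class = "generic",
                              fractions = default_carbon_fractions(),
                              reported_fraction = NA_real_) {
  n <- length(value)
  mass_basis <- rep_len(mass_basis, n)
  material_class <- rep_len(material_class, n)
  reported_fraction <- rep_len(reported_fraction, n)
  if (any(is.finite(reported_fraction) &
          (reported_fraction <= 0 | reported_fraction > 1))) {
    abort("reported carbon fraction must lie in (0, 1]",
          class = "crossflux_domain_error")
  }
  value * carbon_factor(mass_basis, material_class, fractions,
                        reported_fraction)$factor
}

# Resolves the multiplier and the rule that produced it.
carbon_factor <- function(mass_basis, material_class, fractions,
                          reported_fraction) {
  n <- length(mass_basis)
  factor <- rep(NA_real_, n)
  rule <- rep(NA_character_, n)

  use_reported <- is.finite(reported_fraction) & mass_basis != "carbon"
  factor[use_reported] <- reported_fraction[use_reported]
  rule[use_reported] <- "reported_fraction"
  factor[mass_basis == "carbon"] <- 1
  rule[mass_basis == "carbon"] <- "already_carbon"

  left <- which(is.na(factor))
  if (length(left) > 0) {
    key <- paste(material_class[left], mass_basis[left], sep = "|")
    lut <- setNames(fractions$fraction,
                    paste(fractions$material_class, fractions$mass_basis,
                          sep = "|"))
    hit <- lut[key]
    factor[left] <- unname(hit)
    rule[left] <- paste0("table:", key)
    miss <- left[is.na(hit)]
    if (length(miss) > 0) {
      gkey <- paste("generic", mass_basis[miss], sep = "|")
      ghit <- lut[gkey]
      factor[miss] <- unname(ghit)
      rule[miss] <- paste0("table:", gkey)
      if (any(is.na(ghit))) {
        abort(paste0("no carbon conversion factor for ",
                     paste(unique(key[is.na(hit)][is.na(ghit)]),
                           collapse = ", ")),
              class = "crossflux_conversion_error")
      }
    }
  }
  list(factor = factor, rule = rule)
}

#' Extrapolate a flux to an annual basis
#'
#' Per-day fluxes are multiplied by the growing-season length (GSL, in days)
#' of the record's climate zone, i.e. activity is assumed confined to the
#' growing season (or ice-free period). Fluxes integrated over a study
#' period shorter than the GSL are rescaled by `GSL / days`; no conversion
#' is applied when the study period already covers the growing season. Study
#' periods longer than a year are divided down to an annual rate
#' (`365 / days`), conserving the measured total. Annual input is returned
#' unchanged. Works for any sign (net fluxes may be negative).
#'
#' @param value Magnitude per time basis (vectorised).
#' @param time_basis One of `per_year`, `per_day`, `per_study_period`.
#' @param climate Climate zone token (recycled).
#' @param gsl Named vector of growing-season lengths in days, see
#'   [crossflux_config()].
#' @param study_period_days Study period length in days, required for
#'   `per_study_period`.
#' @return Value per year.
#' @examples
#' annualize(1, "per_day", "temperate")   # 181
#' annualize(1, "per_day", "tropical")    # 365
#' annualize(200, "per_study_period", "temperate",
#'           study_period_days = 365)     # 200, unchanged
#' @export
annualize <- function(value, time_basis, climate,
                      gsl = crossflux_config()$gsl_days,
                      study_period_days = NA_real_) {
  annualize_factor(time_basis, climate, gsl, study_period_days)$factor * value
}

annualize_factor <- function(time_basis, climate, gsl, study_period_days) {
  n <- length(time_basis)
  climate <- rep_len(climate, n)
  study_period_days <- rep_len(study_period_days, n)
  g <- unname(gsl[climate])
  factor <- rep(1, n)
  rule <- rep("already_annual", n)

  day <- time_basis == "per_day"
  factor[day] <- g[day]
  rule[day] <- paste0("gsl_", climate[day])

  sp <- time_basis == "per_study_period"
  if (any(sp & !(is.finite(study_period_days) & study_period_days > 0))) {
    abort("per_study_period requires positive study_period_days",
          class = "crossflux_contract_error")
  }
  short <- sp & study_period_days < g
  factor[short] <- g[short] / study_period_days[short]
  rule[short] <- paste0("gsl_", climate[short], "_over_period")
  covered <- sp & study_period_days >= g & study_period_days <= 365
  rule[covered] <- "period_covers_gsl"
  long <- sp & study_period_days > 365
  factor[long] <- 365 / study_period_days[long]
  rule[long] <- "multi_year_period"

  bad <- time_basis == "none"
  if (any(bad)) {
    abort("cannot annualize a record without a time basis",
          class = "crossflux_contract_error")
  }
  list(factor = factor, rule = rule)
}

#' Mean lake depth from volume and area
#'
#' @param volume Lake volume in m3 (> 0).
#' @param area Lake area in m2 (> 0).
#' @return Mean depth in m (`volume / area`).
#' @examples
#' lake_mean_depth(1e6, 1e5)  # 10
#' @export
lake_mean_depth <- function(volume, area) {
  check_positive(volume, "volume")
  check_positive(area, "area")
  volume / area
}

#' Mean river depth from discharge
#'
#' Hydraulic-geometry power law `depth = c * Q^f` with the standard
#' downstream exponents `c = 0.2`, `f = 0.4` (`Q` in m3 s-1). Streams
#' draining catchments smaller than 1 km2 are assigned a depth of 5 cm, per
#' known river scaling properties.
#'
#' @param q Discharge in m3 s-1 (> 0), or `NA` when only the catchment area
#'   is known.
#' @param catchment_area_km2 Catchment area in km2, used for the small-
#'   catchment rule.
#' @param c,f Power-law constants.
#' @param small_catchment_km2,small_catchment_depth_m Small-catchment
#'   threshold and the depth assigned below it.
#' @return Depth in m.
#' @examples
#' depth_from_discharge(32)   # 0.2 * 32^0.4 = 0.8
#' depth_from_discharge(NA, catchment_area_km2 = 0.5)  # 0.05
#' @export
depth_from_discharge <- function(q = NA_real_, catchment_area_km2 = NA_real_,
                                 c = 0.2, f = 0.4,
                                 small_catchment_km2 = 1,
                                 small_catchment_depth_m = 0.05) {
  n <- max(length(q), length(catchment_area_km2))
  q <- rep_len(q, n)
  catchment_area_km2 <- rep_len(catchment_area_km2, n)
  small <- is.finite(catchment_area_km2) &
    catchment_area_km2 < small_catchment_km2
  usable_q <- is.finite(q) & q > 0
  if (any(!small & !usable_q)) {
    abort("need a positive discharge or a catchment area to estimate depth",
          class = "crossflux_contract_error")
  }
  out <- rep(small_catchment_depth_m, n)
  out[!small] <- c * q[!small]^f
  out
}

#' Integrate a volumetric measurement over the water column
#'
#' @param value Magnitude per m3 (vectorised).
#' @param depth Integration depth in m (> 0): the mean depth in freshwater,
#'   the euphotic depth (e.g. Secchi) in pelagic systems, or 100 m when a
#'   pelagic study reports only sampling depths.
#' @return Magnitude per m2.
#' @examples
#' integrate_over_depth(2, 0.5)  # 1
#' @export
integrate_over_depth <- function(value, depth) {
  if (any(!is.finite(depth) | depth <= 0)) {
    abort("integration depth must be positive",
          class = "crossflux_contract_error")
  }
  value * depth
}

# Material class used for the carbon table: spatial flows keyed by their
# material origin (primary producers split terrestrial vs. marine by donor),
# detritus stocks by mixed_detritus, everything else generic.
material_class_of <- function(ecosystem, flux_class, material_origin,
                              donor_ecosystem) {
  marine_donor <- donor_ecosystem %in% c("ocean_pelagic", "ocean_benthic")
  dplyr::case_when(
    material_origin == "primary_producer" & marine_donor ~ "macroalga",
    material_origin == "primary_producer" ~ "terrestrial_plant",
    material_origin %in% c("invertebrate", "vertebrate", "poc_doc") ~
      material_origin,
    flux_class == "detritus_stock" ~ "mixed_detritus",
    TRUE ~ "generic"
  )
}

#' Harmonize a flux table to canonical carbon areal annual units
#'
#' Applies, in order: carbon conversion, volume-to-area depth integration,
#' shoreline re-expression of lateral aquatic-to-terrestrial flows, and
#' annualization. Decomposition-rate records keep their measured mass basis
#' (carbon loss rate is taken as identical to mass loss rate) and are only
#' annualized; detritus stocks are converted to carbon but carry no time
#' basis. Every multiplicative step is recorded in the `audit` list-column
#' (`step`, `factor`, `rule`), and an already-canonical record passes
#' through unchanged with an empty audit, so harmonization is idempotent.
#'
#' @param records A `flux_table` (see [as_flux_table()]).
#' @param config A [crossflux_config()]; `band_width_m` controls the
#'   shoreline band.
#' @return The harmonized `flux_table` with canonical units and an `audit`
#'   list-column; extract the long-format trail with [audit_trail()].
#' @examples
#' raw <- as_flux_table(tibble::tibble(
#'   record_id = "r1", study_id = "s1", ecosystem = "lake",
#'   climate = "boreal", flux_class = "gpp", material_origin = "none",
#'   driver = "none", donor_ecosystem = "none", value = 0.5,
#'   mass_basis = "dry_weight", spatial_basis = "per_m3",
#'   time_basis = "per_day", depth_m = 2
#' ))
#' harmonize(raw)$value  # 0.5 * 0.5 * 2 * 155 = 77.5
#' @export
harmonize <- function(records, config = crossflux_config()) {
  stopifnot(inherits(records, "data.frame"))
  x <- tibble::as_tibble(records)
  n <- nrow(x)
  audits <- vector("list", n)
  rows <- vector("list", n)
  plain_cols <- setdiff(names(x), "audit")
  plain <- x[, plain_cols]
  for (i in seq_len(n)) {
    res <- withCallingHandlers(
      harmonize_one(plain[i, ], config),
      error = function(e) {
        abort(paste0("record ", x$record_id[i], ": ", conditionMessage(e)),
              class = "crossflux_harmonize_error", parent = e)
      }
    )
    rows[[i]] <- res$row
    audits[[i]] <- res$audit
  }
  out <- if (n > 0) dplyr::bind_rows(rows) else plain
  out$audit <- audits
  class(out) <- c("flux_table", setdiff(class(out), "flux_table"))
  out
}

# One record through the full path; returns the updated row and its audit.
harmonize_one <- function(row, config) {
  steps <- list()
  push <- function(step, factor, rule) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      step = step, factor = factor, rule = rule)
  }

  # 1. carbon conversion (skipped for decay rates)
  if (row$mass_basis != "carbon") {
    if (row$flux_class == "decomposition_rate") {
      row$mass_basis <- row$mass_basis  # rate kept in its measured basis
    } else {
      cls <- material_class_of(row$ecosystem, row$flux_class,
                               row$material_origin, row$donor_ecosystem)
      fr <- if (is.finite(row$carbon_fraction)) row$carbon_fraction else NA_real_
      cf <- carbon_factor(row$mass_basis, cls, config$carbon_fractions, fr)
      row$value <- row$value * cf$factor
      row$mass_basis <- "carbon"
      push("carbon_conversion", cf$factor, cf$rule)
    }
  }

  # 2. volume to area
  if (row$spatial_basis == "per_m3") {
    d <- resolve_depth(row, config)
    row$value <- row$value * d$depth
    row$spatial_basis <- if (row$flux_class == "spatial_flow")
      "per_m2_donor" else "per_m2_recipient"
    push("depth_integration", d$depth, d$rule)
  }

  # 3. shoreline re-expression (spatial flows not yet in recipient units)
  if (row$spatial_basis != "per_m2_recipient") {
    if (row$flux_class != "spatial_flow") {
      abort(paste0("local flux with donor-referenced spatial basis ",
                   row$spatial_basis))
    }
    row <- reexpress_spatial(row, config, push)
  }

  # 4. annualization (stocks carry no time basis)
  if (row$flux_class != "detritus_stock" && row$time_basis != "per_year") {
    af <- annualize_factor(row$time_basis, row$climate, config$gsl_days,
                           row$study_period_days)
    row$value <- row$value * af$factor
    row$time_basis <- "per_year"
    push("annualization", af$factor, af$rule)
  }

  audit <- if (length(steps) == 0) {
    tibble::tibble(step = character(), factor = numeric(), rule = character())
  } else {
    dplyr::bind_rows(steps)
  }
  list(row = row, audit = audit)
}

resolve_depth <- function(row, config) {
  eco <- if (row$flux_class == "spatial_flow" &&
             row$donor_ecosystem %in% aquatic_ecosystems())
    row$donor_ecosystem else row$ecosystem
  if (is.finite(row$depth_m)) {
    return(list(depth = row$depth_m, rule = "measured_mean_depth"))
  }
  if (eco == "lake") {
    if (is.finite(row$lake_volume_m3) && is.finite(row$lake_area_m2)) {
      return(list(depth = lake_mean_depth(row$lake_volume_m3,
                                          row$lake_area_m2),
                  rule = "volume_over_area"))
    }
    abort("lake volumetric record needs depth_m or volume + area")
  }
  if (eco == "stream") {
    small <- is.finite(row$catchment_area_km2) &&
      row$catchment_area_km2 < config$small_catchment_km2
    if (!small && !(is.finite(row$discharge_m3s) && row$discharge_m3s > 0)) {
      abort("stream volumetric record needs depth_m, discharge or catchment area")
    }
    d <- depth_from_discharge(
      row$discharge_m3s, row$catchment_area_km2,
      c = config$depth_c, f = config$depth_f,
      small_catchment_km2 = config$small_catchment_km2,
      small_catchment_depth_m = config$small_catchment_depth_m)
    return(list(depth = d,
                rule = if (small) "small_catchment_5cm"
                       else "discharge_power_law"))
  }
  if (eco %in% c("ocean_pelagic", "ocean_benthic")) {
    if (is.finite(row$photic_depth_m)) {
      return(list(depth = row$photic_depth_m, rule = "euphotic_depth"))
    }
    return(list(depth = config$pelagic_default_depth_m,
                rule = "default_pelagic_depth"))
  }
  abort("volumetric record in a non-aquatic ecosystem needs depth_m")
}

# Lateral aquatic -> terrestrial flows route through the shoreline band;
# vertical flows between stacked water-column ecosystems keep their area.
reexpress_spatial <- function(row, config, push) {
  lateral <- row$donor_ecosystem %in% aquatic_ecosystems() &&
    row$ecosystem %in% terrestrial_ecosystems()

  if (row$spatial_basis == "per_lake") {
    if (!is.finite(row$lake_area_m2)) {
      abort("per_lake flow needs lake_area_m2")
    }
    row$value <- row$value / row$lake_area_m2
    row$spatial_basis <- "per_m2_donor"
    push("whole_lake_to_donor_area", 1 / row$lake_area_m2, "per_lake_over_area")
  }
  if (row$spatial_basis == "per_stream_reach") {
    if (!is.finite(row$stream_width_m) || !is.finite(row$reach_length_m)) {
      abort("per_stream_reach flow needs stream_width_m and reach_length_m")
    }
    a <- row$stream_width_m * row$reach_length_m
    row$value <- row$value / a
    row$spatial_basis <- "per_m2_donor"
    push("reach_to_donor_area", 1 / a, "width_times_length")
  }

  if (row$spatial_basis == "per_m2_donor") {
    if (!lateral) {
      # vertical (e.g. pelagic -> benthic) or canopy-over-channel flows:
      # donor and recipient areas coincide
      row$spatial_basis <- "per_m2_recipient"
      push("donor_area_equivalence", 1, "donor_recipient_area_equivalent")
      return(row)
    }
    if (row$donor_ecosystem == "stream") {
      if (!is.finite(row$stream_width_m)) {
        abort("stream donor-area flow needs stream_width_m")
      }
      row$value <- flow_per_shoreline_stream(row$value, row$stream_width_m)
      push("stream_to_shoreline", row$stream_width_m / 2, "width_over_two")
    } else {
      if (!is.finite(row$lake_area_m2)) {
        abort("lake donor-area flow needs lake_area_m2")
      }
      if (is.finite(row$lake_perimeter_m)) {
        per <- row$lake_perimeter_m
        rule <- "measured_perimeter"
      } else {
        dl <- if (is.finite(row$shoreline_development))
          row$shoreline_development else config$default_shoreline_development
        per <- lake_perimeter(row$lake_area_m2, dl)
        rule <- if (is.finite(row$shoreline_development))
          "development_factor_perimeter" else "assumed_circular_perimeter"
      }
      row$value <- flow_per_shoreline_lake(row$value, row$lake_area_m2, per)
      push("lake_to_shoreline", row$lake_area_m2 / per, rule)
    }
    row$spatial_basis <- "per_m_shoreline"
  }

  if (row$spatial_basis == "per_m_shoreline") {
    row$value <- distribute_on_band(row$value, config$band_width_m)
    row$spatial_basis <- "per_m2_recipient"
    push("band_distribution", 1 / config$band_width_m,
         paste0("uniform_band_", config$band_width_m, "m"))
  }
  row
}

#' Extract the harmonization audit trail in long format
#'
#' @param records A harmonized `flux_table` carrying the `audit`
#'   list-column.
#' @return A tibble with one row per conversion step: `record_id`,
#'   `step_index`, `step`, `factor`, `rule`.
#' @export
audit_trail <- function(records) {
  if (!"audit" %in% names(records)) {
    abort("records carry no audit column; run harmonize() first",
          class = "crossflux_contract_error")
  }
  tibble::tibble(record_id = records$record_id, audit = records$audit) |>
    dplyr::mutate(audit = purrr::map(.data$audit, ~ dplyr::mutate(
      .x, step_index = dplyr::row_number()))) |>
    tidyr::unnest("audit") |>
    dplyr::select("record_id", "step_index", "step", "factor", "rule")
}
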