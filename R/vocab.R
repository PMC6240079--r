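# Controlled vocabularies for the flux-record schema. Closed enums: free-text
# ecosystem names (e.g. "prairie", "meadow") must be mapped by the user before
# import; pooling of synonyms is a search-time, not analysis-time, concern.

#' Controlled vocabularies of the flux-record schema
#'
#' Closed sets of tokens accepted in the categorical columns of a flux table.
#' Matching at import is case-insensitive, but tables are always written in
#' the canonical lower-case form returned here.
#'
#' @return A named list of character vectors: `ecosystem` (4 terrestrial + 4
#'   aquatic types), `climate` (5 zones), `flux_class`, `material_origin`,
#'   `driver` (4 passive + 3 active + `none`), `mass_basis`, `spatial_basis`,
#'   `time_basis`.
#' @examples
#' flux_vocab()$ecosystem
#' @export
flux_vocab <- function() {
  list(
    ecosystem = c("forest", "grassland", "agro_ecosystem", "desert",
                  "stream", "lake", "ocean_pelagic", "ocean_benthic"),
    climate = c("arctic_alpine", "boreal", "temperate", "tropical", "arid"),
    flux_class = c("gpp", "ecosystem_respiration", "nep", "npp",
                   "secondary_production", "detritus_stock",
                   "decomposition_rate", "decomposition_flux", "spatial_flow"),
    material_origin = c("primary_producer", "invertebrate", "vertebrate",
                        "poc_doc", "none"),
    driver = c("fall_wind", "leaching", "current_tides", "sinking",
               "foraging", "migration", "life_cycle", "none"),
    mass_basis = c("carbon", "dry_weight", "ash_free_dry_weight", "wet_weight"),
    spatial_basis = c("per_m2_recipient", "per_m2_donor", "per_m3",
                      "per_m_shoreline", "per_lake", "per_stream_reach"),
    time_basis = c("per_year", "per_day", "per_study_period", "none")
  )
}

#' @rdname flux_vocab
#' @details `terrestrial_ecosystems()`, `aquatic_ecosystems()`,
#'   `passive_drivers()` and `active_drivers()` are convenience subsets used
#'   throughout the pipeline (band routing fires only for aquatic donor to
#'   terrestrial recipient; driver tabulations split passive physical
#'   transport from active animal movement).
#' @export
terrestrial_ecosystems <- function() {
  c("forest", "grassland", "agro_ecosystem", "desert")
}

#' @rdname flux_vocab
#' @export
aquatic_ecosystems <- function() {
  c("stream", "lake", "ocean_pelagic", "ocean_benthic")
}

#' @rdname flux_vocab
#' @export
passive_drivers <- function() {
  c("fall_wind", "leaching", "current_tides", "sinking")
}

#' @rdname flux_vocab
#' @export
active_drivers <- function() {
  c("foraging", "migration", "life_cycle")
}

#' Climate groups used for marine summaries
#'
#' Marine records keep their source climate; for reporting, ocean climates are
#' pooled into Cold (arctic/alpine, boreal, temperate) and Warm (arid,
#' tropical) because large water volumes buffer climatic influence.
#'
#' @param climate Character vector of climate tokens.
#' @return Character vector of the same length with values `"Cold"` or
#'   `"Warm"`.
#' @examples
#' marine_climate_group(c("boreal", "tropical"))
#' @export
marine_climate_group <- function(climate) {
  stopifnot(all(climate %in% flux_vocab()$climate))
  ifelse(climate %in% c("arctic_alpine", "boreal", "temperate"), "Cold", "Warm")
}

# Geometry columns recognised on a flux table. All in SI units noted in the
# column dictionary; absent geometry is NA.
geometry_columns <- function() {
  c("lake_area_m2", "lake_volume_m3", "lake_perimeter_m",
    "shoreline_development", "stream_width_m", "reach_length_m",
    "discharge_m3s", "catchment_area_km2", "depth_m", "photic_depth_m")
}

# Full column set of a raw flux table, in canonical order.
flux_table_columns <- function() {
  c("record_id", "study_id", "ecosystem", "climate", "flux_class",
    "material_origin", "driver", "donor_ecosystem", "value",
    "mass_basis", "spatial_basis", "time_basis", "study_period_days",
    "carbon_fraction", geometry_columns())
}
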