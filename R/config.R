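#' Pipeline configuration
#'
#' Builds the configuration object consumed by [harmonize()],
#' [sensitivity_band()] and [run_pipeline()]. Every element has a default;
#' `crossflux_config()` with no arguments gives the standard analysis
#' configuration, and [read_config()] overlays values from a YAML file on top
#' of these defaults.
#'
#' Defaults:
#' * `band_width_m = 10` — lateral aquatic-to-terrestrial flows are spread
#'   uniformly over the first 10 m of shore; 100 m is the conservative
#'   sensitivity setting.
#' * `gsl_days` — growing-season lengths used to annualize per-day fluxes:
#'   temperate 181, boreal 155, arctic/alpine 116, arid 163, tropical 365.
#' * `carbon_fractions` — gC per g of reported mass basis, by material class;
#'   a study-reported carbon content always takes precedence. The shipped
#'   fractions (dry weight 0.5, ash-free dry weight 0.5, wet weight 0.1) are
#'   parsimonious field defaults and can be overridden per material class.
#' * `depth_c = 0.2`, `depth_f = 0.4` — hydraulic-geometry constants of the
#'   depth–discharge power law for rivers, depth = c * Q^f.
#' * `small_catchment_km2 = 1`, `small_catchment_depth_m = 0.05` — streams
#'   draining < 1 km2 are assigned a 5 cm depth.
#' * `pelagic_default_depth_m = 100` — depth used to integrate pelagic
#'   volumetric data when only sampling depths are reported.
#' * `default_shoreline_development = 1` — development factor assumed when a
#'   lake's shoreline complexity is unknown (1 = circular), flagged in the
#'   audit trail.
#' * `alpha = 0.05` — family alpha for the NEP tests and post-hoc letters.
#' * `seed = 1L` — seed echoed into logs and manifests.
#'
#' @param ... Named overrides of any default element. `carbon_fractions` and
#'   `gsl_days` may be partial; missing entries keep their defaults.
#' @return A list of class `crossflux_config`.
#' @examples
#' cfg <- crossflux_config(band_width_m = 100)
#' cfg$band_width_m
#' @export
crossflux_config <- function(...) {
  defaults <- list(
    band_width_m = 10,
    gsl_days = c(arctic_alpine = 116, boreal = 155, temperate = 181,
                 tropical = 365, arid = 163),
    carbon_fractions = default_carbon_fractions(),
    depth_c = 0.2,
    depth_f = 0.4,
    small_catchment_km2 = 1,
    small_catchment_depth_m = 0.05,
    pelagic_default_depth_m = 100,
    default_shoreline_development = 1,
    alpha = 0.05,
    strict = TRUE,
    seed = 1L
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides)
  validate_config(cfg)
  structure(cfg, class = "crossflux_config")
}

# Recursive overlay: named vectors/lists merge entry-wise, scalars replace.
merge_config <- function(base, overrides) {
  if (length(overrides) == 0) return(base)
  bad <- setdiff(names(overrides), c(names(base), ""))
  if (length(bad) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")),
          class = "crossflux_config_error")
  }
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    if (nm %in% c("gsl_days", "carbon_fractions") && !is.null(names(ov))) {
      merged <- base[[nm]]
      if (is.data.frame(merged)) {
        # carbon_fractions given as named list of (material_class = fraction)
        for (mc in names(ov)) {
          hit <- merged$material_class == mc
          if (!any(hit)) {
            abort(paste0("unknown material class in carbon_fractions: ", mc),
                  class = "crossflux_config_error")
          }
          merged$fraction[hit] <- as.numeric(ov[[mc]])
        }
      } else {
        ov <- unlist(ov)
        bad <- setdiff(names(ov), names(merged))
        if (length(bad) > 0) {
          abort(paste0("unknown climate in gsl_days: ",
                       paste(bad, collapse = ", ")),
                class = "crossflux_config_error")
        }
        merged[names(ov)] <- ov
      }
      base[[nm]] <- merged
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

#' @rdname crossflux_config
#' @details `default_carbon_fractions()` returns the shipped carbon-content
#'   table as a tibble with columns `material_class` (`terrestrial_plant`,
#'   `macroalga`, `invertebrate`, `vertebrate`, `mixed_detritus`, `poc_doc`,
#'   `generic`), `mass_basis` and `fraction` (gC per g of that basis). The
#'   fraction for `carbon` basis is identically 1.
#' @export
default_carbon_fractions <- function() {
  classes <- c("terrestrial_plant", "macroalga", "invertebrate", "vertebrate",
               "mixed_detritus", "poc_doc", "generic")
  # gC per g: organic dry matter is close to half carbon; wet tissue is
  # dominated by water.
  per_basis <- c(carbon = 1, dry_weight = 0.5, ash_free_dry_weight = 0.5,
                 wet_weight = 0.1)
  tidyr::expand_grid(material_class = classes,
                     mass_basis = names(per_basis)) |>
    dplyr::mutate(fraction = unname(per_basis[.data$mass_basis]))
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$band_width_m), length(cfg$band_width_m) == 1)
  if (!is.finite(cfg$band_width_m) || cfg$band_width_m <= 0) {
    abort("band_width_m must be a positive number",
          class = "crossflux_config_error")
  }
  if (any(!is.finite(cfg$gsl_days)) || any(cfg$gsl_days < 1) ||
      any(cfg$gsl_days > 365)) {
    abort("gsl_days must lie in [1, 365]", class = "crossflux_config_error")
  }
  if (!setequal(names(cfg$gsl_days), flux_vocab()$climate)) {
    abort("gsl_days must cover all five climate zones",
          class = "crossflux_config_error")
  }
  cf <- cfg$carbon_fractions
  if (any(cf$fraction <= 0 | cf$fraction > 1)) {
    abort("carbon fractions must lie in (0, 1]",
          class = "crossflux_config_error")
  }
  if (any(cf$fraction[cf$mass_basis == "carbon"] != 1)) {
    abort("carbon fraction for carbon basis must be exactly 1",
          class = "crossflux_config_error")
  }
  for (key in c("depth_c", "depth_f", "small_catchment_depth_m",
                "pelagic_default_depth_m")) {
    if (!is.finite(cfg[[key]]) || cfg[[key]] <= 0) {
      abort(paste0(key, " must be positive"), class = "crossflux_config_error")
    }
  }
  if (cfg$default_shoreline_development < 1) {
    abort("default_shoreline_development must be >= 1 (1 = circular)",
          class = "crossflux_config_error")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort("alpha must lie in (0, 1)", class = "crossflux_config_error")
  }
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a YAML configuration file and overlays it on the package defaults
#' (see [crossflux_config()]); keys absent from the file keep their defaults.
#' The fully resolved configuration is echoed to the message stream so every
#' run records the settings it actually used.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param quiet Suppress the configuration echo.
#' @return A `crossflux_config` list.
#' @export
read_config <- function(path = NULL, quiet = FALSE) {
  overrides <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path),
            class = "crossflux_config_error")
    }
    overrides <- yaml::read_yaml(path)
    if (is.null(overrides)) overrides <- list()
  }
  cfg <- do.call(crossflux_config, overrides)
  if (!quiet) {
    flat <- utils::capture.output(utils::str(unclass(cfg), give.attr = FALSE))
    inform(c("resolved configuration:", flat))
  }
  cfg
}

#' @export
print.crossflux_config <- function(x, ...) {
  cat("<crossflux_config>\n")
  cat("  band width:", x$band_width_m, "m | alpha:", x$alpha,
      "| seed:", x$seed, "\n")
  cat("  GSL (days):",
      paste(names(x$gsl_days), x$gsl_days, sep = "=", collapse = ", "), "\n")
  cat("  depth = ", x$depth_c, " * Q^", x$depth_f,
      "; small catchment < ", x$small_catchment_km2, " km2 -> ",
      x$small_catchment_depth_m, " m; pelagic default depth ",
      x$pelagic_default_depth_m, " m\n", sep = "")
  invisible(x)
}
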