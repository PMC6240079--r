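# Flux-record tables: one row per literature measurement. The column
# dictionary (inst/extdata/column_dictionary.csv) is this package's own
# layout; categorical columns use the closed vocabularies in flux_vocab().

#' Coerce a data frame to a validated flux table
#'
#' Normalises column types and token case, fills optional columns with `NA`,
#' and checks the record invariants:
#' * spatial flows carry a donor ecosystem and a driver; local fluxes carry
#'   neither (both `"none"`) and a `"none"` material origin is only allowed
#'   for local fluxes;
#' * `nep` is the only flux class allowed a negative value;
#' * detritus stocks carry no time basis; decomposition rates carry only a
#'   time basis;
#' * `per_study_period` requires `study_period_days`.
#'
#' @param x A data frame with at least the mandatory columns (`record_id`,
#'   `study_id`, `ecosystem`, `climate`, `flux_class`, `material_origin`,
#'   `driver`, `donor_ecosystem`, `value`, `mass_basis`, `spatial_basis`,
#'   `time_basis`).
#' @param strict If `TRUE` (default) any invalid row aborts; if `FALSE`
#'   invalid rows are dropped and reported in the `"rejects"` attribute, a
#'   tibble with columns `row`, `record_id`, `reason`.
#' @return A tibble with the full canonical column set, classed
#'   `flux_table`.
#' @examples
#' tbl <- as_flux_table(data.frame(
#'   record_id = "r1", study_id = "s1", ecosystem = "forest",
#'   climate = "temperate", flux_class = "gpp", material_origin = "none",
#'   driver = "none", donor_ecosystem = "none", value = 1200,
#'   mass_basis = "carbon", spatial_basis = "per_m2_recipient",
#'   time_basis = "per_year"
#' ))
#' nrow(tbl)
#' @export
as_flux_table <- function(x, strict = TRUE) {
  x <- tibble::as_tibble(x)
  mandatory <- setdiff(flux_table_columns(),
                       c("study_period_days", "carbon_fraction",
                         geometry_columns()))
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "crossflux_schema_error")
  }
  for (col in setdiff(flux_table_columns(), names(x))) {
    x[[col]] <- NA_real_
  }

  enum_cols <- c("ecosystem", "climate", "flux_class", "material_origin",
                 "driver", "mass_basis", "spatial_basis", "time_basis")
  for (col in enum_cols) {
    x[[col]] <- tolower(trimws(as.character(x[[col]])))
  }
  x$donor_ecosystem <- tolower(trimws(as.character(x$donor_ecosystem)))
  x$donor_ecosystem[is.na(x$donor_ecosystem) | x$donor_ecosystem == ""] <- "none"
  x$driver[is.na(x$driver) | x$driver == ""] <- "none"
  x$material_origin[is.na(x$material_origin) | x$material_origin == ""] <- "none"
  x$time_basis[is.na(x$time_basis) | x$time_basis == ""] <- "none"
  x$record_id <- as.character(x$record_id)
  x$study_id <- as.character(x$study_id)
  x$value <- as.numeric(x$value)
  for (col in c("study_period_days", "carbon_fraction", geometry_columns())) {
    x[[col]] <- as.numeric(x[[col]])
  }
  x <- x[, flux_table_columns()]

  problems <- validate_flux_rows(x)
  if (nrow(problems) > 0) {
    if (strict) {
      msgs <- paste0("row ", problems$row, " (", problems$record_id, "): ",
                     problems$reason)
      abort(c("invalid flux records:", utils::head(msgs, 10)),
            class = "crossflux_validation_error")
    }
    warn(paste0("dropped ", length(unique(problems$row)),
                " invalid row(s); see attr(., 'rejects')"))
    x <- x[-unique(problems$row), , drop = FALSE]
  }
  attr(x, "rejects") <- problems
  class(x) <- c("flux_table", class(x))
  x
}

# One row per violation; a row can appear several times with different reasons.
validate_flux_rows <- function(x) {
  voc <- flux_vocab()
  problems <- list()
  note <- function(rows, reason) {
    rows <- which(rows)
    if (length(rows) > 0) {
      problems[[length(problems) + 1]] <<- tibble::tibble(
        row = rows, record_id = x$record_id[rows], reason = reason)
    }
  }

  note(is.na(x$record_id) | x$record_id == "", "missing record_id")
  note(duplicated(x$record_id), "duplicated record_id")
  for (col in names(voc)) {
    if (col %in% names(x)) {
      note(!(x[[col]] %in% voc[[col]]), paste0("unknown ", col, " token"))
    }
  }
  note(!(x$donor_ecosystem %in% c(voc$ecosystem, "none")),
       "unknown donor_ecosystem token")
  note(!is.finite(x$value), "value missing or non-finite")
  note(is.finite(x$value) & x$value < 0 & x$flux_class != "nep",
       "negative value outside flux_class nep")

  spatial <- x$flux_class == "spatial_flow"
  note(spatial & x$donor_ecosystem == "none",
       "spatial_flow requires a donor_ecosystem")
  note(spatial & x$driver == "none", "spatial_flow requires a driver")
  note(spatial & x$material_origin == "none",
       "spatial_flow requires a material_origin")
  note(!spatial & x$donor_ecosystem != "none",
       "donor_ecosystem only allowed for spatial_flow")
  note(!spatial & x$driver != "none", "driver only allowed for spatial_flow")

  note(x$flux_class == "detritus_stock" & x$time_basis != "none",
       "detritus_stock carries no time basis")
  note(x$flux_class == "decomposition_rate" & x$time_basis == "none",
       "decomposition_rate requires a time basis")
  note(x$time_basis == "per_study_period" &
         !(is.finite(x$study_period_days) & x$study_period_days > 0),
       "per_study_period requires positive study_period_days")
  note(is.finite(x$carbon_fraction) &
         (x$carbon_fraction <= 0 | x$carbon_fraction > 1),
       "carbon_fraction must lie in (0, 1]")

  if (length(problems) == 0) {
    return(tibble::tibble(row = integer(), record_id = character(),
                          reason = character()))
  }
  dplyr::arrange(dplyr::bind_rows(problems), .data$row)
}

#' Read a flux table from a delimited file
#'
#' Reads a comma- (default) or tab-delimited UTF-8 table and validates it
#' with [as_flux_table()]. The delimiter is sniffed from the header line.
#'
#' @param path File path.
#' @param strict Passed to [as_flux_table()]: abort on invalid rows (`TRUE`)
#'   or drop and report them (`FALSE`).
#' @return A validated `flux_table` tibble; in non-strict mode the
#'   `"rejects"` attribute lists dropped rows with reasons.
#' @seealso [write_harmonized()]
#' @export
read_flux_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "crossflux_io_error")
  }
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_double(), record_id = readr::col_character(),
    study_id = readr::col_character(), ecosystem = readr::col_character(),
    climate = readr::col_character(), flux_class = readr::col_character(),
    material_origin = readr::col_character(), driver = readr::col_character(),
    donor_ecosystem = readr::col_character(),
    mass_basis = readr::col_character(),
    spatial_basis = readr::col_character(),
    time_basis = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  as_flux_table(raw, strict = strict)
}

#' Write a harmonized flux table
#'
#' Serialises a harmonized table so that [read_flux_table()] reads it back
#' field-identically (values at full double precision). Refuses tables that
#' still carry raw units: after harmonization every record must be in carbon
#' mass basis, per m2 of recipient ecosystem, and per year (time basis
#' `none` for detritus stocks).
#'
#' @param records A harmonized `flux_table`.
#' @param path Output file path (`.csv` comma-delimited, `.tsv` tab).
#' @return Invisibly, `path`.
#' @export
write_harmonized <- function(records, path) {
  bad <- !is_harmonized_row(records)
  if (any(bad)) {
    abort(c("records not in canonical harmonized units:",
            utils::head(records$record_id[bad], 10)),
          class = "crossflux_contract_error")
  }
  out <- dplyr::select(tibble::as_tibble(records),
                       dplyr::all_of(flux_table_columns()))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

# Canonical-unit predicate. Stocks have no time basis; rates are per year but
# keep whatever mass basis they were measured in (no carbon correction).
is_harmonized_row <- function(x) {
  time_ok <- dplyr::case_when(
    x$flux_class == "detritus_stock" ~ x$time_basis == "none",
    TRUE ~ x$time_basis == "per_year"
  )
  mass_ok <- x$flux_class == "decomposition_rate" | x$mass_basis == "carbon"
  time_ok & mass_ok & x$spatial_basis == "per_m2_recipient"
}

#' @export
print.flux_table <- function(x, ...) {
  n_rej <- nrow(attr(x, "rejects") %||% data.frame())
  cat("<flux_table> ", nrow(x), " records (",
      sum(x$flux_class == "spatial_flow"), " spatial, ",
      sum(x$flux_class != "spatial_flow"), " local)",
      if (n_rej > 0) paste0("; ", n_rej, " reject note(s)") else "",
      "\n", sep = "")
  NextMethod()
}
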