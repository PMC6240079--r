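test_that("a well-formed table validates and round-trips losslessly", {
  tbl <- flux_fixture(
    flux_row("a", value = 100.123456789),
    flux_row("b", ecosystem = "stream", flux_class = "nep", value = -114.1),
    flux_row("c", flux_class = "detritus_stock", value = 600,
             time_basis = "none")
  )
  expect_s3_class(tbl, "flux_table")
  expect_equal(nrow(tbl), 3)
  expect_equal(nrow(attr(tbl, "rejects")), 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_harmonized(tbl, path)
  back <- read_flux_table(path)
  expect_equal(tibble::as_tibble(back)[names(tibble::as_tibble(tbl))],
               tibble::as_tibble(tbl), ignore_attr = TRUE)
})

test_that("geometry columns survive the round trip", {
  tbl <- flux_fixture(
    flux_row("g1", ecosystem = "grassland", flux_class = "spatial_flow",
             material_origin = "invertebrate", driver = "life_cycle",
             donor_ecosystem = "lake", value = 1.51,
             lake_area_m2 = 12345.678, shoreline_development = 1.75)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_harmonized(tbl, path)
  back <- read_flux_table(path)
  expect_identical(back$lake_area_m2, 12345.678)
  expect_identical(back$shoreline_development, 1.75)
})

test_that("empty tables produce a header-only file that reads back", {
  tbl <- flux_fixture(flux_row())[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_harmonized(tbl, path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_flux_table(path)), 0)
})

test_that("schema and invariant violations are caught", {
  expect_error(as_flux_table(data.frame(record_id = "x")),
               class = "crossflux_schema_error")
  # spatial flow without driver
  expect_error(
    flux_fixture(flux_row(flux_class = "spatial_flow",
                          material_origin = "primary_producer",
                          donor_ecosystem = "forest", ecosystem = "stream")),
    class = "crossflux_validation_error")
  # negative GPP
  expect_error(flux_fixture(flux_row(value = -5)),
               class = "crossflux_validation_error")
  # stock with a time basis
  expect_error(
    flux_fixture(flux_row(flux_class = "detritus_stock",
                          time_basis = "per_day")),
    class = "crossflux_validation_error")
  # unknown enum token
  expect_error(flux_fixture(flux_row(ecosystem = "savanna")),
               class = "crossflux_validation_error")
})

test_that("non-strict mode drops invalid rows and reports row and reason", {
  raw <- dplyr::bind_rows(flux_row("ok"), flux_row("bad", value = -5),
                          flux_row("ok2", ecosystem = "lake"))
  expect_warning(tbl <- as_flux_table(raw, strict = FALSE), "dropped 1")
  expect_equal(tbl$record_id, c("ok", "ok2"))
  rej <- attr(tbl, "rejects")
  expect_equal(rej$row, 2L)
  expect_equal(rej$record_id, "bad")
  expect_match(rej$reason, "negative value")
})

test_that("validation is deterministic and case-insensitive on tokens", {
  raw <- dplyr::bind_rows(flux_row("A", ecosystem = "Forest"),
                          flux_row("B", ecosystem = "LAKE"))
  t1 <- as_flux_table(raw)
  t2 <- as_flux_table(raw)
  expect_identical(t1$ecosystem, c("forest", "lake"))
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
})

test_that("write_harmonized refuses raw-unit records, naming them", {
  raw <- flux_fixture(flux_row("rawrec", mass_basis = "dry_weight"))
  err <- expect_error(write_harmonized(raw, tempfile()),
                      class = "crossflux_contract_error")
  expect_match(conditionMessage(err), "rawrec")
})

test_that("configuration defaults match the documented constants", {
  cfg <- crossflux_config()
  expect_equal(cfg$band_width_m, 10)
  expect_equal(unname(cfg$gsl_days[c("temperate", "boreal", "arctic_alpine",
                                     "arid", "tropical")]),
               c(181, 155, 116, 163, 365))
  expect_equal(cfg$depth_c, 0.2)
  expect_equal(cfg$depth_f, 0.4)
  expect_equal(cfg$pelagic_default_depth_m, 100)
  cf <- cfg$carbon_fractions
  expect_true(all(cf$fraction > 0 & cf$fraction <= 1))
  expect_true(all(cf$fraction[cf$mass_basis == "carbon"] == 1))
})

test_that("config files overlay defaults and bad values error", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("band_width_m: 100", "gsl_days:", "  boreal: 150"), path)
  cfg <- read_config(path, quiet = TRUE)
  expect_equal(cfg$band_width_m, 100)
  expect_equal(unname(cfg$gsl_days["boreal"]), 150)
  expect_equal(unname(cfg$gsl_days["temperate"]), 181)  # untouched default

  expect_error(crossflux_config(band_width_m = -5),
               class = "crossflux_config_error")
  expect_error(crossflux_config(nonsense_key = 1),
               class = "crossflux_config_error")
  expect_error(crossflux_config(carbon_fractions = list(poc_doc = 1.5)),
               class = "crossflux_config_error")
})
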