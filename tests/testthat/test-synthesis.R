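test_that("group summaries use linear-interpolation quartiles", {
  tbl <- flux_fixture(purrr::map2(paste0("r", 1:5), c(1, 2, 3, 4, 100),
                                  ~ flux_row(.x, value = .y)))
  s <- group_summaries(tbl)
  expect_equal(s$median, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  expect_equal(s$min, 1)
  expect_equal(s$max, 100)
  expect_equal(s$n, 5)

  single <- group_summaries(flux_fixture(flux_row(value = 7)))
  expect_equal(single$median, 7)
  expect_equal(single$q25, 7)
  expect_equal(single$q75, 7)
})

test_that("summaries are permutation-invariant in record order", {
  sim <- simulate_fluxes(seed = 5)
  h <- harmonize(sim$records)
  set.seed(1)
  shuffled <- h[sample.int(nrow(h)), ]
  expect_equal(dplyr::arrange(group_summaries(h), ecosystem, flux_class),
               dplyr::arrange(group_summaries(shuffled), ecosystem,
                              flux_class))
})

test_that("spatial-local comparison reports the order-of-magnitude gap", {
  rows <- c(
    purrr::map(1:3, ~ flux_row(paste0("g", .x), ecosystem = "grassland",
                               value = 611.5)),
    purrr::map(1:3, ~ flux_row(paste0("s", .x), ecosystem = "grassland",
                               flux_class = "spatial_flow",
                               material_origin = "invertebrate",
                               driver = "life_cycle",
                               donor_ecosystem = "lake", value = 1.3))
  )
  cmp <- compare_spatial_local(flux_fixture(rows))
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$median_local, 611.5)
  expect_equal(cmp$median_spatial, 1.3)
  expect_equal(cmp$log10_ratio, log10(611.5 / 1.3), tolerance = 1e-12)
  expect_equal(round(cmp$log10_ratio, 2), 2.67)
})

test_that("equal medians give a zero gap and zero medians an undefined one", {
  rows <- c(
    purrr::map(1:2, ~ flux_row(paste0("l", .x), ecosystem = "stream",
                               value = 50)),
    purrr::map(1:2, ~ flux_row(paste0("sp", .x), ecosystem = "stream",
                               flux_class = "spatial_flow",
                               material_origin = "primary_producer",
                               driver = "fall_wind",
                               donor_ecosystem = "forest", value = 50))
  )
  cmp <- compare_spatial_local(flux_fixture(rows))
  expect_equal(cmp$log10_ratio, 0)

  zero <- c(
    purrr::map(1:2, ~ flux_row(paste0("z", .x), ecosystem = "stream",
                               value = 0)),
    purrr::map(1:2, ~ flux_row(paste0("zs", .x), ecosystem = "stream",
                               flux_class = "spatial_flow",
                               material_origin = "poc_doc",
                               driver = "leaching",
                               donor_ecosystem = "grassland", value = 10))
  )
  cmp0 <- compare_spatial_local(flux_fixture(zero))
  expect_equal(nrow(cmp0), 1)        # row retained
  expect_true(is.na(cmp0$log10_ratio))
})

test_that("driver and interface tabulations count exactly and sum to 100", {
  mk <- function(id, donor, eco, driver)
    flux_row(id, ecosystem = eco, flux_class = "spatial_flow",
             material_origin = "primary_producer", driver = driver,
             donor_ecosystem = donor, value = 1)
  tbl <- flux_fixture(
    mk("1", "forest", "stream", "fall_wind"),
    mk("2", "forest", "lake", "fall_wind"),
    mk("3", "ocean_pelagic", "ocean_benthic", "sinking")
  )
  tabs <- driver_interface_tabulation(tbl)
  tf <- tabs$interfaces
  expect_equal(tf$pct[tf$interface == "terrestrial-freshwater"], 66.7)
  expect_equal(tf$pct[tf$interface == "pelagic-benthic"], 33.3)
  expect_equal(tabs$driver_modes$pct[tabs$driver_modes$driver_mode ==
                                       "passive"], 100)
  expect_equal(sum(tabs$drivers$share), 1, tolerance = 1e-12)

  sim <- simulate_fluxes(seed = 9)
  big <- driver_interface_tabulation(sim$records)
  for (t in big[c("drivers", "driver_modes", "interfaces")]) {
    expect_equal(sum(t$share), 1, tolerance = 1e-12)
    expect_lt(abs(sum(t$pct) - 100), 0.1 * nrow(t))
  }
})

test_that("band sensitivity scales band-routed strata by exactly 10", {
  sim <- simulate_fluxes(seed = 13)
  sens <- sensitivity_band(sim$records, widths = c(10, 100))
  routed <- sens[!is.na(sens$affected) & sens$affected, ]
  expect_gt(nrow(routed), 0)
  expect_equal(routed$median_100, routed$median_10 / 10, tolerance = 1e-12)
  expect_equal(routed$q25_100, routed$q25_10 / 10, tolerance = 1e-12)

  untouched <- sens[!is.na(sens$affected) & !sens$affected, ]
  expect_gt(nrow(untouched), 0)
  expect_equal(untouched$median_100, untouched$median_10, tolerance = 1e-12)
  # local fluxes are never band-routed
  local <- sens[sens$flux_class != "spatial_flow", ]
  expect_true(all(!local$affected, na.rm = TRUE))
})
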