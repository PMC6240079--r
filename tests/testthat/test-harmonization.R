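test_that("carbon conversion applies the documented precedence", {
  # multiplicative definition
  expect_equal(convert_to_carbon(100, "dry_weight"), 50)
  # identity on carbon basis
  expect_equal(convert_to_carbon(7.3, "carbon", "invertebrate"), 7.3)
  # reported fraction overrides the table
  expect_equal(convert_to_carbon(100, "ash_free_dry_weight",
                                 reported_fraction = 0.42), 42)
  # unknown material class falls back to the generic entry
  expect_equal(convert_to_carbon(10, "wet_weight", "unheard_of_class"),
               10 * 0.1)
  expect_error(convert_to_carbon(1, "dry_weight", reported_fraction = 1.2),
               class = "crossflux_domain_error")
})

test_that("annualization follows the growing-season rules", {
  expect_equal(annualize(1, "per_day", "temperate"), 181)
  expect_equal(annualize(1, "per_day", "tropical"), 365)
  expect_equal(annualize(1, "per_day", "boreal"), 155)
  # study period longer than the GSL: no conversion
  expect_equal(annualize(200, "per_study_period", "temperate",
                         study_period_days = 365), 200)
  expect_equal(annualize(200, "per_study_period", "temperate",
                         study_period_days = 200), 200)
  # shorter: scaled up to the growing season
  expect_equal(annualize(10, "per_study_period", "temperate",
                         study_period_days = 90.5), 20)
  # multi-year periods are averaged down to a year
  expect_equal(annualize(730, "per_study_period", "tropical",
                         study_period_days = 730), 365)
  expect_equal(annualize(42, "per_year", "arid"), 42)
  expect_error(annualize(1, "per_study_period", "temperate"),
               class = "crossflux_contract_error")
})

test_that("depth rules match their closed forms", {
  expect_equal(lake_mean_depth(1e6, 1e5), 10)
  expect_equal(lake_mean_depth(2.5e5, 5e4), 5)
  expect_error(lake_mean_depth(0, 1), class = "crossflux_domain_error")

  expect_equal(depth_from_discharge(32), 0.8)   # 0.2 * 2^5*0.4... = 0.2*4
  expect_equal(depth_from_discharge(1), 0.2)
  expect_equal(depth_from_discharge(NA, catchment_area_km2 = 0.5), 0.05)
  expect_error(depth_from_discharge(NA, NA), class = "crossflux_contract_error")

  expect_equal(integrate_over_depth(2, 0.5), 1)
  expect_error(integrate_over_depth(1, 0), class = "crossflux_contract_error")
})

test_that("depth_from_discharge increases monotonically in discharge", {
  q <- sort(exp(seq(log(0.01), log(1e4), length.out = 200)))
  d <- depth_from_discharge(q)
  expect_true(all(diff(d) > 0))
})

test_that("harmonize composes the four steps in order", {
  # 0.5 g DW m-3 d-1 in a boreal lake of 2 m depth:
  # 0.5 (carbon) * 2 (depth) * 155 (GSL) on the raw 0.5 -> 77.5
  rec <- flux_fixture(flux_row(ecosystem = "lake", climate = "boreal",
                               value = 0.5, mass_basis = "dry_weight",
                               spatial_basis = "per_m3",
                               time_basis = "per_day", depth_m = 2))
  h <- harmonize(rec)
  expect_equal(h$value, 77.5)
  expect_equal(h$mass_basis, "carbon")
  expect_equal(h$spatial_basis, "per_m2_recipient")
  expect_equal(h$time_basis, "per_year")
  trail <- audit_trail(h)
  expect_equal(trail$step, c("carbon_conversion", "depth_integration",
                             "annualization"))
  expect_equal(trail$factor, c(0.5, 2, 155))
})

test_that("already-canonical records pass through with an empty audit", {
  rec <- flux_fixture(flux_row(value = 1234.5))
  h <- harmonize(rec)
  expect_equal(h$value, 1234.5)
  expect_equal(nrow(audit_trail(h)), 0)
})

test_that("decay rates are annualized but never carbon-converted", {
  rec <- flux_fixture(flux_row(flux_class = "decomposition_rate",
                               value = 0.004, mass_basis = "dry_weight",
                               time_basis = "per_day", climate = "temperate"))
  h <- harmonize(rec)
  expect_equal(h$value, 0.004 * 181)
  expect_equal(h$mass_basis, "dry_weight")  # kept in the measured basis
  expect_false("carbon_conversion" %in% audit_trail(h)$step)
})

test_that("detritus stocks convert mass but carry no time basis", {
  rec <- flux_fixture(flux_row(flux_class = "detritus_stock", value = 1200,
                               mass_basis = "ash_free_dry_weight",
                               time_basis = "none"))
  h <- harmonize(rec)
  expect_equal(h$value, 600)
  expect_equal(h$time_basis, "none")
})

test_that("pelagic volumetric records use the euphotic or 100 m depth", {
  with_photic <- flux_fixture(flux_row(ecosystem = "ocean_pelagic",
                                       climate = "tropical", value = 2,
                                       spatial_basis = "per_m3",
                                       photic_depth_m = 40))
  h1 <- harmonize(with_photic)
  expect_equal(h1$value, 80)
  without <- flux_fixture(flux_row(ecosystem = "ocean_pelagic",
                                   climate = "tropical", value = 2,
                                   spatial_basis = "per_m3"))
  h2 <- harmonize(without)
  expect_equal(h2$value, 200)
  expect_equal(audit_trail(h2)$rule[1], "default_pelagic_depth")
})

test_that("missing geometry aborts with the record id in the message", {
  rec <- flux_fixture(flux_row(record_id = "insects7",
                               ecosystem = "grassland",
                               flux_class = "spatial_flow",
                               material_origin = "invertebrate",
                               driver = "life_cycle",
                               donor_ecosystem = "lake",
                               spatial_basis = "per_m2_donor"))
  err <- expect_error(harmonize(rec), class = "crossflux_harmonize_error")
  expect_match(conditionMessage(err), "insects7")
})

test_that("harmonization is idempotent and homogeneous of degree one", {
  sim <- simulate_fluxes(seed = 11)
  h1 <- harmonize(sim$records)
  h2 <- harmonize(h1)
  expect_equal(h2$value, h1$value, tolerance = 1e-12)

  alpha <- 3.7
  scaled <- sim$records
  scaled$value <- scaled$value * alpha
  hs <- harmonize(scaled)
  expect_equal(hs$value, alpha * h1$value, tolerance = 1e-12)
})
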