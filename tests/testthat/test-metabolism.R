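test_that("triplet closure fills derivable members and reaches a fixpoint", {
  r1 <- close_flux_triplet(gpp = 100, r_e = 40)
  expect_equal(r1$nep, 60)
  expect_true(r1$consistent)
  expect_equal(r1$derived[[1]], "nep")

  r2 <- close_flux_triplet(npp = 70, r_h = 30, gpp = 100)
  expect_equal(r2$nep, 40)
  expect_equal(r2$r_a, 30)
  expect_equal(r2$r_e, 60)   # chained through both identities

  # a complete consistent triplet is a fixed point
  r3 <- close_flux_triplet(gpp = 100, r_e = 40, nep = 60)
  expect_true(r3$consistent)
  expect_length(r3$derived[[1]], 0)

  r4 <- close_flux_triplet(gpp = 100, r_e = 40, nep = 10)
  expect_false(r4$consistent)
  expect_equal(r4$max_residual, 50 / 100)
})

test_that("study-level closure derives the missing third flux", {
  tbl <- flux_fixture(
    flux_row("g", study_id = "st1", value = 100),
    flux_row("r", study_id = "st1", flux_class = "ecosystem_respiration",
             value = 40),
    flux_row("n_only", study_id = "st2", flux_class = "nep", value = -20),
    flux_row("g2", study_id = "st2", value = 55)
  )
  out <- close_metabolism_records(harmonize(tbl))
  derived <- out[grepl("_derived$", out$record_id), ]
  expect_equal(nrow(derived), 2)
  expect_equal(derived$value[derived$flux_class == "nep"], 60)
  expect_equal(derived$value[derived$flux_class == "ecosystem_respiration"],
               75)
})

test_that("nep t test matches the closed-form t interval", {
  x <- c(1, 2, 3, 4, 5)
  res <- tidy(nep_ttest(x))
  se <- sd(x) / sqrt(5)
  expect_equal(res$mean, 3)
  expect_equal(res$ci_low, 3 - qt(0.975, 4) * se, tolerance = 1e-12)
  expect_equal(res$ci_high, 3 + qt(0.975, 4) * se, tolerance = 1e-12)
  expect_equal(res$t_stat, 3 / se, tolerance = 1e-12)
  expect_equal(res$p_plus, pnorm(3 / sd(x)), tolerance = 1e-12)
})

test_that("p_plus is 0.5 for symmetric samples and saturates when degenerate", {
  sym <- c(-3, 3, -1.5, 1.5, -0.2, 0.2)
  res <- tidy(nep_ttest(sym))
  expect_equal(res$mean, 0)
  expect_equal(res$p_plus, 0.5)

  cst <- tidy(nep_ttest(rep(5, 4)))
  expect_true(cst$degenerate)
  expect_equal(cst$p_plus, 1)
  neg <- tidy(nep_ttest(rep(-2, 4)))
  expect_equal(neg$p_plus, 0)

  expect_error(nep_ttest(3), class = "crossflux_insufficient_data")
})

test_that("Bartlett test flags heteroscedasticity and not homoscedasticity", {
  expect_equal(bartlett_test(list(a = c(1, 2, 3), b = c(1, 2, 3)))$statistic,
               0, tolerance = 1e-12)
  set.seed(301)
  het <- list(a = rnorm(50, sd = 1), b = rnorm(50, sd = 10))
  expect_lt(bartlett_test(het)$p_value, 0.001)
  # type-I calibration under equal variances
  set.seed(302)
  rej <- mean(replicate(2000, {
    g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    bartlett_test(g)$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("Kruskal-Wallis agrees with brute-force ranks, with and without ties", {
  fixtures <- list(
    list(a = c(1, 2, 3), b = c(101, 102, 103)),
    list(a = c(1, 5, 9, 2), b = c(3, 7, 4), c = c(6, 8, 10, 11, 12)),
    list(a = c(1, 1, 2, 2), b = c(2, 3, 3), c = c(1, 4, 4)),   # heavy ties
    list(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10, 4))
  )
  set.seed(77)
  for (f in fixtures) {
    kw <- kruskal_wallis(f)
    expect_equal(kw$chi2, brute_force_kw(f), tolerance = 1e-10)
    expect_equal(kw$df, length(f) - 1)
    expect_equal(kw$p_value, pchisq(kw$chi2, kw$df, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  kw2 <- kruskal_wallis(list(a = c(1, 2, 3), b = c(101, 102, 103)))
  expect_equal(kw2$chi2, 3.857, tolerance = 1e-3)
  expect_equal(kw2$p_value, 0.0495, tolerance = 1e-3)
})

test_that("identical groups give a zero statistic and empty groups warn", {
  kw <- kruskal_wallis(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(kw$chi2, 0, tolerance = 1e-12)
  expect_warning(
    kw3 <- kruskal_wallis(list(a = 1:3, b = 4:6, c = numeric(0))),
    "excluding")
  expect_equal(kw3$df, 1)
})

test_that("Kruskal-Wallis p values are calibrated under the null", {
  set.seed(515)
  rej <- mean(replicate(1000, {
    g <- split(rnorm(80), rep(1:8, each = 10))
    kruskal_wallis(g)$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("post-hoc letters reproduce the critical-difference inequality", {
  set.seed(99)
  cases <- list(
    separated = list(a = rnorm(30), b = rnorm(30, 50)),
    identical = list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5)),
    chain = list(lo = rnorm(15), mid = rnorm(15, 1.0), hi = rnorm(15, 2.4)),
    four = list(a = rnorm(12), b = rnorm(12, 0.3), c = rnorm(12, 3),
                d = rnorm(12, 6))
  )
  for (case in cases) {
    out <- posthoc_rank_letters(case)
    hand <- hand_rank_significance(case)
    pairs <- attr(out, "pairs")
    for (p in seq_len(nrow(pairs))) {
      i <- match(pairs$group1[p], out$group)
      j <- match(pairs$group2[p], out$group)
      expect_identical(pairs$significant[p], hand[i, j])
      shares <- any(strsplit(out$letters[i], "")[[1]] %in%
                      strsplit(out$letters[j], "")[[1]])
      # groups share a letter exactly when they are not significantly different
      expect_identical(shares, !hand[i, j])
    }
  }
})

test_that("far-separated groups get distinct letters, identical groups share", {
  set.seed(100)
  out <- posthoc_rank_letters(list(a = rnorm(30), b = rnorm(30, 50)))
  expect_equal(out$letters, c("a", "b"))
  same <- posthoc_rank_letters(list(a = 1:5, b = 1:5))
  expect_equal(same$letters, c("a", "a"))
  single <- posthoc_rank_letters(list(only = 1:5))
  expect_equal(single$letters, "a")
})

test_that("a middle group can straddle two letter classes", {
  # extremes differ; the middle overlaps both
  set.seed(6)
  case <- list(lo = rnorm(20), mid = rnorm(20, 1.1), hi = rnorm(20, 2.2))
  hand <- hand_rank_significance(case)
  # only run the structural assertion when the planted pattern holds
  expect_true(hand[1, 3])
  expect_false(hand[1, 2])
  expect_false(hand[2, 3])
  out <- posthoc_rank_letters(case)
  expect_equal(out$letters, c("a", "ab", "b"))
})

test_that("letter partition is invariant to group input order", {
  set.seed(7)
  case <- list(a = rnorm(15), b = rnorm(15, 1.2), c = rnorm(15, 3),
               d = rnorm(15, 3.1))
  fwd <- posthoc_rank_letters(case)
  rev_case <- rev(case)
  bwd <- posthoc_rank_letters(rev_case)
  shares <- function(tbl, g1, g2) {
    l1 <- strsplit(tbl$letters[match(g1, tbl$group)], "")[[1]]
    l2 <- strsplit(tbl$letters[match(g2, tbl$group)], "")[[1]]
    any(l1 %in% l2)
  }
  for (g1 in names(case)) for (g2 in setdiff(names(case), g1)) {
    expect_identical(shares(fwd, g1, g2), shares(bwd, g1, g2))
  }
})

test_that("nep_analysis assembles tests, letters and the rank test", {
  sim <- simulate_fluxes(seed = 3)
  h <- harmonize(sim$records)
  an <- nep_analysis(h)
  td <- tidy(an)
  expect_equal(nrow(td), 8)
  expect_true(all(c("p_plus", "letters", "ci_low") %in% names(td)))
  gl <- glance(an)
  expect_gt(gl$chi2, 0)
  expect_equal(gl$df, 7)
  expect_lt(gl$p_value, 0.001)
  # net heterotrophic freshwater, net autotrophic forest
  expect_lt(td$p_plus[td$ecosystem == "stream"], 0.5)
  expect_gt(td$p_plus[td$ecosystem == "forest"], 0.5)
  p <- autoplot(an)
  expect_s3_class(p, "ggplot")
})
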