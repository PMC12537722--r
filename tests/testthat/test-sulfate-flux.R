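# Sulfate gradient fitting, depth of no sulfate, diffusion coefficients and
# Fick's-law fluxes.

test_that("an exact linear profile is fitted perfectly", {
  p <- linear_sulfate_profile(surface = 28, dns = 25)
  fit <- fit_sulfate_gradient(p)
  expect_equal(fit$slope, -1.12, tolerance = 1e-12)
  expect_equal(fit$intercept, 28, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("constant and degenerate profiles are handled", {
  z <- seq(1, 21, 2)
  const <- porewater_profile("A", "b", "s", z, list(sulfate = rep(5, length(z))))
  fit <- fit_sulfate_gradient(const)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_true(is.na(fit$r_squared))
  expect_error(depth_of_no_sulfate(fit), "undefined")
  allzero <- porewater_profile("A", "b", "s", z,
                               list(sulfate = rep(0, length(z))))
  expect_error(fit_sulfate_gradient(allzero), "zero")
  short <- porewater_profile("A", "b", "s", c(1, 3),
                             list(sulfate = c(4, 2)))
  expect_error(fit_sulfate_gradient(short), ">= 3")
})

test_that("the regression window starts at a subsurface sulfate maximum", {
  z <- seq(2, 38, 4)
  s <- pmax(0, 6 * (1 - z / 37)) - 2 * pmax(0, 1 - z / 10)
  p <- porewater_profile("A", "control", "winter", z, list(sulfate = pmax(0, s)))
  fit <- fit_sulfate_gradient(p)
  expect_gt(fit$depth_window[1], z[1])
  # the peak-onward line still points at the true depletion depth
  expect_equal(depth_of_no_sulfate(fit), 37, tolerance = 1)
})

test_that("depth of no sulfate is the x-intercept of the fitted line", {
  mkfit <- function(intercept, slope) {
    z <- seq(1, 21, 2)
    fit_sulfate_gradient(porewater_profile("A", "b", "s", z,
      list(sulfate = pmax(0, intercept + slope * z))))
  }
  expect_equal(depth_of_no_sulfate(mkfit(28, -1.12)), 25, tolerance = 1e-9)
  expect_equal(depth_of_no_sulfate(mkfit(28, -0.7568)), 37, tolerance = 0.01)
})

test_that("the free-solution diffusion coefficient is linear in temperature", {
  expect_equal(sulfate_diffusion_coefficient(10), 7.20e-6, tolerance = 1e-12)
  expect_equal(sulfate_diffusion_coefficient(15, m1 = 0),
               sulfate_diffusion_coefficient(0, m1 = 0))
  d0 <- vapply(c(0, 5, 10, 20), sulfate_diffusion_coefficient, numeric(1))
  expect_true(all(diff(d0) > 0))
  expect_warning(sulfate_diffusion_coefficient(45), "range")
})

test_that("tortuosity correction follows ds = d0 / (1 - ln(phi^2))", {
  expect_equal(sediment_diffusivity(7.20e-6, 0.8),
               7.20e-6 / (1 - log(0.64)), tolerance = 1e-12)
  expect_equal(sediment_diffusivity(7.20e-6, 0.8), 4.978e-6, tolerance = 1e-4)
  expect_equal(sediment_diffusivity(1, 0.999999), 1, tolerance = 1e-5)
  phis <- seq(0.1, 0.9, 0.1)
  ds <- vapply(phis, function(f) sediment_diffusivity(1e-5, f), numeric(1))
  expect_true(all(diff(ds) > 0))      # monotone in porosity
  expect_true(all(ds < 1e-5))         # always below free solution
  expect_error(sediment_diffusivity(1e-5, 1.1), "porosity")
})

test_that("Fick's-law flux converts units correctly", {
  expect_identical(diffusive_flux(0, 5e-6, 0.8), 0)
  expect_equal(diffusive_flux(-1, 5e-6, 0.8), 3.456, tolerance = 1e-12)
  expect_equal(diffusive_flux(-1, 5e-6, 0.8, include_porosity_factor = FALSE),
               4.32, tolerance = 1e-12)
  expect_gt(diffusive_flux(-1, 5e-6, 0.8), 0)   # downward sulfate flux
  expect_lt(diffusive_flux(1, 5e-6, 0.8), 0)
})

test_that("scaling all concentrations scales the flux but not the DNS", {
  for (k in c(0.25, 4)) {
    p1 <- linear_sulfate_profile(surface = 28, dns = 25)
    pk <- linear_sulfate_profile(surface = 28 * k, dns = 25)
    f1 <- core_flux(p1, 10); fk <- core_flux(pk, 10)
    expect_equal(fk$flux, k * f1$flux, tolerance = 1e-9)
    expect_equal(fk$dns, f1$dns, tolerance = 1e-9)
  }
})

test_that("non-linear profiles are excluded at the default threshold", {
  good <- fit_sulfate_gradient(linear_sulfate_profile())
  expect_true(apply_linearity_exclusion(good)$included)
  z <- seq(1, 31, 2)
  curved <- porewater_profile("A", "b", "s", z,
                              list(sulfate = pmax(0, 28 * (1 - z / 25)^4)))
  fit <- fit_sulfate_gradient(curved)
  expect_lt(fit$r_squared, 0.9)
  excl <- apply_linearity_exclusion(fit)
  expect_false(excl$included)
  expect_match(excl$exclusion_reason, "non-linear")
  # threshold is configurable
  expect_true(apply_linearity_exclusion(fit, r2_threshold = 0.5)$included)
})

test_that("noisy slope estimates stay within sampling error of the truth", {
  tr <- profile_truth("A", "control", "summer", sulfate_surface = 28,
                      dns_true = 25, noise_sd = 0.5)
  slopes <- vapply(1:200, function(i) {
    g <- generate_porewater_profiles(list(tr), seq(1, 31, 2), seed = 10000 + i)
    fit_sulfate_gradient(g$profiles[[1]])$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-1.12)), 3 * se + 0.005)
})

test_that("core_flux flags non-depleting cores instead of failing", {
  z <- seq(1, 21, 2)
  rising <- porewater_profile("A", "b", "s", z, list(sulfate = 2 + 0.1 * z))
  res <- core_flux(rising, 10)
  expect_false(res$included)
  expect_match(res$exclusion_reason, "unusable sulfate profile")
  expect_true(is.na(res$flux))
  # a flat profile fits but shows no depletion
  flat <- porewater_profile("A", "b", "s", z,
                            list(sulfate = rep(3, length(z))))
  res2 <- core_flux(flat, 10)
  expect_false(res2$included)
  expect_match(res2$exclusion_reason, "no sulfate depletion")
})

test_that("bay/season summary averages included cores only", {
  p <- linear_sulfate_profile(surface = 28, dns = 25)
  one <- core_flux(p, 10)
  expect_equal(bay_season_flux_summary(list(one))$mean_flux_mmol_m2_d,
               one$flux)
  # hand-built results: mean of 1.0 and 1.12 is 1.06; excluded core ignored
  fake <- function(flux, dns, included, bay = "control", season = "summer") {
    r <- one
    r$flux <- flux; r$dns <- dns; r$included <- included
    r$bay <- bay; r$season <- season
    r
  }
  summ <- bay_season_flux_summary(list(fake(1.0, 24, TRUE),
                                       fake(1.12, 26, TRUE),
                                       fake(99, 99, FALSE)))
  expect_equal(summ$mean_flux_mmol_m2_d, 1.06)
  expect_equal(summ$mean_dns_cm, 25)
  expect_identical(summ$n_included, 2L)
  # a group with no included cores yields an NA row, not an error
  summ2 <- bay_season_flux_summary(list(fake(1.0, 24, TRUE),
                                        fake(9, 9, FALSE, bay = "heated")))
  expect_true(is.na(summ2$mean_flux_mmol_m2_d[summ2$bay == "heated"]))
})
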