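wt_like <- tibble::tibble(mutant = "wt", k_cat = 0.05, K_m = 2e-7)

test_that("noiseless Michaelis-Menten data are recovered exactly", {
  d <- simulate_titrations(kinetic_sim_spec(wt_like, noise_sd = 0, seed = 2))
  fit <- fit_michaelis_menten(d)
  expect_equal(fit$k_cat, 0.05, tolerance = 1e-8)
  expect_equal(fit$K_m, 2e-7, tolerance = 1e-8)
  expect_equal(fit$efficiency, fit$k_cat / fit$K_m)
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(nrow(tidy(fit)), 2L)
})

test_that("round-trip: refitting data generated from fitted parameters", {
  d <- simulate_titrations(kinetic_sim_spec(wt_like, noise_sd = 0.05, seed = 4))
  fit1 <- fit_michaelis_menten(d)
  d2 <- simulate_titrations(kinetic_sim_spec(
    tibble::tibble(mutant = "wt", k_cat = fit1$k_cat, K_m = fit1$K_m),
    noise_sd = 0, seed = 1))
  fit2 <- fit_michaelis_menten(d2)
  expect_equal(fit2$k_cat, fit1$k_cat, tolerance = 1e-6)
  expect_equal(fit2$K_m, fit1$K_m, tolerance = 1e-6)
})

test_that("k_cat is recovered within 5% median relative error at 5% noise", {
  errs <- vapply(1:60, function(s) {
    d <- simulate_titrations(kinetic_sim_spec(wt_like, noise_sd = 0.05,
                                              replicates = 3, seed = 1000 + s))
    abs(fit_michaelis_menten(d)$k_cat - 0.05) / 0.05
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("degenerate titrations fail loudly", {
  d <- simulate_titrations(kinetic_sim_spec(wt_like, noise_sd = 0, seed = 1))
  expect_error(fit_michaelis_menten(dplyr::mutate(d, rate_per_s = 0)), "~0")
  expect_error(fit_michaelis_menten(d[d$conc_M < 1e-6, ]), "concentrations")
  expect_error(fit_michaelis_menten(dplyr::mutate(d, conc_M = -conc_M)),
               "positive")
})

test_that("free-energy changes of mutation follow -RT ln(efficiency ratio)", {
  expect_equal(ddg_of_mutation(2.5e5, 2.5e5), 0)
  # antisymmetry property
  set.seed(6)
  for (rep in 1:10) {
    ea <- 10^runif(1, 3, 7); eb <- 10^runif(1, 3, 7)
    expect_equal(ddg_of_mutation(ea, eb), -ddg_of_mutation(eb, ea))
  }
  expect_error(ddg_of_mutation(-1, 2.5e5), "positive")
  expect_error(ddg_of_mutation(2.5e5, 0), "positive")
})

test_that("coupling energy arithmetic and M1/M2 swap invariance", {
  expect_equal(coupling_energy_therm(1.0, 1.0, 2.0), 0.0)
  expect_equal(coupling_energy_therm(-1.0, 0.5, -2.5), 2.0)
  set.seed(12)
  for (rep in 1:10) {
    g <- rnorm(3)
    expect_equal(coupling_energy_therm(g[1], g[2], g[3]),
                 coupling_energy_therm(g[2], g[1], g[3]))
  }
})

test_that("epistasis classes follow the documented ordered rules", {
  # |ce| = 0.89 -> additive (the negative-control regime)
  expect_equal(classify_epistasis(1.0, 1.0, 1.11), "additive")
  # cooperative non-additive: double mutant below the summed singles
  cls <- classify_epistasis(2.0, 2.0, 2.0)   # ce = 2, between max single and sum
  expect_true(cls %in% c("partially-additive", "antagonistic",
                         "no-additional-effect"))
  expect_false(cls == "additive")
  # definitional synergy: |ddg12| > |ddg1| + |ddg2| + bound
  expect_equal(classify_epistasis(1.0, 1.0, 3.5), "synergistic")
  # double mutant tracking one single mutant
  expect_equal(classify_epistasis(2.0, 1.5, 2.1), "no-additional-effect")
  # double mutant between larger single and sum
  expect_equal(classify_epistasis(2.0, 1.5, 2.5), "partially-additive")
  # counteracting mutations
  expect_equal(classify_epistasis(2.0, 1.5, 0.5), "antagonistic")
})

make_cycle_fits <- function(effs, seed = 1) {
  # build mm_fit objects via noiseless titrations with the requested
  # efficiencies (k_cat fixed, K_m = k_cat / efficiency)
  specs <- tibble::tibble(mutant = names(effs), k_cat = 0.05,
                          K_m = 0.05 / unname(effs))
  d <- simulate_titrations(kinetic_sim_spec(specs, noise_sd = 0, seed = seed))
  fit_titrations(d)
}

test_that("cycles constructed additive by design give CE_THERM ~ 0", {
  # ddg1 = 0.5, ddg2 = 0.8, ddg12 = 1.3 kcal/mol exactly
  RT <- 1.987e-3 * 298
  eff_wt <- 2.5e5
  effs <- c(wt = eff_wt,
            m1 = eff_wt * exp(-0.5 / RT),
            m2 = eff_wt * exp(-0.8 / RT),
            m1m2 = eff_wt * exp(-1.3 / RT))
  fits <- make_cycle_fits(effs)
  cyc <- mutant_cycle(fits$wt, fits$m1, fits$m2, fits$m1m2)
  expect_equal(cyc$ce_therm, 0, tolerance = 1e-6)
  expect_equal(cyc$class, "additive")
  expect_equal(tidy(cyc)$ddg_m1, 0.5, tolerance = 1e-6)
})

test_that("additivity offset recovers imposed coupling energies", {
  cycles0 <- tibble::tibble(ddg_m1 = c(1, 2, 0.5), ddg_m2 = c(0.5, 1, 1),
                            ddg_m1m2 = c(1.5, 3, 1.5))
  expect_equal(additivity_offset(cycles0)$offset, 0)

  cycles_c <- dplyr::mutate(cycles0, ddg_m1m2 = ddg_m1m2 - 1.7)
  expect_equal(additivity_offset(cycles_c)$offset, 1.7)

  set.seed(42)
  n <- 6
  s <- runif(n, 1, 4)
  ce <- rnorm(n, mean = 2.0, sd = 0.3)
  sim <- tibble::tibble(ddg_m1 = s / 2, ddg_m2 = s / 2, ddg_m1m2 = s - ce)
  off <- additivity_offset(sim)
  expect_true(off$conf_low <= 2.0 && 2.0 <= off$conf_high)
  expect_equal(off$n, n)

  expect_error(additivity_offset(cycles0[1, ]), "at least two")
})

test_that("run_mutant_cycles assembles a tidy cycle table from a manifest", {
  RT <- 1.987e-3 * 298
  effs <- c(wt = 2.5e5,
            A = 2.5e5 * exp(-1.0 / RT), B = 2.5e5 * exp(-1.2 / RT),
            AB = 2.5e5 * exp(-0.4 / RT))
  fits <- make_cycle_fits(effs)
  manifest <- tibble::tibble(wt = "wt", m1 = "A", m2 = "B", m1m2 = "AB")
  res <- run_mutant_cycles(fits, manifest)
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$table$ce_therm, 1.0 + 1.2 - 0.4, tolerance = 1e-6)
  expect_error(run_mutant_cycles(fits, dplyr::mutate(manifest, m1 = "missing")),
               "missing")
})

test_that("imposed CE-distance decay is recovered from synthetic cycles", {
  set.seed(9)
  slope_true <- -0.05   # kcal/mol per angstrom
  d <- seq(7, 30, length.out = 8)
  ce <- 2.5 + slope_true * d + rnorm(8, sd = 0.05)
  s <- runif(8, 2, 4)
  cycles <- tibble::tibble(ddg_m1 = s / 2, ddg_m2 = s / 2, ddg_m1m2 = s - ce,
                           d_ij = d)
  fit <- lm(I(ddg_m1 + ddg_m2 - ddg_m1m2) ~ d_ij, data = cycles)
  expect_equal(unname(coef(fit)["d_ij"]), slope_true, tolerance = 0.3)
})
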