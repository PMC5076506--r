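# Gas constant in kcal mol^-1 K^-1
R_KCAL <- 1.987e-3

#' Fit the Michaelis-Menten equation to an ATPase titration
#'
#' Nonlinear least-squares fit of
#' \deqn{v = k_{cat} [S] / (K_m + [S])}
#' by Levenberg-Marquardt with positivity bounds. Replicates are averaged per
#' concentration before fitting (set `average_replicates = FALSE` to fit all
#' points). Initialisation: `k_cat` from the maximum observed rate and `K_m`
#' from the concentration nearest half-max, with a log-spaced `K_m` grid
#' fallback if the first attempt fails to converge.
#'
#' @param data Tibble with columns `conc_M` (substrate concentration,
#'   molar, > 0) and `rate_per_s` (turnover, 1/s); optional `replicate`.
#' @param average_replicates Average rates per concentration first (default
#'   `TRUE`).
#' @param min_concentrations Minimum number of distinct concentrations
#'   (default 5).
#' @return An object of class `mm_fit`: `k_cat`, `k_cat_se`, `K_m`, `K_m_se`
#'   (standard errors from the fit covariance), `efficiency`
#'   (`k_cat / K_m`, 1/(M s)), `converged`, `n_points`, and the underlying
#'   `nls` fit. Failure to converge (or all-zero rates) is an explicit error.
#' @examples
#' d <- simulate_titrations(kinetic_sim_spec(
#'   tibble::tibble(mutant = "wt", k_cat = 0.05, K_m = 2e-7),
#'   noise_sd = 0, seed = 1))
#' fit_michaelis_menten(d[d$mutant == "wt", ])
#' @export
fit_michaelis_menten <- function(data, average_replicates = TRUE,
                                 min_concentrations = 5L) {
  data <- as_tibble(data)
  stopifnot(all(c("conc_M", "rate_per_s") %in% names(data)))
  if (any(data$conc_M <= 0)) abort("concentrations must be positive")
  if (length(unique(data$conc_M)) < min_concentrations) {
    abort(sprintf("need at least %d distinct concentrations", min_concentrations))
  }
  pts <- if (average_replicates) {
    data |> group_by(.data$conc_M) |>
      summarise(rate_per_s = mean(.data$rate_per_s), .groups = "drop")
  } else {
    select(data, "conc_M", "rate_per_s")
  }
  if (max(abs(pts$rate_per_s)) < .Machine$double.eps^0.5) {
    abort("all rates are ~0; Michaelis-Menten fit is undefined")
  }
  vmax0 <- max(pts$rate_per_s)
  km0 <- pts$conc_M[which.min(abs(pts$rate_per_s - vmax0 / 2))]
  km_grid <- unique(c(km0, 10^seq(log10(min(pts$conc_M)) - 1,
                                  log10(max(pts$conc_M)) + 1, length.out = 7)))
  fit <- NULL
  for (km_try in km_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(rate_per_s ~ k_cat * conc_M / (K_m + conc_M),
                        data = pts,
                        start = list(k_cat = vmax0, K_m = km_try),
                        lower = c(k_cat = 1e-12, K_m = 1e-15),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$convInfo$isConv) break
    fit <- NULL
  }
  if (is.null(fit)) {
    abort("Michaelis-Menten fit did not converge (tried grid of K_m starts)")
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(k_cat = NA_real_, K_m = NA_real_))
  structure(list(k_cat = unname(est[["k_cat"]]),
                 k_cat_se = unname(se[["k_cat"]]),
                 K_m = unname(est[["K_m"]]),
                 K_m_se = unname(se[["K_m"]]),
                 efficiency = unname(est[["k_cat"]] / est[["K_m"]]),
                 converged = fit$convInfo$isConv,
                 n_points = nrow(pts),
                 data = pts,
                 fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> k_cat = %.4g /s, K_m = %.4g M, k_cat/K_m = %.4g /(M s)\n",
              x$k_cat, x$K_m, x$efficiency))
  invisible(x)
}

#' @rdname glance.mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("k_cat", "K_m"),
         estimate = c(x$k_cat, x$K_m),
         std.error = c(x$k_cat_se, x$K_m_se))
}

#' Tidy and summarise Michaelis-Menten fits
#'
#' `tidy()` gives one row per parameter, `glance()` a one-row model summary
#' including the catalytic efficiency `k_cat / K_m`.
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(k_cat = x$k_cat, k_cat_se = x$k_cat_se, K_m = x$K_m,
         K_m_se = x$K_m_se, efficiency = x$efficiency,
         converged = x$converged, n_points = x$n_points)
}

#' Free-energy change of catalysis caused by mutation
#'
#' \deqn{\Delta\Delta G_M = -RT \ln\left(\frac{(k_{cat}/K_m)_{mut}}
#'   {(k_{cat}/K_m)_{wt}}\right)}
#' in kcal/mol, with R = 1.987e-3 kcal/(mol K). Negative values mark
#' facilitating mutations (lower catalytic barrier than wild type).
#'
#' @param eff_mut,eff_wt Catalytic efficiencies `k_cat / K_m` in 1/(M s),
#'   both > 0. Vectorised.
#' @param temperature Assay temperature in kelvin (default 298).
#' @return Free-energy change(s) in kcal/mol.
#' @examples
#' ddg_of_mutation(1.6e6, 2.5e5)  # -1.1 kcal/mol
#' @export
ddg_of_mutation <- function(eff_mut, eff_wt, temperature = 298) {
  if (any(eff_mut <= 0) || any(eff_wt <= 0)) {
    abort("catalytic efficiencies must be positive")
  }
  -R_KCAL * temperature * log(eff_mut / eff_wt)
}

#' Thermodynamic coupling energy of a double-mutant cycle
#'
#' \deqn{CE_{THERM} = \Delta\Delta G_{M1} + \Delta\Delta G_{M2} -
#'   \Delta\Delta G_{M1M2}}
#' Positive values mean the double mutant is less perturbed than the sum of
#' its single mutants (cooperative coupling); the measure is symmetric in the
#' two single mutants.
#'
#' @param ddg1,ddg2,ddg12 Free-energy changes in kcal/mol (single mutants and
#'   double mutant). Vectorised.
#' @return Coupling energy in kcal/mol.
#' @export
coupling_energy_therm <- function(ddg1, ddg2, ddg12) {
  stopifnot(all(is.finite(c(ddg1, ddg2, ddg12))))
  ddg1 + ddg2 - ddg12
}

#' Classify the epistatic interaction of a residue pair
#'
#' Coupling energies smaller in magnitude than the additivity bound are
#' additive (independent residues). Non-additive cycles are subdivided by an
#' ordered magnitude rule set on `s = ddg1 + ddg2`, `d = ddg12` and
#' `m = max(|ddg1|, |ddg2|)`:
#' \enumerate{
#'   \item `additive`: `|s - d| < additivity_bound`;
#'   \item `synergistic`: the double mutant exceeds the summed singles
#'     (`|d| > |s|`, same sign);
#'   \item `no-additional-effect`: the double mutant tracks one single mutant
#'     (`|d - ddg1| or |d - ddg2| < additivity_bound / 2`);
#'   \item `partially-additive`: `m < |d| < |s|`;
#'   \item `antagonistic`: the remaining cooperative cases (`|d| <= m`, the
#'     mutations counteract).
#' }
#'
#' @param ddg1,ddg2,ddg12 Free-energy changes in kcal/mol.
#' @param additivity_bound Magnitude below which a coupling energy is
#'   experimentally additive, kcal/mol (default 1.0; 1.5 is the permissive
#'   literature bound).
#' @return One of `"additive"`, `"synergistic"`, `"no-additional-effect"`,
#'   `"partially-additive"`, `"antagonistic"`.
#' @export
classify_epistasis <- function(ddg1, ddg2, ddg12, additivity_bound = 1.0) {
  s <- ddg1 + ddg2
  d <- ddg12
  ce <- s - d
  m <- max(abs(ddg1), abs(ddg2))
  if (abs(ce) < additivity_bound) return("additive")
  if (abs(d) > abs(s) && sign(d) == sign(s)) return("synergistic")
  if (min(abs(d - ddg1), abs(d - ddg2)) < additivity_bound / 2) {
    return("no-additional-effect")
  }
  if (abs(d) > m && abs(d) < abs(s)) return("partially-additive")
  "antagonistic"
}

#' Assemble a double-mutant cycle from four kinetic fits
#'
#' @param wt,m1,m2,m12 `mm_fit` objects (wild type, single mutants, double).
#' @param temperature Kelvin (default 298).
#' @param additivity_bound kcal/mol (default 1.0).
#' @param ids Optional character vector of the four construct names.
#' @return An object of class `mutant_cycle` with the four efficiencies,
#'   `ddg_m1`, `ddg_m2`, `ddg_m1m2`, `ce_therm` and the epistasis `class`.
#' @export
mutant_cycle <- function(wt, m1, m2, m12, temperature = 298,
                         additivity_bound = 1.0,
                         ids = c("wt", "m1", "m2", "m1m2")) {
  fits <- list(wt = wt, m1 = m1, m2 = m2, m12 = m12)
  stopifnot(all(vapply(fits, inherits, logical(1), "mm_fit")))
  ddg1 <- ddg_of_mutation(m1$efficiency, wt$efficiency, temperature)
  ddg2 <- ddg_of_mutation(m2$efficiency, wt$efficiency, temperature)
  ddg12 <- ddg_of_mutation(m12$efficiency, wt$efficiency, temperature)
  structure(list(ids = ids, fits = fits,
                 ddg_m1 = ddg1, ddg_m2 = ddg2, ddg_m1m2 = ddg12,
                 ce_therm = coupling_energy_therm(ddg1, ddg2, ddg12),
                 class = classify_epistasis(ddg1, ddg2, ddg12, additivity_bound),
                 temperature = temperature,
                 additivity_bound = additivity_bound),
            class = "mutant_cycle")
}

#' @export
print.mutant_cycle <- function(x, ...) {
  cat(sprintf("<mutant_cycle> %s/%s: CE_THERM = %.2f kcal/mol (%s)\n",
              x$ids[2], x$ids[3], x$ce_therm, x$class))
  invisible(x)
}

#' @rdname mutant_cycle
#' @param x A `mutant_cycle`.
#' @param ... Unused.
#' @export
tidy.mutant_cycle <- function(x, ...) {
  tibble(m1 = x$ids[2], m2 = x$ids[3],
         ddg_m1 = x$ddg_m1, ddg_m2 = x$ddg_m2, ddg_m1m2 = x$ddg_m1m2,
         ce_therm = x$ce_therm, class = x$class)
}

#' Fit every mutant in a titration table
#'
#' @param data Tibble with columns `mutant`, `conc_M`, `rate_per_s` and
#'   optionally `replicate`.
#' @param ... Passed to [fit_michaelis_menten()].
#' @return Named list of `mm_fit` objects, one per mutant.
#' @export
fit_titrations <- function(data, ...) {
  data <- as_tibble(data)
  stopifnot("mutant" %in% names(data))
  data |> split(~mutant) |> purrr::map(fit_michaelis_menten, ...)
}

#' Run double-mutant cycles from fits and a cycle manifest
#'
#' @param fits Named list of `mm_fit` objects (from [fit_titrations()]).
#' @param manifest Tibble with columns `wt`, `m1`, `m2`, `m1m2` naming the
#'   constructs of each cycle.
#' @param temperature,additivity_bound Passed to [mutant_cycle()].
#' @return A list: `cycles` (list of `mutant_cycle`) and `table` (tidy tibble,
#'   one row per cycle).
#' @export
run_mutant_cycles <- function(fits, manifest, temperature = 298,
                              additivity_bound = 1.0) {
  manifest <- as_tibble(manifest)
  stopifnot(all(c("wt", "m1", "m2", "m1m2") %in% names(manifest)))
  missing <- setdiff(unique(unlist(manifest[c("wt", "m1", "m2", "m1m2")])),
                     names(fits))
  if (length(missing) > 0L) {
    abort(paste0("no fit for construct(s): ", paste(missing, collapse = ", ")))
  }
  cycles <- purrr::pmap(manifest[c("wt", "m1", "m2", "m1m2")],
                        function(wt, m1, m2, m1m2) {
                          mutant_cycle(fits[[wt]], fits[[m1]], fits[[m2]],
                                       fits[[m1m2]], temperature,
                                       additivity_bound,
                                       ids = c(wt, m1, m2, m1m2))
                        })
  list(cycles = cycles,
       table = purrr::map_dfr(cycles, tidy.mutant_cycle))
}

#' Fit the additivity offset across a set of cycles
#'
#' Least-squares intercept of `ddg_m1 + ddg_m2` against `ddg_m1m2` with the
#' slope fixed at 1: the fitted offset is the mean coupling energy, reported
#' with its standard error and t-based confidence interval. A free-slope
#' regression is returned as a diagnostic.
#'
#' @param cycles Tibble with columns `ddg_m1`, `ddg_m2`, `ddg_m1m2` (e.g. the
#'   `table` from [run_mutant_cycles()]), or a list of `mutant_cycle` objects.
#' @param conf_level Confidence level for the offset interval (default 0.95).
#' @return A list: `offset` (kcal/mol), `se`, `conf_low`, `conf_high`, `n`,
#'   and `free_slope` (tibble with slope/intercept of the unconstrained fit,
#'   `NA` slope when degenerate).
#' @export
additivity_offset <- function(cycles, conf_level = 0.95) {
  if (is.list(cycles) && length(cycles) > 0 && inherits(cycles[[1]], "mutant_cycle")) {
    cycles <- purrr::map_dfr(cycles, tidy.mutant_cycle)
  }
  cycles <- as_tibble(cycles)
  if (nrow(cycles) < 2L) abort("need at least two cycles")
  s <- cycles$ddg_m1 + cycles$ddg_m2
  d <- cycles$ddg_m1m2
  ce <- s - d
  n <- length(ce)
  offset <- mean(ce)
  se <- stats::sd(ce) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  free <- if (stats::sd(d) > 0) {
    fit <- stats::lm(s ~ d)
    tibble(intercept = unname(stats::coef(fit)[1]),
           slope = unname(stats::coef(fit)[2]))
  } else {
    tibble(intercept = NA_real_, slope = NA_real_)
  }
  list(offset = offset, se = se,
       conf_low = offset - tq * se, conf_high = offset + tq * se,
       n = n, free_slope = free)
}
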