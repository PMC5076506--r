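test_that("generators are bit-identical under a fixed seed", {
  s1 <- simulate_msa(msa_sim_spec(n_sequences = 50, n_columns = 30, seed = 99))
  s2 <- simulate_msa(msa_sim_spec(n_sequences = 50, n_columns = 30, seed = 99))
  expect_identical(s1$alignment$mat, s2$alignment$mat)
  s3 <- simulate_msa(msa_sim_spec(n_sequences = 50, n_columns = 30, seed = 100))
  expect_false(identical(s1$alignment$mat, s3$alignment$mat))

  spec <- kinetic_sim_spec(tibble::tibble(mutant = "wt", k_cat = 0.05,
                                          K_m = 2e-7), seed = 5)
  expect_identical(simulate_titrations(spec), simulate_titrations(spec))

  expect_identical(simulate_structure(40, "random-coil", seed = 3)$coords,
                   simulate_structure(40, "random-coil", seed = 3)$coords)
})

test_that("planted covariation behaves as specified at the epsilon extremes", {
  # epsilon = 1: covariation exact by construction (columns jointly two-valued)
  pair1 <- tibble::tibble(i = 3L, j = 9L, epsilon = 1)
  s <- simulate_msa(msa_sim_spec(n_sequences = 300, n_columns = 12,
                                 planted_pairs = pair1, seed = 21))
  combos <- unique(paste0(s$alignment$mat[, 3], s$alignment$mat[, 9]))
  expect_lte(length(combos), 2L)

  # epsilon = 0: empirical mutual information of the pair is near zero
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    px <- rowSums(tab); py <- colSums(tab)
    sum(tab * log(tab / outer(px, py)), na.rm = TRUE)
  }
  pair0 <- tibble::tibble(i = 3L, j = 9L, epsilon = 0)
  s0 <- simulate_msa(msa_sim_spec(n_sequences = 2000, n_columns = 12,
                                  planted_pairs = pair0, seed = 22))
  mi_planted <- mi(s0$alignment$mat[, 3], s0$alignment$mat[, 9])
  s1 <- simulate_msa(msa_sim_spec(n_sequences = 2000, n_columns = 12,
                                  planted_pairs = pair1, seed = 22))
  mi_coupled <- mi(s1$alignment$mat[, 3], s1$alignment$mat[, 9])
  expect_lt(mi_planted, 0.15)           # ~ chi-square noise floor at this n
  expect_gt(mi_coupled, 0.5)            # two equiprobable combos: MI ~ ln 2
})

test_that("infeasible alignment specs are rejected", {
  expect_error(msa_sim_spec(n_columns = 10,
                            planted_pairs = tibble::tibble(i = 1, j = 11,
                                                           epsilon = 0.5)),
               "range")
  expect_error(msa_sim_spec(planted_pairs = tibble::tibble(i = c(1, 1),
                                                           j = c(2, 3),
                                                           epsilon = 0.5)),
               "disjoint")
  expect_error(msa_sim_spec(planted_pairs = tibble::tibble(i = 1, j = 2,
                                                           epsilon = 1.5)),
               "epsilon")
})

test_that("injected redundancy clusters and fragments are curated away", {
  sim <- simulate_msa(msa_sim_spec(
    n_sequences = 40, n_columns = 60, seed = 31,
    planted_pairs = tibble::tibble(i = integer(0), j = integer(0),
                                   epsilon = numeric(0)),
    redundancy_clusters = list(count = 3, within_identity = 0.97),
    fragment_fraction = 0.1))
  expect_equal(length(sim$truth$duplicate_ids), 6L)
  expect_equal(length(sim$truth$fragment_ids), 4L)
  res <- curate_sequences(sim$sequences, aligned = TRUE)
  expect_true(all(sim$truth$fragment_ids %in%
                    res$report$removed$id[res$report$removed$reason == "fragment"]))
  # each duplicate cluster collapses to a single representative
  removed_red <- res$report$removed$id[res$report$removed$reason == "redundant"]
  expect_true(all(sim$truth$duplicate_ids %in% removed_red))
  expect_equal(glance(res$report)$n_output, 40L)
})

test_that("noiseless titrations lie exactly on the Michaelis-Menten curve", {
  spec <- kinetic_sim_spec(tibble::tibble(mutant = c("wt", "mut"),
                                          k_cat = c(0.05, 0.5),
                                          K_m = c(2e-7, 1e-3)),
                           noise_sd = 0, seed = 2)
  d <- simulate_titrations(spec)
  truth <- dplyr::left_join(d, spec$mutants, by = "mutant")
  expect_equal(d$rate_per_s,
               truth$k_cat * truth$conc_M / (truth$K_m + truth$conc_M))
  expect_equal(length(unique(d$conc_M)), 12L)
  expect_equal(range(d$conc_M), c(238e-9, 1e-3))
})

test_that("ideal-geometry traces match the closed-form helix oracle", {
  hel <- simulate_structure(25, "helix")
  # chord/rise closed form: d(i, i+k)^2 = (2 r sin(k * 50 deg))^2 + (1.5 k)^2
  r <- 2.3
  for (k in c(1, 3, 4, 7)) {
    expected <- sqrt((2 * r * sin(k * 50 * pi / 180))^2 + (1.5 * k)^2)
    expect_equal(ca_distance(hel, 1, 1 + k), expected, tolerance = 1e-12)
  }
  expect_equal(ca_distance(hel, 1, 2), 3.83, tolerance = 1e-2)
  expect_equal(classify_pair(ca_distance(hel, 1, 4)), "contact")

  ext <- simulate_structure(10, "extended")
  expect_equal(ca_distance(ext, 1, 10), 9 * 3.8)

  coil <- simulate_structure(150, "random-coil", seed = 8)
  pairs <- t(combn(seq(1, 150, by = 7), 2))
  d <- apply(pairs, 1, function(p) ca_distance(coil, p[1], p[2]))
  cls <- classify_pair(d)
  expect_true(all(c("contact", "distal") %in% cls) || all(cls == "distal"))
  expect_equal(sort(unique(cls)), sort(unique(ifelse(d < 6, "contact", "distal"))))
})
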