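toy_alignment <- function(rows, ref = NULL) {
  aa_alignment(setNames(rows, sprintf("s%02d", seq_along(rows))), ref_id = ref)
}

test_that("column statistics match a hand tally", {
  aln <- toy_alignment(c("GA", "GV", "GA", "GV"))
  s1 <- column_statistics(aln, 1)
  expect_equal(unname(s1$frequencies["G"]), 1.0)
  s2 <- column_statistics(aln, 2)
  expect_equal(unname(s2$frequencies[c("A", "V")]), c(0.5, 0.5))
  expect_equal(s2$n_effective, 4L)

  set.seed(13)
  rows <- replicate(30, random_seq(5, gap_rate = 0.2))
  aln <- toy_alignment(rows)
  for (col in 1:5) {
    st <- column_statistics(aln, col)
    hand <- table(factor(substr(rows, col, col), levels = AA20))
    expect_equal(unname(st$counts), as.vector(hand))
    expect_equal(st$n_effective, sum(hand))
  }
})

test_that("all-gap columns are flagged and excluded from the matrix", {
  aln <- toy_alignment(c("A-C", "A-C", "V-C", "V-C"))
  expect_warning(column_statistics(aln, 2), "all-gap")
  cm <- suppressWarnings(sca_coupling(aln, min_sub_rows = 1,
                                      min_sub_fraction = 0))
  expect_false(cm$included[2])
  expect_true(all(is.na(cm$ddg[2, ])))
})

test_that("conservation energy is zero at background and ranks rare above common", {
  q <- setNames(c(0.30, rep(0.7 / 19, 19)), AA20)   # A common, others rare
  stats_bg <- list(frequencies = q, background = q)
  expect_equal(conservation_energy(stats_bg), 0)

  # columns fully conserved at a common (A) vs a rare residue (C)
  lambda <- 0.01
  n <- 50
  counts_common <- setNames(c(n, rep(0, 19)), AA20)
  counts_rare <- setNames(c(0, n, rep(0, 18)), AA20)
  mk <- function(counts) list(
    probabilities = (counts / n + lambda) / (1 + 20 * lambda), background = q)
  e_common <- conservation_energy(mk(counts_common))
  e_rare <- conservation_energy(mk(counts_rare))
  expect_gt(e_rare, e_common)
  # longhand check of the common case
  expect_equal(e_common,
               oracle_conservation(rep("A", n), q, lambda))
})

test_that("tiny-alignment conservation energies equal longhand evaluation", {
  set.seed(31)
  rows <- replicate(5, random_seq(3))
  aln <- toy_alignment(rows)
  q <- background_frequencies(aln, pseudocount = 0.2)
  for (col in 1:3) {
    st <- column_statistics(aln, col, pseudocount = 0.2, background = q)
    expect_equal(conservation_energy(st),
                 oracle_conservation(substr(rows, col, col), q, 0.2),
                 tolerance = 1e-12)
  }
})

test_that("perfect covariation couples more strongly than independence", {
  # columns 1-2 perfectly covary (two compatible combinations); column 3 is
  # independent of both
  set.seed(17)
  n <- 2000
  state <- sample(1:2, n, replace = TRUE)
  rows <- paste0(c("A", "L")[state], c("G", "W")[state],
                 sample(c("S", "T"), n, replace = TRUE))
  aln <- toy_alignment(rows)
  cm <- sca_coupling(aln, min_sub_rows = 10, min_sub_fraction = 0.05)
  expect_gt(cm$ddg[1, 2], cm$ddg[1, 3])
  expect_gt(cm$ddg[1, 2], cm$ddg[2, 3])
  # independence limit: energy near zero relative to the covarying pair
  expect_lt(cm$ddg[1, 3] / cm$ddg[1, 2], 0.2)
})

test_that("inadmissible perturbations are masked as missing, never zero", {
  set.seed(5)
  rows <- replicate(12, random_seq(4))
  aln <- toy_alignment(rows)
  res <- coupling_energy(aln, 1, 2, min_sub_fraction = 0.9, min_sub_rows = 1)
  expect_false(res$valid)
  expect_true(is.na(res$energy))
})

test_that("a two-column toy matrix reproduces the pairwise coupling energy", {
  rows <- c("AG", "AG", "AG", "LW", "LW", "AW", "LG", "AG")
  aln <- toy_alignment(rows)
  cm <- sca_coupling(aln, min_sub_rows = 1, min_sub_fraction = 0)
  d12 <- coupling_energy(aln, 1, 2, min_sub_fraction = 0, min_sub_rows = 1)
  d21 <- coupling_energy(aln, 2, 1, min_sub_fraction = 0, min_sub_rows = 1)
  expect_equal(cm$ddg[1, 2], mean(c(d12$energy, d21$energy)))
  expect_equal(cm$ddg[1, 2], cm$ddg[2, 1])
})

test_that("coupling matrix is invariant to row permutation", {
  set.seed(23)
  rows <- replicate(40, random_seq(6))
  aln1 <- toy_alignment(rows)
  aln2 <- aa_alignment(setNames(sample(rows), sprintf("p%02d", 1:40)))
  cm1 <- sca_coupling(aln1, min_sub_rows = 2, min_sub_fraction = 0.02)
  cm2 <- sca_coupling(aln2, min_sub_rows = 2, min_sub_fraction = 0.02)
  expect_equal(cm1$ddg, cm2$ddg)
})

test_that("matrix entries equal the longhand oracle to 1e-12 (small alignments)", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(5:10, 1); L <- sample(3:6, 1)
    rows <- replicate(n, random_seq(L))
    aln <- toy_alignment(rows)
    cm <- sca_coupling(aln, min_sub_rows = 1, min_sub_fraction = 0)
    mat <- matrix(unlist(strsplit(rows, "")), nrow = n, byrow = TRUE)
    expect_equal(cm$ddg, oracle_sca(mat, lambda = 1 / n),
                 tolerance = 1e-12)
  }
})

test_that("planted pairs dominate the coupling distribution", {
  sim <- simulate_msa(msa_sim_spec(n_sequences = 800, n_columns = 120,
                                   seed = 101))
  cm <- sca_coupling(sim$alignment)
  tp <- tidy(cm)
  pp <- sim$truth$planted_pairs
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  planted_keys <- key(pp$i, pp$j)
  tp$key <- key(tp$col_i, tp$col_j)
  planted_e <- tp$energy[tp$key %in% planted_keys]
  other_e <- tp$energy[!tp$key %in% planted_keys & tp$valid]
  expect_true(all(!is.na(planted_e)))
  # planted pairs rank above the 95th percentile of background couplings
  expect_true(all(planted_e > quantile(other_e, 0.95, na.rm = TRUE)))
})

test_that("sector extraction recovers planted blocks and handles cliques", {
  # block-diagonal: 3 planted blocks of strong coupling
  blocks <- rep(1:3, times = c(4, 5, 3))
  L <- length(blocks)
  m <- matrix(0.1, L, L)
  for (b in 1:3) m[blocks == b, blocks == b] <- 2.0
  cm <- as_sca_matrix(m)
  sec <- extract_sectors(cm, threshold = 1.0, k_sectors = 3)
  expect_equal(nrow(sec), L)
  # exact block recovery up to label permutation
  expect_equal(length(unique(paste(blocks, sec$sector))), 3L)
  expect_false(any(sec$co_sector))

  # a single fully-coupled clique collapses to one sector
  clique <- as_sca_matrix(matrix(1.5, 6, 6))
  expect_warning(extract_sectors(clique, k_sectors = 3), "one sector")
  sec1 <- suppressWarnings(extract_sectors(clique, k_sectors = 3))
  expect_equal(unique(sec1$sector), 1L)

  expect_error(extract_sectors(as_sca_matrix(matrix(2, 2, 2)), k_sectors = 3),
               "sector")
})
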