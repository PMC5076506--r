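#' Specification for a synthetic MSA with planted co-varying pairs
#'
#' The generator emulates a curated protein-family alignment: background
#' columns are i.i.d. draws from the background amino-acid frequencies (star
#' phylogeny, no phylogenetic correlation), and each planted column pair
#' follows a two-state compensatory scheme — with probability `epsilon` a
#' sequence draws one of the pair's two compatible residue combinations,
#' otherwise both columns are independent background draws. `epsilon = 0` is
#' full independence; `epsilon = 1` deterministic covariation. Optional
#' near-duplicate clusters and C-terminally truncated fragments stress-test
#' the curation stage.
#'
#' @param n_sequences,n_columns Alignment size (defaults 800 x 120).
#' @param background Amino-acid frequency vector of length 20 (default
#'   uniform).
#' @param planted_pairs Tibble with columns `i`, `j`, `epsilon`; pairs must be
#'   disjoint. Default: four pairs at mixing 0.8.
#' @param redundancy_clusters List with `count` and `within_identity`, or
#'   `NULL` (default) for none.
#' @param fragment_fraction Fraction of extra truncated-copy sequences to
#'   inject (default 0).
#' @param gap_rate Per-cell gap probability (default 0).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `msa_sim_spec`.
#' @export
msa_sim_spec <- function(n_sequences = 800L, n_columns = 120L,
                         background = NULL, planted_pairs = NULL,
                         redundancy_clusters = NULL, fragment_fraction = 0,
                         gap_rate = 0, seed = 1L) {
  background <- background %||% rep(1 / 20, 20)
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-8)
  # default: four planted pairs at fixed relative positions (for the default
  # 120-column alignment: (10,60), (25,90), (48,101), (77,112))
  planted_pairs <- planted_pairs %||%
    tibble(i = as.integer(round(n_columns * c(0.083, 0.208, 0.400, 0.642))),
           j = as.integer(round(n_columns * c(0.500, 0.750, 0.842, 0.933))),
           epsilon = 0.8)
  planted_pairs <- as_tibble(planted_pairs)
  cols <- c(planted_pairs$i, planted_pairs$j)
  if (nrow(planted_pairs) > 0) {
    if (anyDuplicated(cols)) abort("planted pairs must be disjoint")
    if (any(cols < 1 | cols > n_columns)) abort("planted pair out of range")
    if (any(planted_pairs$epsilon < 0 | planted_pairs$epsilon > 1)) {
      abort("epsilon must be in [0, 1]")
    }
  }
  structure(list(n_sequences = n_sequences, n_columns = n_columns,
                 background = background, planted_pairs = planted_pairs,
                 redundancy_clusters = redundancy_clusters,
                 fragment_fraction = fragment_fraction,
                 gap_rate = gap_rate, seed = as.integer(seed)),
            class = "msa_sim_spec")
}

#' Simulate an alignment with known ground truth
#'
#' @param spec An [msa_sim_spec()].
#' @return A list: `alignment` (an [aa_alignment()] of the base sequences),
#'   `sequences` (tibble incl. injected duplicates/fragments, for curation
#'   tests) and `truth` (planted pairs, duplicate/fragment ids).
#' @export
simulate_msa <- function(spec) {
  stopifnot(inherits(spec, "msa_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_sequences; L <- spec$n_columns
  enc <- matrix(sample.int(20L, n * L, replace = TRUE, prob = spec$background),
                nrow = n, ncol = L)
  pp <- spec$planted_pairs
  for (k in seq_len(nrow(pp))) {
    i <- pp$i[[k]]; j <- pp$j[[k]]; eps <- pp$epsilon[[k]]
    # two compatible residue combinations, fixed per pair
    combo <- matrix(sample.int(20L, 4L, replace = FALSE), nrow = 2)
    consistent <- stats::runif(n) < eps
    which_combo <- sample(1:2, n, replace = TRUE)
    enc[consistent, i] <- combo[which_combo[consistent], 1]
    enc[consistent, j] <- combo[which_combo[consistent], 2]
  }
  chars <- matrix(AA_ALPHABET[enc], nrow = n, ncol = L)
  if (spec$gap_rate > 0) {
    gaps <- matrix(stats::runif(n * L) < spec$gap_rate, n, L)
    chars[gaps] <- GAP_CHAR
  }
  base <- tibble(id = sprintf("seq%04d", seq_len(n)),
                 residues = apply(chars, 1, paste0, collapse = ""))
  seqs <- base
  dup_ids <- character(0)
  if (!is.null(spec$redundancy_clusters)) {
    rc <- spec$redundancy_clusters
    n_mut <- max(0L, round((1 - rc$within_identity) * L))
    for (c_idx in seq_len(rc$count)) {
      src <- base[c_idx, ]
      for (rep_idx in 1:2) {
        res <- strsplit(src$residues, "")[[1]]
        pos <- sample.int(L, n_mut)
        res[pos] <- AA_ALPHABET[sample.int(20L, n_mut, replace = TRUE)]
        id <- sprintf("%s_dup%d", src$id, rep_idx)
        seqs <- dplyr::bind_rows(seqs, tibble(id = id,
                                              residues = paste0(res, collapse = "")))
        dup_ids <- c(dup_ids, id)
      }
    }
  }
  frag_ids <- character(0)
  n_frag <- round(spec$fragment_fraction * n)
  if (n_frag > 0) {
    src_idx <- sample.int(n, n_frag)
    keep_len <- floor(L / 2)
    frags <- tibble(
      id = sprintf("%s_frag", base$id[src_idx]),
      residues = paste0(substr(base$residues[src_idx], 1, keep_len),
                        strrep(GAP_CHAR, L - keep_len)))
    seqs <- dplyr::bind_rows(seqs, frags)
    frag_ids <- frags$id
  }
  list(alignment = aa_alignment(base, ref_id = base$id[[1]]),
       sequences = seqs,
       truth = list(planted_pairs = pp, duplicate_ids = dup_ids,
                    fragment_ids = frag_ids, seed = spec$seed))
}

#' Specification for synthetic Michaelis-Menten titrations
#'
#' Defaults emulate a steady-state ATPase titration design: 12 substrate
#' concentrations log-spaced from 238 nM to 1 mM, triplicate measurements,
#' and Gaussian noise proportional to the true rate.
#'
#' @param mutants Tibble with columns `mutant`, `k_cat` (1/s), `K_m` (M).
#' @param conc_M Concentration grid in molar (default 12 log-spaced points,
#'   238e-9 to 1e-3).
#' @param noise_sd Relative (fractional) Gaussian noise s.d. (default 0.05).
#' @param replicates Replicates per concentration (default 3).
#' @param seed Integer seed.
#' @return A list of class `kinetic_sim_spec`.
#' @export
kinetic_sim_spec <- function(mutants, conc_M = NULL, noise_sd = 0.05,
                             replicates = 3L, seed = 1L) {
  mutants <- as_tibble(mutants)
  stopifnot(all(c("mutant", "k_cat", "K_m") %in% names(mutants)),
            all(mutants$k_cat > 0), all(mutants$K_m > 0))
  conc_M <- conc_M %||% 10^seq(log10(238e-9), log10(1e-3), length.out = 12)
  if (any(conc_M <= 0)) abort("concentration grid must be positive")
  structure(list(mutants = mutants, conc_M = conc_M, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "kinetic_sim_spec")
}

#' Simulate ATPase titrations
#'
#' Rates follow `k_cat * S / (K_m + S)` with additive Gaussian noise of s.d.
#' `noise_sd` times the true rate; reproducible under the spec seed.
#'
#' @param spec A [kinetic_sim_spec()].
#' @return Tibble: `mutant`, `conc_M`, `rate_per_s`, `replicate`.
#' @export
simulate_titrations <- function(spec) {
  stopifnot(inherits(spec, "kinetic_sim_spec"))
  set.seed(spec$seed)
  grid <- tidyr::crossing(mutant = spec$mutants$mutant,
                          conc_M = spec$conc_M,
                          replicate = seq_len(spec$replicates)) |>
    left_join(spec$mutants, by = "mutant") |>
    mutate(true_rate = .data$k_cat * .data$conc_M / (.data$K_m + .data$conc_M),
           rate_per_s = .data$true_rate *
             (1 + spec$noise_sd * stats::rnorm(dplyr::n()))) |>
    select("mutant", "conc_M", "rate_per_s", "replicate")
  grid
}

#' Simulate an ideal-geometry Calpha trace
#'
#' Geometries: `helix` — ideal alpha-helix (radius 2.3 A, rise 1.5 A and turn
#' 100 degrees per residue, i.e. Calpha(i)-Calpha(i+1) approximately 3.8 A);
#' `extended` — straight chain at 3.8 A spacing; `random-coil` — a seeded
#' self-avoiding-ish random walk with 3.8 A steps.
#'
#' @param n_residues Number of residues (>= 2).
#' @param motif `"helix"`, `"extended"` or `"random-coil"`.
#' @param seed Integer seed (used by `random-coil`).
#' @param start_resno Residue number of the first residue (default 1).
#' @return A `structure_model`.
#' @export
simulate_structure <- function(n_residues, motif = c("helix", "extended",
                                                     "random-coil"),
                               seed = 1L, start_resno = 1L) {
  motif <- match.arg(motif)
  if (n_residues < 2) abort("need at least two residues")
  idx <- seq_len(n_residues) - 1
  xyz <- switch(motif,
    helix = {
      radius <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
      cbind(radius * cos(idx * turn), radius * sin(idx * turn), rise * idx)
    },
    extended = cbind(3.8 * idx, 0 * idx, 0 * idx),
    `random-coil` = {
      set.seed(seed)
      steps <- matrix(stats::rnorm(3 * (n_residues - 1)), ncol = 3)
      steps <- 3.8 * steps / sqrt(rowSums(steps^2))
      rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    })
  new_structure_model_xyz(seq.int(start_resno, length.out = n_residues), xyz,
                          source_id = paste0("synthetic-", motif))
}
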