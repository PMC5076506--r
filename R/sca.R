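# Integer encoding of an alignment: 1..20 for the amino-acid alphabet,
# 0 for gaps and ambiguity characters (both excluded from frequency
# normalisation).
encode_alignment <- function(aln) {
  m <- match(aln$mat, AA_ALPHABET)
  m[is.na(m)] <- 0L
  matrix(m, nrow = nrow(aln$mat), ncol = ncol(aln$mat))
}

count_columns <- function(enc) {
  vapply(seq_len(ncol(enc)), function(j) tabulate(enc[, j], nbins = 20L),
         integer(20L))
}

# Pseudocount is applied in frequency space: P_x = (f_x + lambda) / (1 +
# 20 lambda). This keeps the regularisation comparable between the full
# alignment and a subalignment (a count-space pseudocount would add a
# spurious log(n_full / n_sub) to every unobserved residue, inflating the
# coupling noise floor).
pseudo_freq <- function(counts, n_eff, lambda) {
  (counts / n_eff + lambda) / (1 + 20 * lambda)
}

#' Background amino-acid frequencies of an alignment
#'
#' Family-wide frequencies pooled over all non-gap positions, regularised by
#' the same per-residue pseudocount used for column frequencies.
#'
#' @param aln An [aa_alignment()].
#' @param pseudocount Per-residue pseudocount; default `1 / n_sequences`.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
background_frequencies <- function(aln, pseudocount = NULL) {
  enc <- encode_alignment(aln)
  lambda <- pseudocount %||% (1 / nrow(enc))
  tot <- tabulate(enc[enc > 0L], nbins = 20L)
  q <- pseudo_freq(tot, sum(tot), lambda)
  stats::setNames(q, AA_ALPHABET)
}

#' Per-column amino-acid statistics
#'
#' @param aln An [aa_alignment()].
#' @param col Column index (1-based).
#' @param pseudocount Per-residue pseudocount; default `1 / n_sequences`.
#' @param background Optional background frequency vector; computed from the
#'   alignment when omitted.
#' @return A list of class `column_stats`: `counts` (named, raw), `n_effective`
#'   (non-gap rows), `frequencies` (raw `counts / n_effective`, summing to 1
#'   over the 20-letter alphabet; gaps excluded from normalisation),
#'   `probabilities` (pseudocount-regularised frequencies, used by the energy
#'   computations), `background`, and `gap_fraction`.
#' @export
column_statistics <- function(aln, col, pseudocount = NULL, background = NULL) {
  stopifnot(inherits(aln, "aa_alignment"))
  enc <- encode_alignment(aln)
  if (!(col >= 1 && col <= ncol(enc))) abort("`col` out of range")
  lambda <- pseudocount %||% (1 / nrow(enc))
  counts <- tabulate(enc[, col], nbins = 20L)
  n_eff <- sum(counts)
  if (n_eff == 0L) {
    warn(sprintf("column %d is all-gap; it is excluded from coupling", col))
  }
  q <- background %||% background_frequencies(aln, pseudocount = lambda)
  structure(list(
    counts = stats::setNames(counts, AA_ALPHABET),
    n_effective = n_eff,
    frequencies = stats::setNames(if (n_eff > 0) counts / n_eff else
      rep(NA_real_, 20), AA_ALPHABET),
    probabilities = stats::setNames(pseudo_freq(counts, n_eff, lambda),
                                    AA_ALPHABET),
    background = q,
    gap_fraction = 1 - n_eff / nrow(enc)
  ), class = "column_stats")
}

#' Statistical (conservation) energy of a column
#'
#' The departure of a column's amino-acid distribution from the family
#' background, in statistical energy units kT* (kT* = 1 by convention):
#' \deqn{\Delta G^{stat} = kT^* \sqrt{\sum_x \left[\ln(P_x / q_x)\right]^2}}
#' It is 0 exactly when the column frequencies equal the background and grows
#' as the distribution departs from it; a fully conserved rare residue scores
#' higher than a fully conserved common one.
#'
#' @param stats A `column_stats` object (or list with `probabilities` — or
#'   bare `frequencies` — and `background`).
#' @param kT Statistical energy unit (default 1).
#' @return Non-negative energy in kT*.
#' @export
conservation_energy <- function(stats, kT = 1) {
  if (!is.null(stats$n_effective) && stats$n_effective == 0) {
    abort("conservation energy undefined for an all-gap column")
  }
  p <- stats$probabilities %||% stats$frequencies
  kT * sqrt(sum(log(p / stats$background)^2))
}

# Perturbation admissibility: the dominant-residue subalignment at j must
# retain >= ceiling(min_sub_fraction * N) rows, and additionally >=
# min_sub_rows rows whenever the alignment itself has that many.
required_sub_rows <- function(n_rows, min_sub_fraction, min_sub_rows) {
  req <- ceiling(min_sub_fraction * n_rows)
  if (n_rows >= min_sub_rows) req <- max(req, min_sub_rows)
  max(req, 1L)
}

#' Statistical coupling energy between two columns
#'
#' Perturbation construction: restrict the alignment to the sequences carrying
#' the dominant (most frequent) residue at column `j` and measure how the
#' distribution at column `i` shifts,
#' \deqn{\Delta\Delta G^{stat}_{i|\delta j} =
#'   kT^* \sqrt{\sum_x \left[\ln(P_{x,i|\delta j} / P_{x,i})\right]^2}}
#' with all probabilities pseudocount-regularised observed frequencies. The
#' perturbation is admissible only if the subalignment is large enough (see
#' [sca_coupling()] for the rule); an inadmissible perturbation yields a
#' missing value, never 0.
#'
#' @param aln An [aa_alignment()].
#' @param i,j Column indices, `i != j`; the perturbation is applied at `j`.
#' @param pseudocount Per-residue pseudocount; default `1 / n_sequences`.
#' @param min_sub_fraction,min_sub_rows Admissibility rule (defaults 0.25
#'   and 100).
#' @param kT Statistical energy unit.
#' @return A list: `energy` (kT*, `NA` if inadmissible), `valid`, `n_sub`
#'   (subalignment rows), `perturbation` (dominant residue at `j`).
#' @export
coupling_energy <- function(aln, i, j, pseudocount = NULL,
                            min_sub_fraction = 0.25, min_sub_rows = 100L,
                            kT = 1) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (i == j) abort("`i` and `j` must differ")
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  lambda <- pseudocount %||% (1 / n)
  counts_j <- tabulate(enc[, j], nbins = 20L)
  if (sum(counts_j) == 0L) abort("perturbation column is all-gap")
  dom <- which.max(counts_j)
  rows <- enc[, j] == dom
  n_sub <- sum(rows)
  req <- required_sub_rows(n, min_sub_fraction, min_sub_rows)
  if (n_sub < req) {
    return(list(energy = NA_real_, valid = FALSE, n_sub = n_sub,
                perturbation = AA_ALPHABET[dom]))
  }
  counts_full <- tabulate(enc[, i], nbins = 20L)
  counts_sub <- tabulate(enc[rows, i], nbins = 20L)
  p_full <- pseudo_freq(counts_full, sum(counts_full), lambda)
  p_sub <- pseudo_freq(counts_sub, sum(counts_sub), lambda)
  list(energy = kT * sqrt(sum(log(p_sub / p_full)^2)), valid = TRUE,
       n_sub = n_sub, perturbation = AA_ALPHABET[dom])
}

#' Compute the full statistical coupling matrix
#'
#' Runs the perturbation of [coupling_energy()] at every admissible column and
#' assembles the symmetrised coupling matrix
#' `ddg[i, j] = mean(ddg(i | delta j), ddg(j | delta i))` over the admissible
#' directions (both raw directions are retained in `directional`). Columns
#' with more than `max_gap_fraction` gaps are excluded from the matrix.
#' A pair is `valid` when at least one direction is admissible; invalid pairs
#' are reported as missing, never 0.
#'
#' @param aln An [aa_alignment()].
#' @param pseudocount Per-residue pseudocount; default `1 / n_sequences`.
#' @param min_sub_fraction Minimum fraction of rows the dominant-residue
#'   subalignment must retain (default 0.25).
#' @param min_sub_rows Absolute row floor for the subalignment, applied when
#'   the alignment has at least that many rows (default 100).
#' @param max_gap_fraction Columns gappier than this are excluded (default 0.5).
#' @param kT Statistical energy unit (default 1).
#' @return An object of class `sca_matrix`: `ddg` (L x L symmetric, kT*),
#'   `dg` (per-column conservation energies), `valid` (logical L x L),
#'   `directional` (`directional[i, j]` = energy of i given perturbation at j),
#'   `included` (logical, per column), `column_map`, and `params`.
#' @examples
#' aln <- simulate_msa(msa_sim_spec(n_sequences = 200, n_columns = 20,
#'                                  seed = 1))$alignment
#' cm <- sca_coupling(aln, min_sub_rows = 5, min_sub_fraction = 0.02)
#' @export
sca_coupling <- function(aln, pseudocount = NULL, min_sub_fraction = 0.25,
                         min_sub_rows = 100L, max_gap_fraction = 0.5, kT = 1) {
  stopifnot(inherits(aln, "aa_alignment"))
  enc <- encode_alignment(aln)
  n <- nrow(enc); L <- ncol(enc)
  lambda <- pseudocount %||% (1 / n)
  counts <- count_columns(enc)            # 20 x L
  n_eff <- colSums(counts)
  included <- (1 - n_eff / n) <= max_gap_fraction & n_eff > 0L
  q <- background_frequencies(aln, pseudocount = lambda)

  p_full <- (sweep(counts, 2, pmax(n_eff, 1L), "/") + lambda) /
    (1 + 20 * lambda)                    # 20 x L
  dg <- kT * sqrt(colSums(log(p_full / q)^2))
  dg[!included] <- NA_real_

  req <- required_sub_rows(n, min_sub_fraction, min_sub_rows)
  directional <- matrix(NA_real_, L, L)   # [i, j] = ddg(i | delta j)
  for (j in which(included)) {
    dom <- which.max(counts[, j])
    rows <- enc[, j] == dom
    if (sum(rows) < req) next
    counts_sub <- count_columns(enc[rows, , drop = FALSE])
    p_sub <- (sweep(counts_sub, 2, pmax(colSums(counts_sub), 1L), "/") + lambda) /
      (1 + 20 * lambda)
    e <- kT * sqrt(colSums(log(p_sub / p_full)^2))
    e[!included] <- NA_real_
    e[j] <- NA_real_
    directional[, j] <- e
  }

  both <- array(c(directional, t(directional)), dim = c(L, L, 2))
  ddg <- apply(both, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  valid <- !is.na(ddg)
  diag(ddg) <- NA_real_
  diag(valid) <- FALSE

  structure(list(ddg = ddg, dg = dg, valid = valid, directional = directional,
                 included = included, column_map = aln$column_map,
                 params = list(pseudocount = lambda,
                               min_sub_fraction = min_sub_fraction,
                               min_sub_rows = min_sub_rows,
                               max_gap_fraction = max_gap_fraction, kT = kT)),
            class = "sca_matrix")
}

#' Wrap a bare coupling matrix as an `sca_matrix`
#'
#' For matrices computed elsewhere (or constructed in tests): the matrix is
#' symmetrised by averaging with its transpose, the diagonal is dropped, and
#' missing entries become invalid pairs.
#'
#' @param ddg Square numeric matrix of coupling energies (kT*).
#' @param dg Optional per-column conservation energies.
#' @param column_map Optional reference residue number per column (defaults
#'   to 1..L).
#' @return An `sca_matrix`.
#' @export
as_sca_matrix <- function(ddg, dg = NULL, column_map = NULL) {
  ddg <- as.matrix(ddg)
  stopifnot(nrow(ddg) == ncol(ddg))
  L <- ncol(ddg)
  ddg <- (ddg + t(ddg)) / 2
  diag(ddg) <- NA_real_
  valid <- !is.na(ddg)
  structure(list(ddg = ddg, dg = dg %||% rep(NA_real_, L), valid = valid,
                 directional = ddg, included = rep(TRUE, L),
                 column_map = column_map %||% seq_len(L),
                 params = list()),
            class = "sca_matrix")
}

#' Write a coupling matrix to TSV
#'
#' @param cm An `sca_matrix`.
#' @param path Output path; the symmetrised `ddg` matrix is written with
#'   reference positions as column names.
#' @return `path`, invisibly.
#' @export
write_sca_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "sca_matrix"))
  m <- cm$ddg
  colnames(m) <- cm$column_map
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sca_matrix <- function(x, ...) {
  L <- ncol(x$ddg)
  cat(sprintf("<sca_matrix> %d columns (%d included), %d valid pairs\n",
              L, sum(x$included), sum(x$valid[upper.tri(x$valid)])))
  invisible(x)
}

#' Long-format table of coupling pairs
#'
#' @param x An `sca_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per unordered column pair: `col_i`, `col_j`,
#'   reference positions (`pos_i`, `pos_j`, `NA` when unmapped), `energy`
#'   (kT*, `NA` when the pair is masked) and `valid`.
#' @export
tidy.sca_matrix <- function(x, ...) {
  L <- ncol(x$ddg)
  ut <- which(upper.tri(x$ddg), arr.ind = TRUE)
  tibble(col_i = ut[, 1], col_j = ut[, 2],
         pos_i = x$column_map[ut[, 1]], pos_j = x$column_map[ut[, 2]],
         energy = x$ddg[ut], valid = x$valid[ut])
}

#' Cluster supra-threshold positions into protein sectors
#'
#' Positions with at least one valid coupling at or above `threshold` are
#' clustered by average-linkage agglomeration on the distance
#' `1 - ddg / max(ddg)` (missing couplings treated as maximal distance) and
#' cut into `k_sectors` groups. A position is flagged `co_sector` when it has
#' a supra-threshold coupling into another sector (allosteric cross-talk).
#'
#' @param cm An `sca_matrix`.
#' @param threshold Coupling threshold in kT* (default 1.0).
#' @param k_sectors Number of sectors to cut (default 3).
#' @return Tibble: `column`, `position` (reference numbering), `sector`
#'   (integer label), `co_sector` (logical).
#' @export
extract_sectors <- function(cm, threshold = 1.0, k_sectors = 3L) {
  stopifnot(inherits(cm, "sca_matrix"))
  strong <- cm$valid & !is.na(cm$ddg) & cm$ddg >= threshold
  members <- which(rowSums(strong) > 0)
  if (length(members) < k_sectors) {
    abort(sprintf("only %d network positions; cannot cut %d sectors",
                  length(members), k_sectors))
  }
  sub <- cm$ddg[members, members, drop = FALSE]
  sub[is.na(sub)] <- 0
  d <- stats::as.dist(1 - sub / max(sub))
  hc <- stats::hclust(d, method = "average")
  if (max(hc$height) < 1e-12) {
    # fully coupled clique: all merge heights zero, no sector structure
    warn("couplings are indistinguishable; returning one sector")
    sector <- rep(1L, length(members))
  } else {
    sector <- stats::cutree(hc, k = k_sectors)
  }
  co <- vapply(seq_along(members), function(a) {
    partners <- which(strong[members[a], members])
    any(sector[partners] != sector[a])
  }, logical(1))
  tibble(column = members, position = cm$column_map[members],
         sector = as.integer(sector), co_sector = co)
}
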