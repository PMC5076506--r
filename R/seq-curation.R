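#' Fraction of identical residues between two sequences
#'
#' Two conventions are supported, switched by `aligned`:
#' \describe{
#'   \item{aligned}{sequences are rows of the same alignment; identity is the
#'     number of matching columns divided by the number of columns where
#'     neither sequence carries a gap.}
#'   \item{unaligned}{a global (Needleman-Wunsch) pairwise alignment is
#'     computed first; identity is matches divided by the alignment length
#'     (gapped columns included in the denominator).}
#' }
#' Comparison is case-insensitive; `X` and other ambiguity characters never
#' match anything, including themselves.
#'
#' @param a,b Amino-acid strings (optionally gapped when `aligned = TRUE`).
#' @param aligned If `NULL` (default), treated as aligned when both strings
#'   have equal length and either contains a gap, otherwise unaligned with
#'   equal-length inputs compared column-by-column.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 0.75
#' @export
pairwise_identity <- function(a, b, aligned = NULL) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L) {
    abort("`a` and `b` must be single character strings")
  }
  a <- normalize_residues(a); b <- normalize_residues(b)
  if (nchar(a) == 0L || nchar(b) == 0L) abort("sequences must be non-empty")
  if (is.null(aligned)) {
    aligned <- nchar(a) == nchar(b)
  }
  if (aligned && nchar(a) != nchar(b)) {
    abort("aligned comparison requires equal-length sequences")
  }
  if (aligned) {
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    keep <- ca != GAP_CHAR & cb != GAP_CHAR
    if (!any(keep)) return(0)
    match_ok <- ca == cb & ca %in% AA_ALPHABET
    sum(match_ok[keep]) / sum(keep)
  } else {
    # canonical argument order so the identity is exactly symmetric even when
    # the optimal global alignment is tie-broken differently per orientation
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(gsub(GAP_CHAR, "", a, fixed = TRUE)),
      Biostrings::AAString(gsub(GAP_CHAR, "", b, fixed = TRUE)),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    Biostrings::nmatch(pa) / Biostrings::nchar(pa)
  }
}

new_curation_report <- function(n_input, removed) {
  removed <- as_tibble(removed)
  structure(list(
    n_input = n_input,
    n_removed_unreferenced = sum(removed$reason == "unreferenced"),
    n_removed_fragment = sum(removed$reason == "fragment"),
    n_removed_redundant = sum(removed$reason == "redundant"),
    n_output = n_input - nrow(removed),
    removed = removed
  ), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf(paste0("<curation_report> %d in -> %d kept ",
                     "(%d unreferenced, %d fragment, %d redundant removed)\n"),
              x$n_input, x$n_output, x$n_removed_unreferenced,
              x$n_removed_fragment, x$n_removed_redundant))
  invisible(x)
}

merge_reports <- function(n_input, ...) {
  removed <- dplyr::bind_rows(lapply(list(...), function(r) r$removed))
  new_curation_report(n_input, removed)
}

#' Remove redundant sequences above an identity threshold
#'
#' Greedy, first-seen-kept pruning: sequences are scanned in input order and a
#' sequence is dropped when its identity to any already-kept sequence exceeds
#' `threshold`. The result is deterministic for a given input order and no
#' retained pair has identity above the threshold.
#'
#' @param seqs Tibble with `id` and `residues` columns.
#' @param threshold Identity above which a sequence is redundant (default
#'   0.95, i.e. identity greater than 95 percent removed).
#' @param aligned Passed to [pairwise_identity()].
#' @return A list with `kept` (tibble) and `report` (a `curation_report`).
#' @export
prune_redundant <- function(seqs, threshold = 0.95, aligned = NULL) {
  seqs <- as_tibble(seqs)
  if (nrow(seqs) < 1L) abort("need at least one sequence")
  if (!(threshold > 0 && threshold <= 1)) abort("`threshold` must be in (0, 1]")
  keep <- logical(nrow(seqs))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(seqs))) {
    redundant <- FALSE
    for (j in kept_idx) {
      if (pairwise_identity(seqs$residues[[i]], seqs$residues[[j]],
                            aligned = aligned) > threshold) {
        redundant <- TRUE
        break
      }
    }
    keep[[i]] <- !redundant
    if (!redundant) kept_idx <- c(kept_idx, i)
  }
  removed <- tibble(id = seqs$id[!keep],
                    reason = rep("redundant", sum(!keep)))
  list(kept = seqs[keep, , drop = FALSE],
       report = new_curation_report(nrow(seqs), removed))
}

#' Remove fragmentary sequences
#'
#' A sequence is a fragment when its ungapped length falls below
#' `min_fraction_of_median` times the median ungapped length of the input.
#'
#' @param seqs Tibble with `id` and `residues`.
#' @param min_fraction_of_median Length fraction below which a sequence is
#'   removed (default 0.7).
#' @return A list with `kept` and `report`, as in [prune_redundant()].
#' @export
filter_fragments <- function(seqs, min_fraction_of_median = 0.7) {
  seqs <- as_tibble(seqs)
  if (nrow(seqs) < 1L) abort("need at least one sequence")
  len <- nchar(gsub(GAP_CHAR, "", normalize_residues(seqs$residues), fixed = TRUE))
  cutoff <- min_fraction_of_median * stats::median(len)
  keep <- len >= cutoff
  removed <- tibble(id = seqs$id[!keep], reason = rep("fragment", sum(!keep)))
  list(kept = seqs[keep, , drop = FALSE],
       report = new_curation_report(nrow(seqs), removed))
}

#' Curate a raw sequence collection
#'
#' Applies, in order: removal of ids without a reference (only when the caller
#' supplies `referenced_ids`; there is no live database lookup, so by default
#' this filter is not applied), fragment removal, and redundancy pruning at
#' the identity threshold.
#'
#' @param seqs Tibble with `id`, `residues` and optionally `description`.
#' @param identity_threshold Redundancy threshold (default 0.95).
#' @param min_length_fraction Fragment threshold (default 0.7).
#' @param referenced_ids Optional character vector of ids with a valid
#'   publication/database cross-reference; ids absent from it are removed.
#' @param aligned Passed to [pairwise_identity()].
#' @return List with `kept` (tibble) and `report` (`curation_report`).
#' @export
curate_sequences <- function(seqs, identity_threshold = 0.95,
                             min_length_fraction = 0.7,
                             referenced_ids = NULL, aligned = NULL) {
  seqs <- as_tibble(seqs)
  n_input <- nrow(seqs)
  removed0 <- tibble(id = character(0), reason = character(0))
  if (!is.null(referenced_ids)) {
    drop <- !seqs$id %in% referenced_ids
    removed0 <- tibble(id = seqs$id[drop], reason = rep("unreferenced", sum(drop)))
    seqs <- seqs[!drop, , drop = FALSE]
  }
  frag <- filter_fragments(seqs, min_length_fraction)
  red <- prune_redundant(frag$kept, identity_threshold, aligned = aligned)
  removed <- dplyr::bind_rows(removed0, frag$report$removed, red$report$removed)
  list(kept = red$kept, report = new_curation_report(n_input, removed))
}

#' Write a curation report to JSON and/or TSV
#'
#' @param report A `curation_report`.
#' @param json,tsv Optional output paths.
#' @return The report, invisibly.
#' @export
write_curation_report <- function(report, json = NULL, tsv = NULL) {
  stopifnot(inherits(report, "curation_report"))
  if (!is.null(json)) {
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv)) {
    utils::write.table(report$removed, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}

#' Tidy and summarise curation reports
#'
#' `tidy()` returns the per-sequence removal table; `glance()` the one-row
#' count summary (counts always reconcile: `n_input` equals `n_output` plus
#' the removals).
#'
#' @param x A `curation_report`.
#' @param ... Unused.
#' @return A tibble.
#' @rdname curation_report_tidiers
#' @export
tidy.curation_report <- function(x, ...) x$removed

#' @rdname curation_report_tidiers
#' @export
glance.curation_report <- function(x, ...) {
  tibble(n_input = x$n_input,
         n_removed_unreferenced = x$n_removed_unreferenced,
         n_removed_fragment = x$n_removed_fragment,
         n_removed_redundant = x$n_removed_redundant,
         n_output = x$n_output)
}
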