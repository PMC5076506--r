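#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# 20-letter amino-acid alphabet; '-' is the only gap character after
# normalisation ('.' and gaps of either case are folded into it).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHAR <- "-"

normalize_residues <- function(x) {
  x <- toupper(x)
  gsub("[.~ ]", GAP_CHAR, x)
}

#' Construct an amino-acid alignment
#'
#' Bundles equal-length aligned sequences with an optional reference row that
#' defines residue numbering for every column (e.g. human Eg5 numbering when
#' the Eg5 sequence is the designated reference). Columns where the reference
#' carries a gap receive no number and are reported as `NA` in `column_map`.
#'
#' @param seqs A tibble/data frame with columns `id` and `residues` (aligned,
#'   equal length, 20-letter alphabet plus `-`), or a named character vector.
#' @param ref_id Optional id of the reference row used for residue numbering.
#' @param ref_start Residue number of the first non-gap reference position
#'   (default 1).
#' @return An object of class `aa_alignment`: a list with `ids`, `mat`
#'   (n x L character matrix), `column_map` (integer, length L) and `ref_id`.
#' @examples
#' aln <- aa_alignment(c(s1 = "AC-D", s2 = "ACAD"), ref_id = "s1")
#' aln$column_map  # 1 2 NA 3
#' @export
aa_alignment <- function(seqs, ref_id = NULL, ref_start = 1L) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) abort("character input must be named by sequence id")
    seqs <- tibble(id = names(seqs), residues = unname(seqs))
  }
  seqs <- as_tibble(seqs)
  if (!all(c("id", "residues") %in% names(seqs))) {
    abort("`seqs` needs columns `id` and `residues`")
  }
  if (nrow(seqs) == 0L) abort("alignment needs at least one sequence")
  if (anyDuplicated(seqs$id)) abort("sequence ids must be unique")
  res <- normalize_residues(seqs$residues)
  lens <- nchar(res)
  if (length(unique(lens)) != 1L) abort("aligned sequences must have equal length")
  L <- lens[[1]]
  if (L == 0L) abort("sequences must be non-empty")
  mat <- matrix(unlist(strsplit(res, "", fixed = TRUE), use.names = FALSE),
                nrow = nrow(seqs), ncol = L, byrow = TRUE,
                dimnames = list(seqs$id, NULL))
  bad <- setdiff(unique(as.vector(mat)), c(AA_ALPHABET, GAP_CHAR, "X", "B", "Z", "J", "U", "O", "*"))
  if (length(bad) > 0L) {
    abort(paste0("unexpected characters in alignment: ", paste(bad, collapse = " ")))
  }
  column_map <- rep(NA_integer_, L)
  if (!is.null(ref_id)) {
    if (!ref_id %in% seqs$id) abort(paste0("reference id not in alignment: ", ref_id))
    ref_row <- mat[ref_id, ]
    nongap <- ref_row != GAP_CHAR
    column_map[nongap] <- seq.int(ref_start, length.out = sum(nongap))
  }
  structure(list(ids = seqs$id, mat = mat, column_map = column_map,
                 ref_id = ref_id),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d sequences x %d columns", nrow(x$mat), ncol(x$mat)))
  if (!is.null(x$ref_id)) cat(sprintf(", reference: %s", x$ref_id))
  cat("\n")
  invisible(x)
}

#' @export
dim.aa_alignment <- function(x) dim(x$mat)

#' Look up alignment columns for reference residue numbers
#'
#' @param aln An [aa_alignment()].
#' @param positions Integer vector of reference residue numbers.
#' @return Integer vector of column indices; errors if any position is not
#'   mapped by the reference row.
#' @export
columns_for_positions <- function(aln, positions) {
  stopifnot(inherits(aln, "aa_alignment"))
  idx <- match(as.integer(positions), aln$column_map)
  if (anyNA(idx)) {
    abort(paste0("positions not mapped in the alignment: ",
                 paste(positions[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a plain or aligned FASTA file.
#' @return A tibble with columns `id` (first token of the header),
#'   `description` (remainder of the header) and `residues`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  tibble(id = id, description = desc,
         residues = unname(normalize_residues(as.character(set))))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with `id`, `residues` and optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_tibble(seqs)
  hdr <- seqs$id
  if ("description" %in% names(seqs)) {
    hdr <- ifelse(nzchar(seqs$description), paste(seqs$id, seqs$description), seqs$id)
  }
  writeLines(paste0(">", hdr, "\n", seqs$residues), path)
  invisible(path)
}

#' Read a multiple sequence alignment (FASTA or Stockholm)
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @param ref_id,ref_start Passed to [aa_alignment()].
#' @return An [aa_alignment()].
#' @export
read_msa <- function(path, format = c("fasta", "stockholm"), ref_id = NULL,
                     ref_start = 1L) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- read_fasta(path)
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- tibble(id = rownames(msa),
                   residues = normalize_residues(as.character(msa)))
  }
  aa_alignment(seqs, ref_id = ref_id, ref_start = ref_start)
}
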