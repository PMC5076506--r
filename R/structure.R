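new_structure_model <- function(coords, source_id = NA_character_) {
  coords <- as_tibble(coords)
  stopifnot(all(c("resno", "x", "y", "z") %in% names(coords)))
  if (anyDuplicated(coords$resno)) abort("one Calpha per residue is required")
  if (!all(is.finite(c(coords$x, coords$y, coords$z)))) {
    abort("coordinates must be finite")
  }
  structure(list(coords = coords[order(coords$resno), ],
                 source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d Calpha residues (source: %s)\n",
              nrow(x$coords), x$source_id))
  invisible(x)
}

#' Read Calpha coordinates from a PDB file
#'
#' Keeps the Calpha trace of a single chain of the first model, preferring
#' altloc 'A' where alternates exist. Residue numbers may be shifted by
#' `offset` so that structures numbered differently from the reference
#' sequence (e.g. human Eg5 numbering) line up with network positions.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier (default `"A"`).
#' @param offset Added to PDB residue numbers (default 0).
#' @return A `structure_model`: tibble of `resno`, `x`, `y`, `z` (angstrom)
#'   plus the source id. Unresolved residues are simply absent and show up as
#'   missing when queried.
#' @export
read_ca_structure <- function(path, chain = "A", offset = 0L) {
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  sel <- at$elety == "CA" & at$chain == chain & at$type == "ATOM" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[sel, , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  if (nrow(at) == 0L) abort(paste0("no Calpha atoms for chain ", chain))
  new_structure_model(
    tibble(resno = at$resno + as.integer(offset),
           x = at$x, y = at$y, z = at$z),
    source_id = basename(path))
}

#' Is a residue resolved in the model?
#'
#' @param model A `structure_model`.
#' @param resno Residue number(s).
#' @return Logical vector.
#' @export
is_resolved <- function(model, resno) {
  stopifnot(inherits(model, "structure_model"))
  resno %in% model$coords$resno
}

#' Calpha-Calpha distance between two residues
#'
#' @param model A `structure_model`.
#' @param i,j Residue numbers (reference numbering).
#' @return Euclidean distance in angstrom; `NA_real_` with attribute
#'   `unresolved` naming the missing residue(s) when either endpoint is not
#'   in the model.
#' @examples
#' m <- new_structure_model_xyz(c(1, 2), matrix(c(0, 0, 0, 3, 4, 0),
#'                                              ncol = 3, byrow = TRUE))
#' ca_distance(m, 1, 2)  # 5
#' @export
ca_distance <- function(model, i, j) {
  stopifnot(inherits(model, "structure_model"))
  missing <- c(i, j)[!is_resolved(model, c(i, j))]
  if (length(missing) > 0L) {
    out <- NA_real_
    attr(out, "unresolved") <- unique(missing)
    return(out)
  }
  a <- as.numeric(model$coords[match(i, model$coords$resno), c("x", "y", "z")])
  b <- as.numeric(model$coords[match(j, model$coords$resno), c("x", "y", "z")])
  sqrt(sum((a - b)^2))
}

#' Bare constructor from residue numbers and an xyz matrix
#'
#' @param resno Integer vector of residue numbers.
#' @param xyz Numeric matrix with one row per residue and columns x, y, z.
#' @param source_id Label for the model origin.
#' @return A `structure_model`.
#' @export
new_structure_model_xyz <- function(resno, xyz, source_id = "synthetic") {
  xyz <- matrix(xyz, ncol = 3)
  new_structure_model(tibble(resno = as.integer(resno),
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                      source_id = source_id)
}

#' Contact / distal classification of an inter-residue distance
#'
#' Residues are in tertiary-structure contact when their Calpha-Calpha
#' distance is below 6 angstrom; pairs at 6 angstrom or more are distal.
#'
#' @param d Distance(s) in angstrom, >= 0.
#' @param contact_cut Contact threshold (default 6).
#' @return Character vector, `"contact"` or `"distal"`.
#' @examples
#' classify_pair(c(5.9, 6, 30))  # contact distal distal
#' @export
classify_pair <- function(d, contact_cut = 6) {
  if (any(d < 0, na.rm = TRUE)) abort("distances must be non-negative")
  ifelse(d < contact_cut, "contact", "distal")
}

#' Distance table for network edges on a structure
#'
#' @param net An `allostery_network` with mapped positions.
#' @param model A `structure_model`.
#' @param contact_cut Contact threshold in angstrom (default 6).
#' @return Tibble: edge endpoints, `energy`, `stratum`, `d_ij` (`NA` when an
#'   endpoint is unresolved) and `class`.
#' @export
edge_distances <- function(net, model, contact_cut = 6) {
  stopifnot(inherits(net, "allostery_network"), inherits(model, "structure_model"))
  edges <- net$edges
  if (anyNA(edges$pos_i) || anyNA(edges$pos_j)) {
    abort("network edges must carry mapped reference positions")
  }
  d <- purrr::map2_dbl(edges$pos_i, edges$pos_j,
                       function(a, b) as.numeric(ca_distance(model, a, b)))
  edges |>
    mutate(d_ij = d,
           class = ifelse(is.na(d), NA_character_, classify_pair(d, contact_cut)))
}

#' Stratified histogram of Calpha-Calpha distances between coupled pairs
#'
#' Bins the inter-residue distances of network edges into `n_bins` half-open
#' bins `[lo, hi)` of width `bin_width` starting at `start`, split by coupling
#' stratum, and reports the distal fraction. Edges with an unresolved endpoint
#' are excluded from the histogram but counted in `n_excluded`.
#'
#' @param net An `allostery_network`.
#' @param model A `structure_model`.
#' @param bin_width Bin width in angstrom (default 4).
#' @param n_bins Number of bins (default 10).
#' @param start Lower edge of the first bin (default 4).
#' @param contact_cut Contact threshold (default 6).
#' @return A list: `histogram` (tibble `stratum`, `bin_lo`, `bin_hi`, `count`),
#'   `distal_fraction`, `n_classified`, `n_excluded`, and `distances` (the
#'   per-edge table from [edge_distances()]).
#' @export
distance_histogram <- function(net, model, bin_width = 4, n_bins = 10,
                               start = 4, contact_cut = 6) {
  tab <- edge_distances(net, model, contact_cut)
  classified <- filter(tab, !is.na(.data$d_ij))
  if (nrow(classified) == 0L) abort("no edge has both endpoints resolved")
  # nominal half-open bins [lo, hi); the first and last bins absorb distances
  # below `start` / beyond the nominal range so that counts conserve edges
  bin_lo <- start + bin_width * (seq_len(n_bins) - 1)
  bin_hi <- bin_lo + bin_width
  breaks <- c(0, bin_lo[-1], Inf)
  hist <- classified |>
    mutate(bin = cut(.data$d_ij, breaks = breaks, right = FALSE,
                     labels = FALSE, include.lowest = TRUE)) |>
    count(.data$stratum, .data$bin, name = "count") |>
    mutate(bin_lo = bin_lo[.data$bin], bin_hi = bin_hi[.data$bin]) |>
    select("stratum", "bin_lo", "bin_hi", "count")
  list(histogram = hist,
       distal_fraction = mean(classified$class == "distal"),
       n_classified = nrow(classified),
       n_excluded = nrow(tab) - nrow(classified),
       distances = tab)
}
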