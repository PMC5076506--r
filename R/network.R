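#' Build the thresholded residue-coupling network
#'
#' Nodes are alignment positions with at least one valid coupling at or above
#' `threshold`; edges are the supra-threshold pairs. Edge energies are
#' stratified into `intermediate` (1.0 <= kT* < 1.4) and `high` (>= 1.4 kT*);
#' the printed strata bounds (1-1.39 / 1.4-2.4) are treated as rounded bin
#' edges of the half-open intervals.
#'
#' @param cm An `sca_matrix`.
#' @param threshold Coupling threshold in kT* (default 1.0).
#' @param high_cut Lower edge of the high stratum (default 1.4).
#' @param sectors Optional sector table from [extract_sectors()] to join onto
#'   the nodes.
#' @return An object of class `allostery_network`: tibbles `nodes` (`column`,
#'   `position`, `degree`, `hub`, optional `sector`) and `edges` (`col_i`,
#'   `col_j`, `pos_i`, `pos_j`, `energy`, `stratum`), plus `threshold`.
#'   An empty network (no supra-threshold pair) is valid and warned about.
#' @export
build_network <- function(cm, threshold = 1.0, high_cut = 1.4, sectors = NULL) {
  stopifnot(inherits(cm, "sca_matrix"))
  pairs <- tidy.sca_matrix(cm)
  edges <- pairs |>
    filter(.data$valid, !is.na(.data$energy), .data$energy >= threshold) |>
    mutate(stratum = ifelse(.data$energy >= high_cut, "high", "intermediate")) |>
    select("col_i", "col_j", "pos_i", "pos_j", "energy", "stratum")
  if (nrow(edges) == 0L) {
    warn("no coupling at or above threshold; network is empty")
    nodes <- tibble(column = integer(0), position = integer(0),
                    degree = integer(0), hub = logical(0))
  } else {
    nodes <- tibble(column = c(edges$col_i, edges$col_j)) |>
      count(.data$column, name = "degree") |>
      mutate(position = cm$column_map[.data$column], hub = FALSE) |>
      select("column", "position", "degree", "hub") |>
      arrange(.data$column)
  }
  if (!is.null(sectors)) {
    nodes <- left_join(nodes, select(sectors, "column", "sector", "co_sector"),
                       by = "column")
  }
  net <- structure(list(nodes = nodes, edges = edges, threshold = threshold,
                        high_cut = high_cut),
                   class = "allostery_network")
  net$nodes$hub <- net$nodes$degree >= 9L
  net
}

#' @export
print.allostery_network <- function(x, ...) {
  cat(sprintf("<allostery_network> %d nodes, %d edges (threshold %.2f kT*), %d hubs\n",
              nrow(x$nodes), nrow(x$edges), x$threshold, sum(x$nodes$hub)))
  invisible(x)
}

#' Hub residues of a coupling network
#'
#' Hubs are positions statistically coupled to at least `min_degree` other
#' positions (default 9, the field's hub definition).
#'
#' @param net An `allostery_network`.
#' @param min_degree Minimum correlation count for hub status (default 9).
#' @return Tibble of hub nodes; the network's `nodes$hub` flag is recomputed
#'   against `min_degree` in the returned attribute `network`.
#' @export
classify_hubs <- function(net, min_degree = 9L) {
  stopifnot(inherits(net, "allostery_network"))
  net$nodes$hub <- net$nodes$degree >= min_degree
  hubs <- filter(net$nodes, .data$hub)
  attr(hubs, "network") <- net
  hubs
}

#' Histogram of correlation counts per network residue
#'
#' @param net An `allostery_network`.
#' @param max_degree Upper degree covered by the binning (default 17).
#' @return A list: `histogram` (tibble `degree`, `count`, one bin per integer
#'   degree from 1 to `max(max_degree, observed)`) and `mode` (most frequent
#'   degree). Counts sum to the node count.
#' @export
degree_histogram <- function(net, max_degree = 17L) {
  stopifnot(inherits(net, "allostery_network"))
  degs <- net$nodes$degree
  top <- max(max_degree, degs, 1L)
  hist <- tibble(degree = seq_len(top),
                 count = vapply(seq_len(top), function(d) sum(degs == d),
                                integer(1)))
  mode_deg <- if (length(degs)) hist$degree[which.max(hist$count)] else NA_integer_
  list(histogram = hist, mode = mode_deg)
}

#' Amino-acid divergence between two sequences at network positions
#'
#' Compares the aligned residues of two alignment rows at a set of reference
#' positions (alignment columns, not structural superposition). A gap against
#' a residue counts as divergent and is flagged.
#'
#' @param aln An [aa_alignment()] whose reference row defines `positions`.
#' @param id_a,id_b Sequence ids present in the alignment.
#' @param positions Reference residue numbers (e.g. the network node
#'   positions); an unmapped position is an error naming it.
#' @return A list: `n_divergent` and `table` (tibble `position`, `residue_a`,
#'   `residue_b`, `divergent`, `gap`).
#' @export
divergence_at_positions <- function(aln, id_a, id_b, positions) {
  stopifnot(inherits(aln, "aa_alignment"))
  for (id in c(id_a, id_b)) {
    if (!id %in% aln$ids) abort(paste0("sequence id not in alignment: ", id))
  }
  cols <- columns_for_positions(aln, positions)
  ra <- aln$mat[id_a, cols]
  rb <- aln$mat[id_b, cols]
  gap <- ra == GAP_CHAR | rb == GAP_CHAR
  divergent <- ra != rb
  tab <- tibble(position = as.integer(positions), residue_a = ra,
                residue_b = rb, divergent = divergent, gap = gap)
  list(n_divergent = sum(divergent), table = tab)
}

#' Write network tables to disk
#'
#' @param net An `allostery_network`.
#' @param edges_tsv,nodes_csv Optional output paths.
#' @return The network, invisibly.
#' @export
write_network <- function(net, edges_tsv = NULL, nodes_csv = NULL) {
  stopifnot(inherits(net, "allostery_network"))
  if (!is.null(edges_tsv)) {
    utils::write.table(net$edges, edges_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(nodes_csv)) {
    utils::write.csv(net$nodes, nodes_csv, row.names = FALSE)
  }
  invisible(net)
}
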