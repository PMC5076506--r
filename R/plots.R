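#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_point
#'   geom_line geom_abline geom_histogram labs scale_fill_viridis_c
#'   scale_x_log10 theme_minimal facet_wrap
NULL

#' Heat map of a statistical coupling matrix
#'
#' @param object An `sca_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sca_matrix <- function(object, ...) {
  L <- ncol(object$ddg)
  df <- tidyr::expand_grid(col_i = seq_len(L), col_j = seq_len(L)) |>
    mutate(energy = object$ddg[cbind(.data$col_i, .data$col_j)])
  ggplot(df, aes(.data$col_j, .data$col_i, fill = .data$energy)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(x = "column j", y = "column i", fill = "kT*",
         title = "Statistical coupling energies") +
    theme_minimal()
}

#' Bar graph of correlation counts per network residue
#'
#' @param object An `allostery_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.allostery_network <- function(object, ...) {
  dh <- degree_histogram(object)
  ggplot(dh$histogram, aes(.data$degree, .data$count)) +
    geom_col(fill = "grey30") +
    labs(x = "correlations per residue", y = "number of residues",
         title = sprintf("Degree distribution (mode = %s)", dh$mode)) +
    theme_minimal()
}

#' Michaelis-Menten titration with fitted curve
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(conc_M = 10^seq(log10(min(object$data$conc_M)),
                                 log10(max(object$data$conc_M)),
                                 length.out = 200)) |>
    mutate(rate_per_s = object$k_cat * .data$conc_M / (object$K_m + .data$conc_M))
  ggplot(object$data, aes(.data$conc_M, .data$rate_per_s)) +
    geom_point() +
    geom_line(data = grid, colour = "firebrick") +
    scale_x_log10() +
    labs(x = "[ATP] (M)", y = "rate (1/s)",
         title = sprintf("k_cat = %.3g /s, K_m = %.3g M",
                         object$k_cat, object$K_m)) +
    theme_minimal()
}

#' Stratified histogram of coupled-pair Calpha distances
#'
#' @param dh Result of [distance_histogram()].
#' @return A ggplot.
#' @export
plot_distance_histogram <- function(dh) {
  ggplot(dh$histogram,
         aes((.data$bin_lo + .data$bin_hi) / 2, .data$count,
             fill = .data$stratum)) +
    geom_col(position = "stack", width = diff(range(dh$histogram$bin_lo)) /
               max(1, nrow(dh$histogram))) +
    labs(x = expression(C[alpha] - C[alpha] ~ distance ~ (ring(A))),
         y = "coupled pairs", fill = "coupling",
         title = sprintf("%.0f%% of coupled pairs are distal",
                         100 * dh$distal_fraction)) +
    theme_minimal()
}

#' Additivity plot for double-mutant cycles
#'
#' Plots the double-mutant free-energy change against the summed single-mutant
#' changes; the dashed line is perfect additivity and the solid line the
#' fitted slope-1 offset.
#'
#' @param cycles Cycle table with `ddg_m1`, `ddg_m2`, `ddg_m1m2`.
#' @return A ggplot.
#' @export
plot_additivity <- function(cycles) {
  cycles <- as_tibble(cycles)
  off <- additivity_offset(cycles)
  df <- mutate(cycles, s = .data$ddg_m1 + .data$ddg_m2)
  ggplot(df, aes(.data$ddg_m1m2, .data$s)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    geom_abline(slope = 1, intercept = off$offset, colour = "firebrick") +
    geom_point(size = 2) +
    labs(x = expression(Delta * Delta * G[M1M2] ~ (kcal/mol)),
         y = expression(Delta * Delta * G[M1] + Delta * Delta * G[M2] ~ (kcal/mol)),
         title = sprintf("additivity offset = %.2f kcal/mol", off$offset)) +
    theme_minimal()
}
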