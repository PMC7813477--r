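# ggplot2 display methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_tile scale_fill_viridis_c scale_fill_gradient2 labs theme_minimal
#' @export
ggplot2::autoplot

#' @export
autoplot.thermogram <- function(object, ...) {
  ggplot(object, aes(x = .data$T_K, y = .data$Cp_kJ)) +
    geom_line(linewidth = 0.4) +
    labs(x = "temperature (K)", y = expression(C[p] ~ "(kJ mol"^-1 * " K"^-1 * ")")) +
    theme_minimal()
}

#' @export
autoplot.fe_profile <- function(object, ...) {
  mins <- attr(object, "minima")
  ggplot(object, aes(x = .data$n, y = .data$F_kJ)) +
    geom_line(na.rm = TRUE) +
    geom_point(data = mins, aes(x = .data$n, y = .data$F_kJ),
               color = "red3", size = 2) +
    labs(x = "structured blocks", y = expression(Delta * G ~ "(kJ mol"^-1 * ")"),
         title = sprintf("free-energy profile, T = %.0f K", attr(object, "T"))) +
    theme_minimal()
}

#' @export
autoplot.fe_surface <- function(object, ...) {
  ggplot(object, aes(x = .data$n_nterm, y = .data$n_cterm, fill = .data$F_kJ)) +
    geom_raster(na.rm = TRUE) +
    scale_fill_viridis_c(name = expression(Delta * G ~ "(kJ mol"^-1 * ")"),
                         na.value = "white") +
    labs(x = "structured blocks, N-terminal half",
         y = "structured blocks, C-terminal half") +
    theme_minimal()
}

#' @export
autoplot.pulling_trajectory <- function(object, ...) {
  ggplot(object, aes(x = .data$ext_nm, y = .data$force_pN)) +
    geom_line(linewidth = 0.2, alpha = 0.8) +
    labs(x = "end-to-end distance (nm)", y = "force (pN)") +
    theme_minimal()
}

#' @export
autoplot.circ_corr_map <- function(object, what = c("filtered", "r", "z"), ...) {
  what <- match.arg(what)
  m <- object[[what]]
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue3", mid = "white", high = "red3",
                         na.value = "grey95", name = what) +
    labs(x = "dihedral", y = "dihedral") +
    theme_minimal()
}

#' Scatter of rupture forces vs contour-length gains by pathway
#'
#' @param events A classified event table (see [classify_pathway()]).
#' @return A ggplot.
#' @export
plot_pathway_scatter <- function(events) {
  ggplot(events, aes(x = .data$dLc_nm, y = .data$F_kcal,
                     color = .data$pathway)) +
    geom_point(na.rm = TRUE) +
    labs(x = expression(Delta * L[c] ~ "(nm)"),
         y = expression(F[u] ~ "(kcal mol"^-1 * " A"^-1 * ")")) +
    theme_minimal()
}
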