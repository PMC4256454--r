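# ggplot2 views of the result types: residue-distance time series (the
# binding progression view), contact-frequency heat maps, PMF profiles
# with error ribbons, and a top view of the membrane domain layout.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-residue membrane-surface distances over time
#'
#' @param object A `distance_profile` from [residue_surface_distances()].
#' @param residues Optional residue subset.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_profile <- function(object, residues = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(residues)) d <- dplyr::filter(d, .data$resid %in% residues)
  d$label <- paste0(d$resname, d$resid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$distance,
                                  colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$molecule)) +
    ggplot2::labs(x = "time (ns)", y = "distance to membrane surface (nm)",
                  colour = "residue") +
    ggplot2::theme_minimal()
}

#' Heat map of a contact-frequency matrix
#'
#' @param object A `contact_frequency` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_frequency <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$resid_i, y = .data$resid_j,
                                  fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue",
                  fill = "contact (%)") +
    ggplot2::theme_minimal()
}

#' Plot a PMF profile with bootstrap error ribbon
#'
#' @param object A `pmf_profile` from [wham()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$pmf))
  if ("se" %in% names(d)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$pmf - .data$se,
                   ymax = .data$pmf + .data$se),
      fill = "steelblue", alpha = 0.3)
  }
  p + ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "z, peptide-membrane COM separation (nm)",
                  y = "PMF (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' Top view of a membrane model's domain layout
#'
#' @param model A `membrane_model` from [build_membrane()].
#' @param leaflet Leaflet to draw.
#' @return A ggplot of lipid anchor positions coloured by species.
#' @export
plot_membrane_top <- function(model, leaflet = "upper") {
  d <- dplyr::filter(tibble::as_tibble(model),
                     .data$leaflet == !!leaflet,
                     .data$name %in% c("PO4", "ROH"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$species,
                                  shape = .data$domain)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
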