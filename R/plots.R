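# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot incompressibility fields
#'
#' Scatter of the out-of-plane deformation `2*H*vn` against the covariant
#' in-plane divergence over all patches; the identity line marks perfect
#' incompressibility.
#'
#' @param object a `kinematic_fields` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.kinematic_fields <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = div, y = oop)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = area), alpha = 0.3, show.legend = FALSE) +
    ggplot2::labs(
      x = expression(nabla %.% v["∥"] ~ (min^-1)),
      y = expression(2 * H * v[n] ~ (min^-1)),
      title = "Out-of-plane deformation vs in-plane divergence"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a shear kymograph
#'
#' Tile map of the circumferentially averaged `|mu|` over material AP
#' position and time.
#'
#' @param object a `shear_kymograph` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.shear_kymograph <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = t, y = s_mid, fill = mod_mu)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression("|" * mu * "|")) +
    ggplot2::labs(x = "time (min)", y = "material AP position (µm)",
                  title = "Tissue shear kymograph") +
    ggplot2::theme_minimal()
}

#' Plot a calcium activity kymograph
#'
#' @param object an `activity_kymograph` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.activity_kymograph <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = t_min, y = ap_um, fill = mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "activity") +
    ggplot2::labs(x = "time from onset (min)", y = "AP position (µm)",
                  title = "GCaMP transient activity") +
    ggplot2::theme_minimal()
}

#' Plot cell shape records
#'
#' Cell aspect ratio against AP position, point size by area.
#'
#' @param records a `cell_shape_records` tibble.
#' @return a ggplot.
#' @export
plot_cell_aspects <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = s, y = aspect)) +
    ggplot2::geom_point(ggplot2::aes(size = area), alpha = 0.4, show.legend = FALSE) +
    ggplot2::geom_smooth(formula = y ~ x, method = "loess", se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "AP position s (µm)", y = "aspect ratio a/b",
                  title = "Cell anisotropy along the organ") +
    ggplot2::theme_minimal()
}

#' Plot nuclei pair separation over time
#'
#' @param pm a `pair_motion` result.
#' @return a ggplot.
#' @export
plot_pair_separation <- function(pm) {
  ggplot2::ggplot(pm$summary, ggplot2::aes(x = time, y = mean_sep)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_sep - sd_sep,
                                      ymax = mean_sep + sd_sep),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "pair separation (µm)",
                  title = sprintf("Muscle-endoderm pair separation (%.1f µm/h)",
                                  pm$rate_um_per_h)) +
    ggplot2::theme_minimal()
}
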