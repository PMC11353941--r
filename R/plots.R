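#' Plot a solvation decomposition
#'
#' Bar chart of the cavity and attraction free-energy contributions per
#' solvent, with the total Ben-Naim solvation free energy overlaid as a
#' point.
#'
#' @param object A `vdw_solvation` tibble from [solvate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vdw_solvation <- function(object, ...) {
  d <- tidy.vdw_solvation(object)
  bars <- d[d$term %in% c("dG_c", "dG_a"), ]
  tot <- d[d$term == "dG_star", ]
  ggplot2::ggplot(bars, ggplot2::aes(x = .data$name, y = .data$estimate,
                                     fill = .data$term)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_point(data = tot, ggplot2::aes(fill = NULL),
                        shape = 21, fill = "white") +
    ggplot2::labs(x = NULL, y = expression(Delta * G ~ "(kJ" ~ mol^-1 * ")"),
                  fill = NULL,
                  title = "Solvation free energy decomposition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a temperature scan
#'
#' Cavity free energy, enthalpy and `T * dS_c` against temperature, one
#' panel per solvent, showing the compensation structure: `dG_c` varies
#' weakly while `dH_c` and `T dS_c` move together.
#'
#' @param object A `vdw_scan` tibble from [temperature_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vdw_scan <- function(object, ...) {
  d <- as_tibble(object)
  d$TdS_c <- d$T * d$dS_c / 1e3
  long <- tidyr::pivot_longer(d[c("name", "T", "dG_c", "dH_c", "TdS_c")],
                              c("dG_c", "dH_c", "TdS_c"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$T, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "T (K)", y = expression("kJ" ~ mol^-1), colour = NULL,
                  title = "Cavity thermodynamics vs temperature") +
    ggplot2::theme_minimal()
}

#' Plot the entropy decomposition of cavity creation
#'
#' Bars of the excluded-volume (`dS_x`) and structural-reorganization
#' (`dS_nx`) entropy contributions per solvent, with the net cavity
#' entropy overlaid — the signature that separates water (net negative)
#' from most organic liquids (net positive).
#'
#' @param solvation A `vdw_solvation` tibble from [solvate()] or the
#'   output of [cavity_thermo()].
#' @return A ggplot object.
#' @export
plot_entropy_decomposition <- function(solvation) {
  d <- as_tibble(solvation)
  long <- tidyr::pivot_longer(d[c("name", "dS_x", "dS_nx")],
                              c("dS_x", "dS_nx"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name, y = .data$value,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_point(data = d, ggplot2::aes(y = .data$dS_c, fill = NULL),
                        shape = 21, fill = "white") +
    ggplot2::labs(x = NULL,
                  y = expression(Delta * S ~ "(J" ~ K^-1 ~ mol^-1 * ")"),
                  fill = NULL, title = "Cavity entropy decomposition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
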