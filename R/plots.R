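# ggplot2 autoplot methods for the package's curve and table classes.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for depth-dose curves, lateral profiles and organ
#' dose tables.
#'
#' @param object a `pd_pdd`, `pd_profile` or `pd_organ_doses`
#' @param ... unused
#' @return a ggplot
#' @name autoplot_peridose
NULL

#' @rdname autoplot_peridose
#' @export
autoplot.pd_pdd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_cm, y = .data$pdd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "depth in water (cm)", y = "percent depth dose",
      title = sprintf(
        "Depth dose, %g x %g cm field", attr(object, "field_size"),
        attr(object, "field_size")
      )
    )
}

#' @rdname autoplot_peridose
#' @export
autoplot.pd_profile <- function(object, ...) {
  ggplot2::ggplot(
    object, ggplot2::aes(x = .data$position_cm, y = .data$dose)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "off-axis position (cm)", y = "relative dose",
      title = sprintf(
        "Lateral profile at %g cm depth", attr(object, "depth_cm")
      )
    )
}

#' @rdname autoplot_peridose
#' @export
autoplot.pd_organ_doses <- function(object, ...) {
  df <- object[!is.na(object$dose_cgy), ]
  df$organ <- stats::reorder(df$organ, df$dose_cgy)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$dose_cgy, y = .data$organ, fill = .data$group)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "two-field organ dose (cGy)", y = NULL, fill = NULL,
      title = sprintf("Peripheral organ doses, %s breast",
                      attr(object, "breast_size"))
    )
}
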