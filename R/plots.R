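#' Plot a Kaplan–Meier fit
#'
#' @param object An [km_estimate()] result.
#' @param conf Draw the Greenwood confidence band (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fl_km
#' @export
autoplot.fl_km <- function(object, conf = TRUE, ...) {
  td <- tidy(object)
  has_grp <- "group" %in% names(td)
  aes <- if (has_grp) {
    ggplot2::aes(x = .data$time, y = .data$surv, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$surv)
  }
  p <- ggplot2::ggplot(td, aes) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Progression-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (conf) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$conf.low),
                                linetype = "dashed", alpha = 0.5) +
      ggplot2::geom_step(ggplot2::aes(y = .data$conf.high),
                         linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Plot a decision-curve analysis
#' @param object A [decision_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fl_dca
#' @export
autoplot.fl_dca <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = .data$net_benefit,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibration table
#' @param object A [calibration()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fl_calibration
#' @export
autoplot.fl_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pred_surv,
                                       y = .data$obs_surv)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted survival", y = "Observed survival (KM)") +
    ggplot2::theme_minimal()
}

#' Plot an empirical ROC curve
#' @param object A [roc_binary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fl_roc
#' @export
autoplot.fl_roc <- function(object, ...) {
  curve <- attr(object, "curve")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a maximally selected log-rank scan
#' @param object An [optimal_cutoff()] result.
#' @param ... Unused.
#' @return A ggplot of the chi-square profile over candidate cutoffs.
#' @method autoplot fl_cutpoint
#' @export
autoplot.fl_cutpoint <- function(object, ...) {
  scan <- attr(object, "scan")
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$cutoff, y = .data$chi2)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = object$feature, y = "Log-rank chi-square") +
    ggplot2::theme_minimal()
}
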