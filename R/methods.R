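#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for cut-point results
#'
#' `tidy()` returns the full scan table (one row per candidate cut-off);
#' `glance()` returns a one-row summary with the selected cut-off, its
#' log-rank statistic and raw and Monte-Carlo-corrected p-values.
#'
#' @param x A `cutpoint_result` from [find_optimal_cutpoint()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cutpoint_result
#' @export
tidy.cutpoint_result <- function(x, ...) x$scan

#' @rdname tidy.cutpoint_result
#' @method glance cutpoint_result
#' @export
glance.cutpoint_result <- function(x, ...) {
  tibble::tibble(
    variable = x$variable, cutoff = x$cutoff, statistic = x$statistic,
    raw_p = x$raw_p, corrected_p = x$corrected_p,
    n_monte_carlo = x$n_monte_carlo, n = x$n, method = x$method
  )
}

#' @method tidy cox_result
#' @export
tidy.cox_result <- function(x, ...) tibble::as_tibble(x)

#' @method glance cox_result
#' @export
glance.cox_result <- function(x, ...) {
  tibble::tibble(model_type = x$model_type[1], n_terms = nrow(x),
                 n_events = x$n_events[1],
                 any_separation = any(x$separation_flag))
}

#' Kaplan-Meier step plot
#'
#' @param object A [km_estimate()] result.
#' @param conf_int Draw the confidence band.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, conf_int = FALSE, ...) {
  df <- dplyr::bind_rows(lapply(split(object, object$group), function(g) {
    tibble::tibble(group = g$group[1],
                   time = c(0, g$time), estimate = c(1, g$estimate),
                   conf_low = c(1, g$conf_low), conf_high = c(1, g$conf_high))
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                        colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
  if (conf_int) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$conf_low),
                                linetype = "dashed", alpha = 0.5) +
      ggplot2::geom_step(ggplot2::aes(y = .data$conf_high),
                         linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Scan-profile plot of a cut-point search
#'
#' @param object A `cutpoint_result`.
#' @param ... Unused.
#' @return A ggplot of the log-rank statistic over candidate cut-offs, with
#'   the selected cut-off marked.
#' @method autoplot cutpoint_result
#' @export
autoplot.cutpoint_result <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$cutoff, y = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = object$variable, y = "Log-rank chi-square") +
    ggplot2::theme_minimal()
}

#' Class-coloured overlay of a classified field
#'
#' Quality-control raster mirroring the classification display: tissue
#' regions as muted background, bud classes, vessels and LVI overlap in
#' saturated colours.
#'
#' @param field A [multiplex_field()].
#' @param buds A [classify_buds()] result.
#' @param vessels A [build_vessels()] result.
#' @param lvi_events A [detect_lvi()] result.
#' @param region_map Integer region matrix.
#' @return A ggplot raster.
#' @export
plot_field_overlay <- function(field, buds, vessels, lvi_events, region_map) {
  region_cols <- c(Tumour = "#8c6d31", Stroma = "#dadaeb",
                   NecrosisLumen = "#e7ba52", NoTissue = "#f7f7f7")
  class_cols <- c(irrelevant_marker = "#fbb4ae",
                  bud_with_debris_nucleus = "#80b1d3",
                  tumour_bud = "#e31a1c", large_bud = "#08306b",
                  vessel = "#33a02c", lvi = "#ffff33")
  lab <- matrix(REGION_LEVELS[region_map], nrow(region_map), ncol(region_map))
  for (i in seq_len(nrow(buds$buds))) {
    lab[buds$mask == buds$buds$bud_id[i]] <-
      as.character(buds$buds$bud_class[i])
  }
  lab[vessels$total_mask > 0L] <- "vessel"
  if (nrow(lvi_events)) {
    for (i in seq_len(nrow(lvi_events))) {
      hit <- buds$mask == lvi_events$bud_id[i] &
        vessels$total_mask == lvi_events$vessel_id[i]
      lab[hit] <- "lvi"
    }
  }
  df <- tibble::tibble(
    row = rep(seq_len(nrow(lab)), times = ncol(lab)),
    col = rep(seq_len(ncol(lab)), each = nrow(lab)),
    class = as.vector(lab)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(region_cols, class_cols)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = paste0(field$patient_id, " / ", field$field_id)) +
    ggplot2::theme_void()
}
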