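#' Standard-deviation matrices of Dice distributions
#'
#' Aggregates per-replicate Dice samples into the registration-uncertainty
#' summary: the per-ROI standard deviation of the Dice coefficient for every
#' design cell (frame x mode x iterations x count level x engine), the
#' ROI-averaged SD per cell, the minimum-uncertainty cell per frame, and the
#' cells statistically indistinguishable from that minimum under the
#' Brown-Forsythe equal-variance test.
#'
#' @param samples tibble with columns `frame`, `mode`, `iterations`,
#'   `count_level`, `engine`, `roi`, `replicate`, `dice`, `converged`
#'   (as produced by [run_uncertainty_analysis()]). Failed registrations
#'   (`converged == FALSE`) are excluded from the distributions and counted
#'   in `n_failed`.
#' @param alpha significance level for the indistinguishable-from-minimum
#'   flag (default 0.05).
#' @return object of class `uncertainty_matrix`: list with tibbles
#'   `per_roi` (one row per ROI x cell, with a `samples` list-column, `sd`,
#'   `n`, `n_failed`) and `average` (one row per cell with `sd_mean`,
#'   `is_min`, `indistinct_from_min`, `p_vs_min`), plus `alpha`.
#' @export
sd_matrix <- function(samples, alpha = 0.05) {
  needed <- c("frame", "mode", "iterations", "count_level", "engine", "roi",
              "dice", "converged")
  stopifnot(all(needed %in% names(samples)))
  cell_vars <- c("frame", "mode", "iterations", "count_level", "engine")

  per_roi <- samples |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(cell_vars, "roi")))) |>
    dplyr::summarise(
      samples = list(dice[converged]),
      n = sum(converged),
      n_failed = sum(!converged),
      sd = if (sum(converged) >= 2) stats::sd(dice[converged]) else NA_real_,
      .groups = "drop"
    )

  average <- per_roi |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cell_vars))) |>
    dplyr::summarise(sd_mean = mean(sd), n_roi = dplyr::n(),
                     .groups = "drop")

  # pooled samples per cell (all ROIs) for the equal-variance comparison
  pooled <- samples |>
    dplyr::filter(converged) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cell_vars))) |>
    dplyr::summarise(pooled = list(dice), .groups = "drop")
  average <- dplyr::left_join(average, pooled, by = cell_vars)

  average <- average |>
    dplyr::group_by(frame) |>
    dplyr::group_modify(function(df, key) {
      df$is_min <- FALSE
      df$p_vs_min <- NA_real_
      ok <- which(!is.na(df$sd_mean))
      if (length(ok) > 0) {
        imin <- ok[which.min(df$sd_mean[ok])]
        df$is_min[imin] <- TRUE
        ref <- df$pooled[[imin]]
        for (i in seq_len(nrow(df))) {
          g <- df$pooled[[i]]
          if (i == imin || length(g) < 3 || length(ref) < 3) next
          df$p_vs_min[i] <- brown_forsythe(list(ref, g))$p_value
        }
      }
      df
    }) |>
    dplyr::ungroup()
  average$indistinct_from_min <- average$is_min |
    (!is.na(average$p_vs_min) & average$p_vs_min >= alpha)
  average$pooled <- NULL

  structure(list(per_roi = per_roi, average = average, alpha = alpha),
            class = "uncertainty_matrix")
}

#' @export
print.uncertainty_matrix <- function(x, ...) {
  cat(sprintf("<uncertainty_matrix> %d ROI-cells, %d cells (alpha = %g)\n",
              nrow(x$per_roi), nrow(x$average), x$alpha))
  print(x$average)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an uncertainty matrix
#'
#' @param x an [sd_matrix()] result.
#' @param ... unused.
#' @return tibble of per-ROI SDs (the `samples` list-column dropped).
#' @export
tidy.uncertainty_matrix <- function(x, ...) {
  dplyr::select(x$per_roi, -dplyr::any_of("samples"))
}

#' @rdname tidy.uncertainty_matrix
#' @export
glance.uncertainty_matrix <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$average),
    n_roi_cells = nrow(x$per_roi),
    sd_min = min(x$average$sd_mean, na.rm = TRUE),
    sd_max = max(x$average$sd_mean, na.rm = TRUE),
    n_failed = sum(x$per_roi$n_failed)
  )
}

#' Tidy a registration result
#'
#' @param x a [registration_result()].
#' @param ... unused.
#' @return tibble with one row per rigid parameter.
#' @export
tidy.registration_result <- function(x, ...) {
  tibble::tibble(
    parameter = c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg"),
    value = c(x$transform$translation_mm, x$transform$rotation_deg)
  )
}

#' @rdname tidy.registration_result
#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(final_similarity = x$final_similarity,
                 converged = x$converged,
                 n_evaluations = x$n_evaluations)
}

#' Heatmap of registration uncertainty
#'
#' SD of the Dice coefficient per design cell, one tile per
#' (iterations x mode) or per count level (whichever varies), faceted by
#' frame; the minimum-uncertainty cell per frame is dotted and cells
#' indistinguishable from it are starred.
#'
#' @param object an [sd_matrix()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.uncertainty_matrix <- function(object, ...) {
  av <- object$average
  multi_level <- length(unique(av$count_level)) > 1
  if (multi_level) {
    p <- ggplot2::ggplot(av, ggplot2::aes(
      x = factor(.data$count_level), y = .data$mode, fill = .data$sd_mean))
    xl <- "count level"
  } else {
    p <- ggplot2::ggplot(av, ggplot2::aes(
      x = factor(.data$iterations), y = .data$mode, fill = .data$sd_mean))
    xl <- "OSEM iterations"
  }
  p +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(av, .data$is_min),
                        colour = "white", size = 2) +
    ggplot2::geom_text(
      data = dplyr::filter(av, .data$indistinct_from_min & !.data$is_min),
      label = "*", colour = "white", vjust = 0.75) +
    ggplot2::facet_wrap(~frame) +
    ggplot2::scale_fill_viridis_c(name = "SD(Dice)") +
    ggplot2::labs(x = xl, y = NULL,
                  title = "MR-PET registration uncertainty")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
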