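#' One-way sweep of the outcome-risk threshold
#'
#' Tabulates \eqn{M_t = RV_H H_{rx} / RRR} over a grid of harm risks, one
#' series per preference weight — the threshold-versus-bleeding-risk curves
#' used to show how patient preferences move the treat/no-treat line. Each
#' series is linear in the harm risk with slope \eqn{RV_H / RRR}, so for
#' fixed harm risk the series are ordered by the preference weight.
#'
#' @param h_rx_grid Numeric vector of treatment-harm risks, each in \[0, 1\].
#' @param rv_values Numeric vector of preference weights, each positive.
#' @param rrr Relative risk reduction shared by all points.
#' @return A `sweep_result`: a long-format data frame with columns
#'   `param_name`, `param_value`, `series_label`, `threshold`,
#'   `never_treat`. Degenerate points (e.g. `rrr = 0`) are recorded as
#'   `never_treat` rows rather than dropped.
#' @examples
#' sw <- sweep_outcome_threshold(seq(0, 0.10, by = 0.005),
#'                               rv_values = c(1, 0.75, 0.5, 0.25, 0.05),
#'                               rrr = 0.812)
#' head(sw)
#' @export
sweep_outcome_threshold <- function(h_rx_grid, rv_values, rrr) {
  stopifnot(is.numeric(h_rx_grid), length(h_rx_grid) >= 1L,
            all(h_rx_grid >= 0), all(h_rx_grid <= 1),
            is.numeric(rv_values), length(rv_values) >= 1L,
            all(rv_values > 0))
  rows <- lapply(rv_values, function(rv) {
    res <- lapply(h_rx_grid, function(h) outcome_threshold(rv, h, rrr))
    data.frame(
      param_name = "harm_rx",
      param_value = h_rx_grid,
      series_label = sprintf("RV_H=%g", rv),
      threshold = vapply(res, function(r) r$value, numeric(1)),
      never_treat = vapply(res, function(r) r$never_treat, logical(1)))
  })
  sweep_result(do.call(rbind, rows), parameter = "harm_rx")
}

#' Sweep of the threshold probability in generic versus NNT/NNH metrics
#'
#' Contrasts the two published expressions of the classic threshold
#' probability: as a function of the generic benefit-harm ratio,
#' \eqn{P_t = 1/(1 + B/H)}, and as a function of the evidence-based
#' NNT/NNH ratio, \eqn{P_t = NNT/NNH}. The same underlying threshold looks
#' dramatically different on the two scales, which is the point of the
#' comparison. NNT/NNH ratios above 1 yield `never_treat` rows.
#'
#' @param bh_ratio_grid Positive benefit-to-harm ratios \eqn{B/H}.
#' @param nnt_nnh_grid Positive NNT/NNH ratios.
#' @return A `sweep_result` with one series per expression.
#' @examples
#' sweep_probability_threshold(bh_ratio_grid = c(0.2, 1, 5),
#'                             nnt_nnh_grid = c(0.2, 0.83, 1.2))
#' @export
sweep_probability_threshold <- function(bh_ratio_grid, nnt_nnh_grid) {
  stopifnot(is.numeric(bh_ratio_grid), all(bh_ratio_grid > 0),
            is.numeric(nnt_nnh_grid), all(nnt_nnh_grid > 0))
  generic <- data.frame(
    param_name = "benefit_harm_ratio",
    param_value = bh_ratio_grid,
    series_label = "Pt=1/(1+B/H)",
    threshold = 1 / (1 + bh_ratio_grid),
    never_treat = FALSE)
  ebm <- data.frame(
    param_name = "nnt_nnh_ratio",
    param_value = nnt_nnh_grid,
    series_label = "Pt=NNT/NNH",
    threshold = nnt_nnh_grid,
    never_treat = nnt_nnh_grid > 1)
  sweep_result(rbind(generic, ebm), parameter = "ratio")
}

sweep_result <- function(df, parameter) {
  rownames(df) <- NULL
  structure(df, parameter = parameter,
            class = c("sweep_result", "data.frame"))
}

#' Write a sweep table to CSV
#'
#' Serialises the long-format sweep table (`param_name`, `param_value`,
#' `series_label`, `threshold`, `never_treat`); the table, not any plot of
#' it, is the source of truth for a sensitivity analysis.
#'
#' @param x A `sweep_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(inherits(x, "sweep_result"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Plot a sweep as threshold-versus-parameter curves
#'
#' Optional rendering of the sweep table with ggplot2 (one line per
#' series); thresholds above 1 (never-treat region) are omitted from the
#' lines.
#'
#' @param x A `sweep_result`.
#' @param percent Show the threshold axis in percent.
#' @return A ggplot object.
#' @export
plot_sweep <- function(x, percent = TRUE) {
  stopifnot(inherits(x, "sweep_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting; the sweep table itself is the ",
         "primary output", call. = FALSE)
  df <- as.data.frame(x)
  df <- df[!df$never_treat, , drop = FALSE]
  if (percent) df$threshold <- 100 * df$threshold
  ggplot2::ggplot(df, ggplot2::aes(x = param_value, y = threshold,
                                   colour = series_label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = unique(df$param_name)[1],
                  y = if (percent) "threshold (%)" else "threshold",
                  colour = "series") +
    ggplot2::theme_minimal()
}
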