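#' Root-mean-square error of estimated admixture times, in kya
#'
#' @param table Experiment tibble with `time_true_years` and
#'   `time_est_years` columns (years), e.g. from [run_experiment_grid()].
#' @param ratio Optional: restrict to rows with this `ratio` value.
#' @param filter Optional predicate `function(df) -> logical vector` for
#'   arbitrary row selection.
#' @param include_nonconverged Keep rows whose fit did not converge?
#'   Defaults to `FALSE`.
#' @return RMSE in thousands of years.
#' @examples
#' tab <- tibble::tibble(time_true_years = c(1000, 3000),
#'                       time_est_years = c(2000, 2000), converged = TRUE)
#' rmse_kya(tab) # 1
#' @export
rmse_kya <- function(table, ratio = NULL, filter = NULL,
                     include_nonconverged = FALSE) {
  d <- table
  if (!is.null(ratio)) d <- d[d$ratio %in% ratio, , drop = FALSE]
  if (!is.null(filter)) d <- d[filter(d), , drop = FALSE]
  if (!include_nonconverged && "converged" %in% names(d))
    d <- d[d$converged %in% TRUE, , drop = FALSE]
  d <- d[!is.na(d$time_est_years), , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows left after filtering", call. = FALSE)
  err_kya <- (d$time_est_years - d$time_true_years) / 1000
  sqrt(mean(err_kya^2))
}

TIME_BIN_BREAKS_KYA <- c(-Inf, 20, 40, 60, 80, Inf)
TIME_BIN_LABELS <- c("<=20", "20-40", "40-60", "60-80", ">80")

#' Signed-error summaries by true-admixture-time bin
#'
#' Groups signed errors (estimate minus truth, kya) into five bins of the
#' true time: before 20 kya, 20-40, 40-60, 60-80 and beyond 80 kya.
#' Bins are left-open / right-closed, so a truth at exactly 40 kya falls in
#' the 20-40 bin. Empty bins are reported with `n = 0`.
#'
#' @param table Experiment tibble (see [rmse_kya()]).
#' @param include_nonconverged Keep non-converged rows?
#' @return A tibble with `bin`, `n`, `mean_error_kya`, `median_error_kya`,
#'   `q25_kya`, `q75_kya`.
#' @export
error_by_time_bin <- function(table, include_nonconverged = FALSE) {
  d <- table
  if (!include_nonconverged && "converged" %in% names(d))
    d <- d[d$converged %in% TRUE, , drop = FALSE]
  d <- d[!is.na(d$time_est_years), , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable rows", call. = FALSE)
  d <- dplyr::mutate(
    tibble::as_tibble(d),
    bin = cut(.data$time_true_years / 1000, breaks = TIME_BIN_BREAKS_KYA,
              labels = TIME_BIN_LABELS, right = TRUE),
    error_kya = (.data$time_est_years - .data$time_true_years) / 1000)
  dplyr::summarise(
    dplyr::group_by(d, .data$bin, .drop = FALSE),
    n = dplyr::n(),
    mean_error_kya = if (dplyr::n() > 0) mean(.data$error_kya) else NA_real_,
    median_error_kya = if (dplyr::n() > 0) median(.data$error_kya) else NA_real_,
    q25_kya = if (dplyr::n() > 0) quantile(.data$error_kya, 0.25, names = FALSE) else NA_real_,
    q75_kya = if (dplyr::n() > 0) quantile(.data$error_kya, 0.75, names = FALSE) else NA_real_,
    .groups = "drop")
}

#' Least-squares regression of estimated on true admixture time
#'
#' @param table Experiment tibble (see [rmse_kya()]).
#' @param include_nonconverged Keep non-converged rows?
#' @return A one-row tibble with `slope`, `intercept_years`, `r_squared`.
#' @export
regression_line <- function(table, include_nonconverged = FALSE) {
  d <- table
  if (!include_nonconverged && "converged" %in% names(d))
    d <- d[d$converged %in% TRUE, , drop = FALSE]
  d <- d[!is.na(d$time_est_years), , drop = FALSE]
  if (length(unique(d$time_true_years)) < 2L)
    stop("need at least two distinct true times", call. = FALSE)
  f <- lm(time_est_years ~ time_true_years, data = d)
  tibble::tibble(slope = unname(coef(f)[2]),
                 intercept_years = unname(coef(f)[1]),
                 r_squared = summary(f)$r.squared)
}

#' Scatter plot of estimated versus true admixture times
#'
#' One panel per ratio; the dashed line is the identity (datum) line and the
#' red line the least-squares regression of estimate on truth.
#'
#' @param table Experiment tibble from [run_experiment_grid()].
#' @return A ggplot.
#' @export
plot_experiment_grid <- function(table) {
  d <- table[!is.na(table$time_est_years), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_true_years / 1000,
                                  y = .data$time_est_years / 1000)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ratio, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "simulated admixture time (kya)",
                  y = "estimated admixture time (kya)")
}
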