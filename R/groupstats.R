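#' Unpaired difference of group means with SEM propagation
#'
#' `mean_diff = mean_A - mean_B`, with the SEM of the difference combined in
#' quadrature, `sem_diff = sqrt(sem_A^2 + sem_B^2)` — the standard
#' propagation for independent (unpaired) groups. (The combination is
#' sometimes printed with a minus sign inside the radical; that form is not
#' a valid variance combination for independent groups and can go
#' imaginary, so the quadrature sum is used here.)
#'
#' @param mean_A,sem_A,n_A Mean, SEM and size of group A.
#' @param mean_B,sem_B,n_B Mean, SEM and size of group B.
#' @param label_A,label_B Group labels.
#' @return A tibble of class `group_difference` with columns `label_A`,
#'   `label_B`, `mean_diff`, `sem_diff`, `n_A`, `n_B`.
#' @export
#' @examples
#' unpaired_difference(10, 3, 12, 4, 4, 10)$sem_diff  # 5
unpaired_difference <- function(mean_A, sem_A, n_A, mean_B, sem_B, n_B,
                                label_A = "A", label_B = "B") {
  if (any(c(sem_A, sem_B) < 0)) {
    rlang::abort("SEMs must be >= 0.", class = "synaptrain_error_invalid_n")
  }
  if (any(c(n_A, n_B) < 2)) {
    rlang::abort("group sizes must be >= 2.",
                 class = "synaptrain_error_invalid_n")
  }
  out <- tibble::tibble(
    label_A = label_A, label_B = label_B,
    mean_diff = mean_A - mean_B,
    sem_diff = sqrt(sem_A^2 + sem_B^2),
    n_A = as.integer(n_A), n_B = as.integer(n_B)
  )
  structure(out, class = c("group_difference", class(out)))
}

#' Per-group summary of a cohort metric
#'
#' Mean, SEM and n of a per-cell metric within each sex x genotype
#' (x condition, if present) cell, in deterministic order.
#'
#' @param cohort A data frame with one row per cell (or cell x condition)
#'   holding at least `sex`, `genotype` and the metric column; a `condition`
#'   column is used as an additional grouping variable when present.
#' @param metric Name of the metric column (string or bare name).
#' @return A tibble with `sex`, `genotype` (, `condition`), `mean`, `sem`,
#'   `n`.
#' @export
group_summary <- function(cohort, metric) {
  metric <- rlang::as_name(rlang::ensym(metric))
  if (!metric %in% names(cohort)) {
    rlang::abort(sprintf("metric '%s' not found in cohort.", metric),
                 class = "synaptrain_error_missing_metric")
  }
  grp <- intersect(c("sex", "genotype", "condition"), names(cohort))
  out <- cohort |>
    dplyr::filter(!is.na(.data[[metric]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(mean = mean(.data[[metric]]),
                     sem = sem(.data[[metric]]),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)))
  small <- out$n < 2
  if (any(small)) {
    rlang::warn(sprintf("%d group(s) have fewer than 2 cells for '%s'.",
                        sum(small), metric))
  }
  out
}

#' Plot a group summary
#'
#' @param object A [group_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot of group means with SEM error bars.
#' @export
plot_group_summary <- function(object, ...) {
  object$group <- interaction(object$sex, object$genotype, sep = " ")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$group, .data$mean))
  if ("condition" %in% names(object)) {
    p <- ggplot2::ggplot(object,
                         ggplot2::aes(.data$group, .data$mean,
                                      colour = .data$condition))
  }
  p + ggplot2::geom_point(position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.2, position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(x = NULL, y = "Group mean ± SEM")
}
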