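#' Default Boolean recipes linking stage delays to patient outcomes
#'
#' The two binary outcomes are reduced ejection fraction (`EF`, ejection
#' fraction below 50\%) and elevated length of stay (`LOS`). In the default
#' configuration, EF is driven by `ecg*txf*TWT + FMC*ecg*TWT` and LOS by
#' `FMC*ecg*TXF*TWT + FMC*ECG*txf*TWT` evaluated on the per-stage delay
#' flags — upper case meaning the stage was delayed, lower case meaning it
#' was not.
#'
#' @return Named list of expression strings, one per outcome.
#' @export
default_outcome_recipes <- function() {
  list(
    EF = "ecg*txf*TWT + FMC*ecg*TWT",
    LOS = "FMC*ecg*TXF*TWT + FMC*ECG*txf*TWT"
  )
}

#' Generate a synthetic STEMI cohort
#'
#' Each patient receives independent stage durations drawn from the
#' calibrated per-stage mixtures (see [calibrate_stage_mixture()]), a binary
#' delay flag per stage (1 exactly when the duration exceeds the stage's
#' ideal time), and binary outcomes computed deterministically from the
#' delay flags through the outcome recipes. With `noise_rate = 0` (the
#' default) the recipe linkage is exact, so a downstream csQCA run can
#' recover the recipes; a positive noise rate flips each outcome bit
#' independently with that probability.
#'
#' @param stage_specs Stage table, see [default_stage_specs()].
#' @param outcome_recipes Named list of Boolean expression strings over the
#'   four stage names, see [default_outcome_recipes()].
#' @param n Number of patients (at least 1).
#' @param seed Optional integer seed for reproducibility.
#' @param noise_rate Probability in \[0, 1\] of flipping each outcome bit.
#' @return A tibble with columns `patient_id`, `fmc_min`, `ecg_min`,
#'   `txf_min`, `twt_min`, the 0/1 delay flags `FMC`, `ECG`, `TXF`, `TWT`,
#'   and one 0/1 column per outcome (by default `EF` and `LOS`).
#' @examples
#' cohort <- generate_cohort(n = 29, seed = 7)
#' head(cohort)
#' @export
generate_cohort <- function(stage_specs = default_stage_specs(),
                            outcome_recipes = default_outcome_recipes(),
                            n = 29, seed = NULL, noise_rate = 0) {
  validate_stage_specs(stage_specs)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    rlang::abort("n must be a single integer >= 1")
  }
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate > 1) {
    rlang::abort("noise_rate must lie in [0, 1]")
  }
  if (is.null(names(outcome_recipes)) || any(!nzchar(names(outcome_recipes)))) {
    rlang::abort("outcome_recipes must be a named list of expression strings")
  }
  # parse up front so a bad recipe fails before any sampling
  recipe_mats <- purrr::map(outcome_recipes,
                            parse_qca_expression,
                            conditions = stage_specs$stage)

  build <- function() {
    calibrated <- calibrate_stage_mixtures(stage_specs)
    durations <- purrr::map(calibrated$mixture, sample_stage_durations, n = n)
    names(durations) <- calibrated$stage
    flags <- purrr::map2(durations, calibrated$ideal_time,
                         function(d, t) as.integer(d > t))
    flag_df <- tibble::as_tibble(flags)
    outcomes <- purrr::map(recipe_mats, function(mat) {
      y <- eval_qca_expression(mat, flag_df)
      if (noise_rate > 0) {
        flip <- stats::rbinom(n, 1, noise_rate)
        y <- as.integer(xor(y, flip))
      }
      y
    })
    tibble::tibble(
      patient_id = seq_len(n),
      fmc_min = durations$FMC,
      ecg_min = durations$ECG,
      txf_min = durations$TXF,
      twt_min = durations$TWT
    ) |>
      dplyr::bind_cols(flag_df) |>
      dplyr::bind_cols(tibble::as_tibble(outcomes))
  }
  if (is.null(seed)) build() else with_preserved_seed(seed, build())
}

#' Summarize a cohort's per-stage delays
#'
#' Computes, per stage, the sample mean duration and the fraction of
#' patients exceeding the stage's ideal time, plus the mean total
#' door-in-door-out time (the stages are sequential and non-overlapping, so
#' the total is the per-patient sum of the four stage durations).
#'
#' @param cohort Cohort tibble from [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param stage_specs Stage table supplying the ideal times.
#' @return A `cohort_summary` object; [generics::tidy()] returns the
#'   per-stage table, [generics::glance()] the one-row overall summary.
#' @examples
#' summarize_cohort(generate_cohort(n = 200, seed = 1))
#' @export
summarize_cohort <- function(cohort, stage_specs = default_stage_specs()) {
  if (nrow(cohort) == 0) rlang::abort("cohort is empty")
  validate_stage_specs(stage_specs)
  dur_cols <- c(FMC = "fmc_min", ECG = "ecg_min", TXF = "txf_min", TWT = "twt_min")
  missing <- setdiff(unname(dur_cols), names(cohort))
  if (length(missing) > 0) {
    rlang::abort(paste0("cohort missing duration column(s): ",
                        paste(missing, collapse = ", ")))
  }
  stages <- purrr::map2_dfr(names(dur_cols), dur_cols, function(stage, col) {
    ideal <- stage_specs$ideal_time[stage_specs$stage == stage]
    tibble::tibble(
      stage = stage,
      n = nrow(cohort),
      ideal_time = ideal,
      mean_duration = mean(cohort[[col]]),
      exceed_frac = mean(cohort[[col]] > ideal)
    )
  })
  total <- cohort$fmc_min + cohort$ecg_min + cohort$txf_min + cohort$twt_min
  structure(
    list(
      stages = stages,
      total_mean = mean(total),
      n = nrow(cohort)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (", x$n, " patients)\n", sep = "")
  print(x$stages)
  cat("Mean total door-in-door-out time: ",
      format(round(x$total_mean, 1)), " min\n", sep = "")
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary` object.
#' @param ... Unused.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) x$stages

#' @rdname summarize_cohort
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(n = x$n, total_mean = x$total_mean)
}

#' @describeIn summarize_cohort Plot per-stage mean durations against ideal
#'   times.
#' @param object A `cohort_summary`.
#' @method autoplot cohort_summary
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- object$stages |>
    dplyr::mutate(stage = factor(.data$stage, levels = stemi_stages)) |>
    tidyr::pivot_longer(c("ideal_time", "mean_duration"),
                        names_to = "measure", values_to = "minutes")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$minutes,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(ideal_time = "#2ca02c", mean_duration = "#d62728"),
      labels = c(ideal_time = "Ideal", mean_duration = "Observed mean")
    ) +
    ggplot2::labs(x = NULL, y = "Minutes", fill = NULL,
                  title = "Per-stage care durations vs guideline ideals")
}

#' Binarize a continuous outcome by median split
#'
#' Convenience helper for externally supplied length-of-stay values: returns
#' 1 for values strictly above the sample median, 0 otherwise.
#'
#' @param x Numeric vector.
#' @return Integer 0/1 vector of the same length.
#' @export
median_split <- function(x) {
  if (!is.numeric(x) || length(x) == 0) rlang::abort("x must be non-empty numeric")
  as.integer(x > stats::median(x))
}
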