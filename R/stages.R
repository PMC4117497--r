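#' The four sequential care stages of the door-in-door-out pathway
#'
#' Stage order is fixed: first medical contact (FMC), ECG acquisition and
#' physician review (ECG), ECG transmission and PCI-center feedback (TXF),
#' transfer wait until departure (TWT).
#'
#' @format Character vector of length four.
#' @export
stemi_stages <- c("FMC", "ECG", "TXF", "TWT")

#' Default per-stage specifications for a non-PCI primary hospital
#'
#' Returns the calibration table the rest of the package is built around:
#' guideline ideal times (2, 8, 5 and 15 minutes, summing to the 30-minute
#' door-in-door-out goal), observed mean stage durations (7, 28, 76 and 78
#' minutes), the fraction of patients exceeding each ideal time, and the
#' improvement policy estimates with their uncertainty intervals used by the
#' sensitivity module.
#'
#' The FMC exceedance fraction is not pinned down by the observed summaries
#' (the FMC calibration target is its mean only); the default of 0.75 is a
#' documented free parameter, configurable by editing the returned tibble.
#'
#' @return A tibble with one row per stage and columns `stage`, `ideal_time`,
#'   `mean_duration`, `exceed_frac`, `improvement_estimate`,
#'   `improvement_low`, `improvement_high`.
#' @examples
#' default_stage_specs()
#' @export
default_stage_specs <- function() {
  tibble::tibble(
    stage = stemi_stages,
    ideal_time = c(2, 8, 5, 15),
    mean_duration = c(7, 28, 76, 78),
    exceed_frac = c(0.75, 0.79, 0.76, 0.86),
    improvement_estimate = c(0.40, 0.40, 0.50, 0.50),
    improvement_low = c(0.10, 0.10, 0.10, 0.10),
    improvement_high = c(0.50, 0.50, 0.60, 0.60)
  )
}

#' Validate a stage-specification tibble
#'
#' Checks the structural invariants every stage table must satisfy before it
#' can drive the generator or the simulator: the four stages in canonical
#' order, positive ideal times and means, exceedance fractions in (0, 1],
#' and improvement intervals that contain their point estimate.
#'
#' @param specs A tibble as returned by [default_stage_specs()].
#' @return `specs`, invisibly, if valid; otherwise an error.
#' @export
validate_stage_specs <- function(specs) {
  required <- c(
    "stage", "ideal_time", "mean_duration", "exceed_frac",
    "improvement_estimate", "improvement_low", "improvement_high"
  )
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "stage specs missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!identical(specs$stage, stemi_stages)) {
    rlang::abort("stage specs must contain exactly FMC, ECG, TXF, TWT in that order")
  }
  if (any(specs$ideal_time <= 0) || any(specs$mean_duration <= 0)) {
    rlang::abort("ideal_time and mean_duration must be positive")
  }
  if (any(specs$exceed_frac <= 0 | specs$exceed_frac > 1)) {
    rlang::abort("exceed_frac must lie in (0, 1]")
  }
  bad_int <- specs$improvement_low > specs$improvement_estimate |
    specs$improvement_estimate > specs$improvement_high |
    specs$improvement_low < 0 | specs$improvement_high >= 1
  if (any(bad_int)) {
    rlang::abort(paste0(
      "improvement interval must satisfy 0 <= low <= estimate <= high < 1 for stage(s): ",
      paste(specs$stage[bad_int], collapse = ", ")
    ))
  }
  invisible(specs)
}

#' Calibrate the two-component duration mixture for one care stage
#'
#' Stage durations are modelled as a mixture chosen so that both printed
#' summaries are matched exactly: with probability `1 - exceed_frac` the
#' duration is uniform on `(0, ideal]` (the patient meets the guideline);
#' with probability `exceed_frac` it is `ideal` plus an exponential excess
#' with mean `mu`. By construction `P(duration > ideal) = exceed_frac`, and
#' solving
#' \deqn{mean = (1-e)\,t^{*}/2 + e\,(t^{*} + \mu)}
#' for `mu` makes the distribution mean equal the calibration target:
#' \deqn{\mu = \frac{mean - (1-e)\,t^{*}/2 - e\,t^{*}}{e}.}
#'
#' @param mean_duration Target mean stage duration in minutes.
#' @param exceed_frac Target probability of exceeding the ideal time, in
#'   (0, 1].
#' @param ideal Ideal (guideline) time in minutes.
#' @param stage Optional stage name, used in error messages.
#' @return An object of class `stage_mixture`: a list with fields `stage`,
#'   `ideal`, `exceed_frac`, `excess_mean`, `mean_duration`.
#' @examples
#' calibrate_stage_mixture(76, 0.76, 5, stage = "TXF")
#' @export
calibrate_stage_mixture <- function(mean_duration, exceed_frac, ideal,
                                    stage = NA_character_) {
  if (!is.numeric(ideal) || length(ideal) != 1 || ideal <= 0) {
    rlang::abort("ideal must be a single positive number of minutes")
  }
  if (!is.numeric(mean_duration) || length(mean_duration) != 1 || mean_duration <= 0) {
    rlang::abort("mean_duration must be a single positive number of minutes")
  }
  if (!is.numeric(exceed_frac) || length(exceed_frac) != 1 ||
      exceed_frac <= 0 || exceed_frac > 1) {
    rlang::abort("exceed_frac must lie in (0, 1]")
  }
  e <- exceed_frac
  mu <- (mean_duration - (1 - e) * ideal / 2 - e * ideal) / e
  if (!is.finite(mu) || mu <= 0) {
    rlang::abort(paste0(
      "infeasible mixture calibration for stage ",
      if (is.na(stage)) "<unnamed>" else stage,
      ": implied excess mean ", signif(mu, 4),
      " is not positive (mean_duration too small for the given ideal and exceed_frac)"
    ))
  }
  structure(
    list(
      stage = stage, ideal = ideal, exceed_frac = e,
      excess_mean = mu, mean_duration = mean_duration
    ),
    class = "stage_mixture"
  )
}

#' @export
print.stage_mixture <- function(x, ...) {
  cat(
    "<stage_mixture> ", if (is.na(x$stage)) "" else x$stage,
    ": ideal ", x$ideal, " min, P(exceed) = ", x$exceed_frac,
    ", excess mean ", signif(x$excess_mean, 5),
    " min (target mean ", x$mean_duration, " min)\n",
    sep = ""
  )
  invisible(x)
}

#' Calibrate mixtures for all four stages
#'
#' @param specs Stage-specification tibble, see [default_stage_specs()].
#' @return The tibble with an added list-column `mixture` of `stage_mixture`
#'   objects and a numeric column `excess_mean`.
#' @export
calibrate_stage_mixtures <- function(specs = default_stage_specs()) {
  validate_stage_specs(specs)
  mixtures <- purrr::pmap(
    list(specs$mean_duration, specs$exceed_frac, specs$ideal_time, specs$stage),
    function(m, e, t, s) calibrate_stage_mixture(m, e, t, stage = s)
  )
  specs |>
    dplyr::mutate(
      mixture = mixtures,
      excess_mean = purrr::map_dbl(mixtures, "excess_mean")
    )
}

#' Draw stage durations from a calibrated mixture
#'
#' @param params A `stage_mixture` from [calibrate_stage_mixture()].
#' @param n Number of independent draws (`n = 0` returns an empty vector).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's random state is untouched.
#' @return Numeric vector of `n` durations in minutes.
#' @examples
#' txf <- calibrate_stage_mixture(76, 0.76, 5, stage = "TXF")
#' mean(sample_stage_durations(txf, 1e4, seed = 1))
#' @export
sample_stage_durations <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "stage_mixture"))
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n)) {
    rlang::abort("n must be a single non-negative integer")
  }
  if (n == 0) return(numeric(0))
  draw <- function() {
    exceeds <- stats::runif(n) < params$exceed_frac
    below <- stats::runif(n, min = 0, max = params$ideal)
    above <- params$ideal + stats::rexp(n, rate = 1 / params$excess_mean)
    ifelse(exceeds, above, below)
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

# Run expr under set.seed(seed) without clobbering the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
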