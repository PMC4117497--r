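#' Build the binary condition matrix for a csQCA run
#'
#' Extracts the per-stage delay flags (conditions) and one outcome column
#' from a cohort, yielding the case-by-condition matrix crisp-set QCA
#' operates on: every entry is 0 (condition/outcome absent) or 1 (present).
#'
#' @param cohort Cohort tibble with 0/1 columns for each condition and the
#'   outcome.
#' @param outcome Name of the outcome column (e.g. `"EF"` or `"LOS"`).
#' @param conditions Ordered condition names; default the four care stages.
#' @return A `condition_matrix`: a tibble with `case_id`, one 0/1 column per
#'   condition, and the outcome column; attributes record the condition
#'   order and outcome name.
#' @examples
#' cohort <- generate_cohort(n = 29, seed = 7)
#' binarize_conditions(cohort, outcome = "EF")
#' @export
binarize_conditions <- function(cohort, outcome = "EF",
                                conditions = stemi_stages) {
  missing <- setdiff(c(conditions, outcome), names(cohort))
  if (length(missing) > 0) {
    rlang::abort(paste0("cohort missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  for (col in c(conditions, outcome)) {
    v <- cohort[[col]]
    if (!all(v %in% c(0L, 1L))) {
      rlang::abort(paste0("column '", col, "' contains non-binary values"))
    }
  }
  out <- tibble::tibble(
    case_id = if ("patient_id" %in% names(cohort)) cohort$patient_id else seq_len(nrow(cohort))
  )
  out <- dplyr::bind_cols(
    out,
    dplyr::select(cohort, dplyr::all_of(conditions)),
    dplyr::select(cohort, dplyr::all_of(outcome))
  )
  if (nrow(out) == 0) rlang::abort("condition matrix must contain at least one case")
  structure(out,
            conditions = conditions, outcome = outcome,
            class = c("condition_matrix", class(out)))
}

#' Construct a crisp-set truth table
#'
#' Groups cases by their condition configuration. A configuration's
#' inclusion is the fraction of its cases showing the outcome; the assigned
#' output is `"1"` when inclusion is at least `inclusion_cutoff`, `"0"` when
#' it is at most `1 - inclusion_cutoff`, and `"C"` (contradiction)
#' otherwise. The `2^k` minus observed configurations are appended as
#' logical remainders (`"R"`), as are observed configurations with fewer
#' than `freq_cutoff` cases.
#'
#' @param matrix A `condition_matrix` from [binarize_conditions()].
#' @param inclusion_cutoff Sufficiency inclusion cutoff in (0.5, 1];
#'   default 1 (perfect sufficiency).
#' @param freq_cutoff Minimum number of cases for a configuration to count
#'   as observed; default 1.
#' @return A `qca_truth_table` tibble with the condition columns, `n`,
#'   `incl` and `OUT`.
#' @export
build_truth_table <- function(matrix, inclusion_cutoff = 1, freq_cutoff = 1) {
  conditions <- attr(matrix, "conditions")
  outcome <- attr(matrix, "outcome")
  if (is.null(conditions)) {
    rlang::abort("input must be a condition_matrix from binarize_conditions()")
  }
  if (inclusion_cutoff <= 0.5 || inclusion_cutoff > 1) {
    rlang::abort("inclusion_cutoff must lie in (0.5, 1]")
  }
  k <- length(conditions)
  observed <- matrix |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(conditions))) |>
    dplyr::summarise(
      n = dplyr::n(),
      incl = mean(.data[[outcome]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      OUT = dplyr::case_when(
        n < freq_cutoff ~ "R",
        incl >= inclusion_cutoff ~ "1",
        incl <= 1 - inclusion_cutoff ~ "0",
        TRUE ~ "C"
      )
    )
  all_cfg <- do.call(tidyr::expand_grid,
                     stats::setNames(rep(list(0:1), k), conditions))
  remainders <- dplyr::anti_join(all_cfg, observed, by = conditions) |>
    dplyr::mutate(n = 0L, incl = NA_real_, OUT = "R")
  tt <- dplyr::bind_rows(observed, remainders) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(conditions)))
  structure(tt,
            conditions = conditions, outcome = outcome,
            inclusion_cutoff = inclusion_cutoff,
            n_cases = nrow(matrix),
            class = c("qca_truth_table", class(tibble::tibble())))
}

#' @export
print.qca_truth_table <- function(x, ...) {
  cat("csQCA truth table | outcome: ", attr(x, "outcome"),
      " | cases: ", attr(x, "n_cases"),
      " | cutoff: ", attr(x, "inclusion_cutoff"), "\n", sep = "")
  NextMethod()
  invisible(x)
}

# ---- Quine-McCluskey core -------------------------------------------------
# Implicants are integer matrices: one row per implicant, entries 1
# (present), 0 (absent), NA (free literal).

implicant_key <- function(mat) {
  apply(mat, 1, function(r) paste(ifelse(is.na(r), "-", r), collapse = ""))
}

unique_implicants <- function(mat) {
  mat[!duplicated(implicant_key(mat)), , drop = FALSE]
}

# TRUE where implicant i covers configuration j (configs: 0/1 matrix)
implicant_covers <- function(implicants, configs) {
  n_i <- nrow(implicants)
  n_c <- nrow(configs)
  out <- matrix(TRUE, n_i, n_c)
  for (j in seq_len(ncol(implicants))) {
    v <- implicants[, j]
    fixed <- !is.na(v)
    if (!any(fixed)) next
    cmp <- outer(v[fixed], configs[, j], "==")
    out[fixed, ] <- out[fixed, , drop = FALSE] & cmp
  }
  out
}

# Iteratively combine terms differing in exactly one fixed literal until no
# combination is possible; the uncombined terms are the prime implicants.
qm_prime_implicants <- function(minterms) {
  current <- unique_implicants(minterms)
  primes <- NULL
  repeat {
    n <- nrow(current)
    combined <- logical(n)
    fresh <- list()
    if (n > 1) {
      na_sig <- apply(is.na(current), 1, paste, collapse = "")
      ones <- rowSums(current == 1, na.rm = TRUE)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (na_sig[i] != na_sig[j]) next
          if (abs(ones[i] - ones[j]) != 1) next
          diff <- which(!is.na(current[i, ]) & current[i, ] != current[j, ])
          if (length(diff) == 1) {
            merged <- current[i, ]
            merged[diff] <- NA_integer_
            fresh[[length(fresh) + 1]] <- merged
            combined[i] <- TRUE
            combined[j] <- TRUE
          }
        }
      }
    }
    primes <- rbind(primes, current[!combined, , drop = FALSE])
    if (length(fresh) == 0) break
    current <- unique_implicants(do.call(rbind, fresh))
  }
  unique_implicants(primes)
}

# Exact minimum cover of the ON-set by prime implicants: essential primes
# first, then exhaustive search over the residual chart (Petrick-style; k is
# small so this is cheap). Ties broken by fewest total literals, then by the
# canonical lexicographic order of the implicant patterns.
qm_min_cover <- function(primes, on_configs) {
  chart <- implicant_covers(primes, on_configs)
  n_lit <- rowSums(!is.na(primes))
  keys <- implicant_key(primes)
  cover_key <- function(idx) paste(sort(keys[idx]), collapse = "|")
  total_lit <- function(idx) sum(n_lit[idx])

  single <- which(colSums(chart) == 1)
  essential <- sort(unique(unlist(lapply(single, function(j) which(chart[, j])))))
  covered <- if (length(essential) > 0) {
    apply(chart[essential, , drop = FALSE], 2, any)
  } else {
    rep(FALSE, ncol(chart))
  }
  remaining <- which(!covered)
  chosen <- essential
  if (length(remaining) > 0) {
    cand <- setdiff(which(rowSums(chart[, remaining, drop = FALSE]) > 0),
                    essential)
    best <- NULL
    for (s in seq_len(length(cand))) {
      combos <- utils::combn(cand, s, simplify = FALSE)
      full <- Filter(function(cc) {
        all(apply(chart[cc, remaining, drop = FALSE], 2, any))
      }, combos)
      if (length(full) > 0) {
        scored <- lapply(full, function(cc) {
          idx <- c(essential, cc)
          list(idx = idx, lit = total_lit(idx), key = cover_key(idx))
        })
        lits <- vapply(scored, function(x) x$lit, numeric(1))
        scored <- scored[lits == min(lits)]
        ks <- vapply(scored, function(x) x$key, character(1))
        best <- scored[[order(ks)[1]]]$idx
        break
      }
    }
    chosen <- best
  }
  sort(unique(chosen))
}

#' Minimize a truth table by the Quine-McCluskey algorithm
#'
#' Finds the minimal disjunction of implicants covering every positive
#' configuration and no negative one. With `use_remainders = FALSE` the
#' logical remainders count as negative (the complex, most conservative
#' solution); with `use_remainders = TRUE` they are usable as don't-cares
#' (the parsimonious solution). Contradictory configurations are excluded
#' from the positive set and, under the default `"off"` policy, counted as
#' negative.
#'
#' Among covers of minimum implicant count, ties are broken by fewest total
#' literals and then by canonical lexicographic order, so the output is
#' deterministic.
#'
#' @param truth_table A `qca_truth_table` from [build_truth_table()].
#' @param use_remainders Logical; admit remainders as don't-cares?
#' @param contradiction_policy `"off"` (contradictions join the negative
#'   set) or `"exclude"` (they are ignored entirely).
#' @param solution_type Label stored on the result; inferred from
#'   `use_remainders` by default.
#' @param dont_care Optional extra 0/1 configuration matrix to admit as
#'   don't-cares (used by [intermediate_solution()]).
#' @return A `qca_solution`: implicant matrix, canonical expression string,
#'   per-implicant and overall consistency and coverage.
#' @examples
#' cohort <- generate_cohort(n = 200, seed = 11)
#' tt <- build_truth_table(binarize_conditions(cohort, "LOS"))
#' minimize_truth_table(tt)
#' @export
minimize_truth_table <- function(truth_table, use_remainders = FALSE,
                                 contradiction_policy = c("off", "exclude"),
                                 solution_type = NULL,
                                 dont_care = NULL) {
  contradiction_policy <- match.arg(contradiction_policy)
  conditions <- attr(truth_table, "conditions")
  if (is.null(conditions)) {
    rlang::abort("input must be a qca_truth_table from build_truth_table()")
  }
  tt <- tibble::as_tibble(truth_table)
  cfg <- as.matrix(tt[, conditions])
  storage.mode(cfg) <- "integer"
  on_rows <- tt$OUT == "1"
  if (!any(on_rows)) rlang::abort("truth table has no positive configuration")
  dc_rows <- if (use_remainders) tt$OUT == "R" else rep(FALSE, nrow(tt))
  if (contradiction_policy == "exclude") {
    dc_rows <- dc_rows | tt$OUT == "C"
  }
  on <- cfg[on_rows, , drop = FALSE]
  dc <- cfg[dc_rows, , drop = FALSE]
  if (!is.null(dont_care) && nrow(dont_care) > 0) {
    extra <- as.matrix(dont_care[, conditions])
    storage.mode(extra) <- "integer"
    dc <- rbind(dc, extra)
  }
  primes <- qm_prime_implicants(rbind(on, dc))
  chosen <- qm_min_cover(primes, on)
  implicants <- primes[chosen, , drop = FALSE]
  colnames(implicants) <- conditions
  implicants <- implicants[order_implicants(implicants), , drop = FALSE]
  if (is.null(solution_type)) {
    solution_type <- if (use_remainders) "parsimonious" else "complex"
  }
  new_qca_solution(implicants, truth_table, solution_type)
}

# Fit measures are computed over the observed truth-table rows, weighting
# each configuration by its case count; incl * n is the number of positive
# cases in a configuration.
new_qca_solution <- function(implicants, truth_table, type) {
  conditions <- attr(truth_table, "conditions")
  tt <- tibble::as_tibble(truth_table)
  obs <- tt[tt$n > 0, , drop = FALSE]
  cfg <- as.matrix(obs[, conditions])
  storage.mode(cfg) <- "integer"
  pos <- obs$n * obs$incl
  total_pos <- sum(pos)
  cov_mat <- implicant_covers(implicants, cfg)   # implicants x observed rows
  details <- purrr::map_dfr(seq_len(nrow(implicants)), function(i) {
    hit <- cov_mat[i, ]
    n_cov <- sum(obs$n[hit])
    tibble::tibble(
      implicant = format_qca_expression(implicants[i, , drop = FALSE], conditions),
      n_cases = n_cov,
      consistency = if (n_cov > 0) sum(pos[hit]) / n_cov else NA_real_,
      coverage = if (total_pos > 0) sum(pos[hit]) / total_pos else NA_real_
    )
  })
  any_hit <- apply(cov_mat, 2, any)
  n_any <- sum(obs$n[any_hit])
  structure(
    list(
      type = type,
      conditions = conditions,
      outcome = attr(truth_table, "outcome"),
      implicants = implicants,
      expression = format_qca_expression(implicants, conditions),
      details = details,
      consistency = if (n_any > 0) sum(pos[any_hit]) / n_any else NA_real_,
      coverage = if (total_pos > 0) sum(pos[any_hit]) / total_pos else NA_real_
    ),
    class = "qca_solution"
  )
}

#' @export
print.qca_solution <- function(x, ...) {
  cat("csQCA ", x$type, " solution for outcome ", x$outcome, "\n  ",
      x$expression, "\n", sep = "")
  cat("  consistency ", format(round(x$consistency, 3)),
      ", coverage ", format(round(x$coverage, 3)), "\n", sep = "")
  invisible(x)
}

#' @rdname minimize_truth_table
#' @param x A `qca_solution`.
#' @param ... Unused.
#' @method tidy qca_solution
#' @export
tidy.qca_solution <- function(x, ...) x$details

#' @rdname minimize_truth_table
#' @method glance qca_solution
#' @export
glance.qca_solution <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    outcome = x$outcome,
    n_implicants = nrow(x$implicants),
    consistency = x$consistency,
    coverage = x$coverage,
    expression = x$expression
  )
}

#' Canonical expression string of a solution
#'
#' @param solution A `qca_solution`.
#' @return The canonical expression string (see [format_qca_expression()]).
#' @export
format_expression <- function(solution) {
  stopifnot(inherits(solution, "qca_solution"))
  solution$expression
}

#' Intermediate csQCA solution under directional expectations
#'
#' Sits between the complex and parsimonious solutions: only logical
#' remainders consistent with the stated directional expectations are
#' admitted as don't-cares. A remainder configuration is consistent when
#' every condition expected `"present"` takes value 1 in it and every
#' condition expected `"absent"` takes value 0; `"agnostic"` (the default
#' for every condition) imposes no constraint. With agnostic expectations
#' everywhere the result equals the parsimonious solution; with no
#' remainders in the table all three solution types coincide.
#'
#' @param truth_table A `qca_truth_table`.
#' @param directional_expectations Named character vector or list mapping
#'   condition names to `"present"`, `"absent"` or `"agnostic"`; conditions
#'   not mentioned are agnostic.
#' @inheritParams minimize_truth_table
#' @return A `qca_solution` with type `"intermediate"`.
#' @export
intermediate_solution <- function(truth_table,
                                  directional_expectations = NULL,
                                  contradiction_policy = c("off", "exclude")) {
  contradiction_policy <- match.arg(contradiction_policy)
  conditions <- attr(truth_table, "conditions")
  if (is.null(conditions)) {
    rlang::abort("input must be a qca_truth_table from build_truth_table()")
  }
  exp_vec <- stats::setNames(rep("agnostic", length(conditions)), conditions)
  if (!is.null(directional_expectations)) {
    de <- unlist(directional_expectations)
    unknown <- setdiff(names(de), conditions)
    if (length(unknown) > 0) {
      rlang::abort(paste0("directional expectation for unknown condition(s): ",
                          paste(unknown, collapse = ", ")))
    }
    bad <- setdiff(unname(de), c("present", "absent", "agnostic"))
    if (length(bad) > 0) {
      rlang::abort("expectations must be 'present', 'absent' or 'agnostic'")
    }
    exp_vec[names(de)] <- de
  }
  tt <- tibble::as_tibble(truth_table)
  rem <- tt[tt$OUT == "R", conditions, drop = FALSE]
  admissible <- rep(TRUE, nrow(rem))
  for (cond in conditions) {
    if (exp_vec[[cond]] == "present") {
      admissible <- admissible & rem[[cond]] == 1
    } else if (exp_vec[[cond]] == "absent") {
      admissible <- admissible & rem[[cond]] == 0
    }
  }
  minimize_truth_table(
    truth_table,
    use_remainders = FALSE,
    contradiction_policy = contradiction_policy,
    solution_type = "intermediate",
    dont_care = rem[admissible, , drop = FALSE]
  )
}

#' Necessity analysis of a condition expression for an outcome
#'
#' Necessity consistency is the share of outcome-positive cases covered by
#' the expression; necessity coverage (relevance) is the share of
#' expression-positive cases that show the outcome.
#'
#' @param matrix A `condition_matrix` from [binarize_conditions()].
#' @param condition_expression Boolean expression string over the
#'   conditions.
#' @param outcome Outcome column name; defaults to the matrix's outcome.
#' @return A one-row tibble with `consistency` and `coverage`.
#' @examples
#' cohort <- generate_cohort(n = 200, seed = 3)
#' m <- binarize_conditions(cohort, "EF")
#' necessity(m, "TWT")
#' @export
necessity <- function(matrix, condition_expression, outcome = NULL) {
  conditions <- attr(matrix, "conditions")
  if (is.null(conditions)) {
    rlang::abort("input must be a condition_matrix from binarize_conditions()")
  }
  if (is.null(outcome)) outcome <- attr(matrix, "outcome")
  if (!outcome %in% names(matrix)) {
    rlang::abort(paste0("unknown outcome column '", outcome, "'"))
  }
  y <- matrix[[outcome]]
  if (sum(y) == 0) {
    rlang::abort("outcome is constant 0: necessity consistency undefined")
  }
  x <- eval_qca_expression(condition_expression, matrix, conditions)
  tibble::tibble(
    consistency = sum(y == 1 & x == 1) / sum(y == 1),
    coverage = if (sum(x) > 0) sum(y == 1 & x == 1) / sum(x == 1) else NA_real_
  )
}
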