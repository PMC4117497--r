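# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written without reusing the package's
# Quine-McCluskey or Euler internals, so agreement is a genuine cross-check.

the_ef_recipe <- "ecg*txf*TWT + FMC*ecg*TWT"
the_los_recipe <- "FMC*ecg*TXF*TWT + FMC*ECG*txf*TWT"

# All 2^k condition configurations, in truth-table order.
full_factorial_grid <- function(conditions = stemi_stages) {
  grid <- do.call(expand.grid, stats::setNames(
    rep(list(0:1), length(conditions)), conditions))
  grid[do.call(order, grid), , drop = FALSE]
}

# Cohort-shaped full-factorial fixture: each configuration once, outcomes
# from the given recipes.
full_factorial_cohort <- function(ef = the_ef_recipe, los = the_los_recipe) {
  grid <- full_factorial_grid()
  grid$EF <- eval_qca_expression(ef, grid)
  grid$LOS <- eval_qca_expression(los, grid)
  grid
}

# Truth table from a vector of outputs ("1"/"0"/"R") over the 2^k grid:
# builds the case data the long way round, through binarize_conditions().
truth_table_from_outputs <- function(outputs, conditions = stemi_stages) {
  grid <- full_factorial_grid(conditions)
  observed <- outputs != "R"
  cases <- grid[observed, , drop = FALSE]
  cases$Y <- as.integer(outputs[observed] == "1")
  m <- binarize_conditions(cases, outcome = "Y", conditions = conditions)
  build_truth_table(m)
}

# --- brute-force minimum-cover oracle --------------------------------------
# An implicant is a vector over {0, 1, NA}. It is allowed if it covers no
# OFF configuration; a minimum cover is the smallest set of allowed
# implicants jointly covering every ON configuration. The search runs over
# maximal allowed implicants only (any cover can be lifted to maximal ones),
# by exhaustive subset enumeration in increasing size.
oracle_covers_one <- function(imp, cfg) {
  all(is.na(imp) | imp == cfg)
}

oracle_min_cover_size <- function(on, off) {
  k <- ncol(on)
  imps <- as.matrix(do.call(expand.grid, rep(list(c(0L, 1L, NA)), k)))
  allowed <- imps[vapply(seq_len(nrow(imps)), function(i) {
    nrow(off) == 0 ||
      !any(vapply(seq_len(nrow(off)), function(j) {
        oracle_covers_one(imps[i, ], off[j, ])
      }, logical(1)))
  }, logical(1)), , drop = FALSE]
  generalizes <- function(a, b) {
    # a's configuration set strictly contains b's
    all(is.na(a) | (!is.na(b) & a == b)) && sum(is.na(a)) > sum(is.na(b))
  }
  maximal <- allowed[vapply(seq_len(nrow(allowed)), function(i) {
    !any(vapply(seq_len(nrow(allowed)), function(j) {
      i != j && generalizes(allowed[j, ], allowed[i, ])
    }, logical(1)))
  }, logical(1)), , drop = FALSE]
  cover <- vapply(seq_len(nrow(maximal)), function(i) {
    vapply(seq_len(nrow(on)), function(j) {
      oracle_covers_one(maximal[i, ], on[j, ])
    }, logical(1))
  }, logical(nrow(on)))
  cover <- matrix(cover, nrow = nrow(on))   # on-rows x implicants
  if (any(rowSums(cover) == 0)) return(NA_integer_)  # uncoverable
  for (s in seq_len(ncol(cover))) {
    for (cc in utils::combn(ncol(cover), s, simplify = FALSE)) {
      if (all(rowSums(cover[, cc, drop = FALSE]) > 0)) return(s)
    }
  }
  NA_integer_
}

# Does a solution's implicant set reproduce exactly the ON-set on observed
# configurations and avoid the OFF-set?
solution_respects <- function(solution, on, off) {
  grid_on <- as.data.frame(on)
  grid_off <- as.data.frame(off)
  names(grid_on) <- solution$conditions
  names(grid_off) <- solution$conditions
  ok_on <- nrow(on) == 0 ||
    all(eval_qca_expression(solution$implicants, grid_on) == 1)
  ok_off <- nrow(off) == 0 ||
    all(eval_qca_expression(solution$implicants, grid_off) == 0)
  ok_on && ok_off
}

# --- hypoexponential pulse-response oracle ---------------------------------
# Survival function of a sum of independent exponentials with distinct
# rates: the in-system fraction after a unit pulse through the chain.
hypoexp_survival <- function(t, rates) {
  stopifnot(length(unique(rates)) == length(rates))
  vapply(t, function(tt) {
    sum(vapply(seq_along(rates), function(i) {
      prod(rates[-i] / (rates[-i] - rates[i])) * exp(-rates[i] * tt)
    }, numeric(1)))
  }, numeric(1))
}
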