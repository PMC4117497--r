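test_that("expression parsing and formatting follow the csQCA case convention", {
  imp <- parse_qca_expression("FMC*ecg*TWT", stemi_stages)
  expect_identical(unname(imp[1, ]), c(1L, 0L, NA, 1L))
  expect_identical(format_qca_expression(imp), "FMC*ecg*TWT")
  # round-trip on both published-style expressions
  for (expr in c(the_ef_recipe, the_los_recipe)) {
    expect_identical(
      format_qca_expression(parse_qca_expression(expr, stemi_stages)), expr)
  }
  # spacing-insensitive parse
  expect_identical(
    format_qca_expression(parse_qca_expression("ecg*txf*TWT+FMC*ecg*TWT")),
    the_ef_recipe)
  taut <- parse_qca_expression("TRUE", stemi_stages)
  expect_true(all(is.na(taut)))
  expect_identical(format_qca_expression(taut), "TRUE")
  expect_error(parse_qca_expression("FMC*XYZ"), "XYZ")
  expect_error(parse_qca_expression("FMC*fmc"), "contradictory")
})

test_that("binarization yields a validated case-by-condition matrix", {
  cohort <- generate_cohort(n = 29, seed = 7)
  m <- binarize_conditions(cohort, outcome = "EF")
  expect_identical(nrow(m), 29L)
  expect_identical(attr(m, "conditions"), stemi_stages)
  expect_identical(attr(m, "outcome"), "EF")
  expect_error(binarize_conditions(cohort, outcome = "NOPE"), "NOPE")
  bad <- cohort
  bad$FMC[1] <- 2L
  expect_error(binarize_conditions(bad, "EF"), "FMC")
})

test_that("truth tables partition configurations into 1/0/C/R", {
  ff <- full_factorial_cohort()
  tt <- build_truth_table(binarize_conditions(ff, "LOS"))
  expect_identical(nrow(tt), 16L)
  expect_identical(sum(tt$OUT == "R"), 0L)
  expect_identical(sum(tt$OUT == "1"), 2L)   # the two LOS minterms
  expect_identical(attr(tt, "n_cases"), 16L)

  one <- ff[1, ]
  tt1 <- build_truth_table(binarize_conditions(one, "LOS"))
  expect_identical(sum(tt1$OUT == "R"), 15L)
  expect_identical(sum(tt1$n), 1L)

  contradictory <- rbind(ff[1, ], ff[1, ])
  contradictory$LOS <- c(0L, 1L)
  ttc <- build_truth_table(binarize_conditions(contradictory, "LOS"))
  expect_identical(ttc$OUT[ttc$n > 0], "C")

  expect_error(build_truth_table(binarize_conditions(ff, "LOS"),
                                 inclusion_cutoff = 0.5), "inclusion_cutoff")
})

test_that("minimization reproduces the published-form delay expressions", {
  ff <- full_factorial_cohort()
  sol_ef <- minimize_truth_table(build_truth_table(binarize_conditions(ff, "EF")))
  expect_identical(format_expression(sol_ef), the_ef_recipe)
  expect_identical(nrow(sol_ef$implicants), 2L)

  sol_los <- minimize_truth_table(build_truth_table(binarize_conditions(ff, "LOS")))
  expect_identical(format_expression(sol_los), the_los_recipe)
  expect_identical(nrow(sol_los$implicants), 2L)

  # perfect sufficiency on a zero-noise fixture
  expect_equal(sol_ef$consistency, 1)
  expect_equal(sol_ef$coverage, 1)
  expect_identical(glance(sol_los)$n_implicants, 2L)
  expect_identical(nrow(tidy(sol_los)), 2L)
})

test_that("degenerate ON-sets minimize to the tautology or error", {
  all_on <- full_factorial_grid()
  all_on$Y <- 1L
  tt <- build_truth_table(binarize_conditions(all_on, "Y"))
  expect_identical(format_expression(minimize_truth_table(tt)), "TRUE")

  none_on <- full_factorial_grid()
  none_on$Y <- 0L
  tt0 <- build_truth_table(binarize_conditions(none_on, "Y"))
  expect_error(minimize_truth_table(tt0), "no positive")
})

test_that("minimization matches a brute-force oracle on all 3-condition tables", {
  conds <- c("A", "B", "C")
  grid <- as.matrix(full_factorial_grid(conds))
  for (mask in 1:255) {
    on_rows <- as.logical(bitwAnd(bitwShiftR(mask, 0:7), 1))
    outputs <- ifelse(on_rows, "1", "0")
    tt <- truth_table_from_outputs(outputs, conds)
    sol <- minimize_truth_table(tt)
    on <- grid[on_rows, , drop = FALSE]
    off <- grid[!on_rows, , drop = FALSE]
    expect_true(solution_respects(sol, on, off))
    expect_identical(nrow(sol$implicants), as.integer(oracle_min_cover_size(on, off)))
  }
})

test_that("minimization matches the oracle on random 4-condition tables with remainders", {
  grid <- as.matrix(full_factorial_grid())
  set.seed(77)
  for (rep in 1:200) {
    outputs <- sample(c("1", "0", "R"), 16, replace = TRUE,
                      prob = c(0.35, 0.45, 0.20))
    if (!any(outputs == "1")) next
    tt <- truth_table_from_outputs(outputs, stemi_stages)
    on <- grid[outputs == "1", , drop = FALSE]
    off <- grid[outputs == "0", , drop = FALSE]
    rem <- grid[outputs == "R", , drop = FALSE]

    complex <- minimize_truth_table(tt, use_remainders = FALSE)
    expect_true(solution_respects(complex, on, rbind(off, rem)))
    expect_identical(nrow(complex$implicants),
                     as.integer(oracle_min_cover_size(on, rbind(off, rem))))

    pars <- minimize_truth_table(tt, use_remainders = TRUE)
    expect_true(solution_respects(pars, on, off))
    expect_identical(nrow(pars$implicants),
                     as.integer(oracle_min_cover_size(on, off)))

    # containment: every complex implicant implies the parsimonious solution
    cfg_cols <- as.data.frame(grid)
    cpx_hits <- eval_qca_expression(complex$implicants, cfg_cols)
    par_hits <- eval_qca_expression(pars$implicants, cfg_cols)
    admissible <- outputs != "0"   # parsimonious may also claim remainders
    expect_true(all(par_hits[cpx_hits == 1 & admissible] == 1))
  }
})

test_that("planted recipes are recovered from zero-noise full-coverage cohorts", {
  grid <- full_factorial_grid()
  set.seed(31)
  for (rep in 1:8) {
    n_terms <- sample(1:3, 1)
    imp <- matrix(sample(c(0L, 1L, NA), n_terms * 4, replace = TRUE,
                         prob = c(0.3, 0.4, 0.3)), n_terms, 4,
                  dimnames = list(NULL, stemi_stages))
    planted <- grid
    planted$Y <- eval_qca_expression(imp, planted)
    if (!any(planted$Y == 1)) next
    sol <- minimize_truth_table(
      build_truth_table(binarize_conditions(planted, "Y")))
    expect_identical(eval_qca_expression(sol$implicants, grid),
                     eval_qca_expression(imp, grid))
  }
  # through the full generator path: large zero-noise cohort covering all 16
  cohort <- generate_cohort(n = 3000, seed = 5)
  tt_counts <- build_truth_table(binarize_conditions(cohort, "EF"))
  expect_identical(sum(tt_counts$OUT == "R"), 0L)
  sol <- minimize_truth_table(tt_counts)
  expect_identical(eval_qca_expression(sol$implicants, grid),
                   eval_qca_expression(the_ef_recipe, grid))
})

test_that("intermediate solutions sit between complex and parsimonious", {
  # no remainders: all three coincide on the recipe fixtures
  ff <- full_factorial_cohort()
  for (outcome in c("EF", "LOS")) {
    tt <- build_truth_table(binarize_conditions(ff, outcome))
    expected <- if (outcome == "EF") the_ef_recipe else the_los_recipe
    expect_identical(format_expression(intermediate_solution(tt)), expected)
    expect_identical(
      format_expression(intermediate_solution(
        tt, c(FMC = "present", ECG = "absent", TXF = "agnostic"))),
      expected)
  }
  # with remainders: agnostic expectations give the parsimonious solution,
  # fully constraining expectations give the complex one
  outputs <- rep("R", 16)
  grid <- full_factorial_grid()
  on_idx <- which(grid$FMC == 1 & grid$ECG == 0 & grid$TXF == 0 & grid$TWT == 1)
  off_idx <- which(grid$FMC == 0 & grid$TWT == 0)
  outputs[on_idx] <- "1"
  outputs[off_idx] <- "0"
  tt <- truth_table_from_outputs(outputs)
  pars <- minimize_truth_table(tt, use_remainders = TRUE)
  cpx <- minimize_truth_table(tt, use_remainders = FALSE)
  expect_identical(format_expression(intermediate_solution(tt)),
                   format_expression(pars))
  blocked <- intermediate_solution(
    tt, c(FMC = "absent", ECG = "present", TXF = "present", TWT = "absent"))
  expect_identical(format_expression(blocked), format_expression(cpx))
  expect_error(intermediate_solution(tt, c(NOPE = "present")), "NOPE")
})

test_that("necessity consistency and coverage behave as set measures", {
  cohort <- generate_cohort(n = 400, seed = 13)
  m <- binarize_conditions(cohort, "EF")
  # both EF recipe terms contain TWT, so TWT is necessary in recipe data
  nec <- necessity(m, "TWT")
  expect_equal(nec$consistency, 1)
  expect_true(nec$coverage >= 0 && nec$coverage <= 1)
  # tautology: consistency 1, coverage = outcome base rate
  taut <- necessity(m, "TRUE")
  expect_equal(taut$consistency, 1)
  expect_equal(taut$coverage, mean(cohort$EF))
  # TWT necessary implies its negation is never present among EF cases
  expect_equal(necessity(m, "twt")$consistency, 0)

  flat <- cohort
  flat$EF <- 0L
  expect_error(necessity(binarize_conditions(flat, "EF"), "TWT"), "constant 0")
})
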