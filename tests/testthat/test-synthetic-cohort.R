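test_that("degenerate noise-free one-class cohort reproduces the growth line exactly", {
  spec1 <- class_spec("only", 1, growth_means = c(0.7, 0, 0.4, 0),
                      eight_year_means = rep(0.2, 6), outcome_logit = 0)
  cfg <- cohort_config(
    n_children = 50L, class_specs = list(spec1), sibling_fraction = 0,
    growth_factor_cov = matrix(0, 4, 4), residual_variances = rep(0, 6),
    eight_year_variances = rep(0, 6),
    wave_response_rates = c(`6m` = 1, `18m` = 1, `3y` = 1, `5y` = 1, `8y` = 1),
    seed = 4L)
  coh <- generate_cohort(cfg)
  ch <- coh$children
  for (col in c("cbcl_int_18m", "cbcl_int_3y", "cbcl_int_5y"))
    expect_equal(ch[[col]], rep(0.7, 50))
  for (col in c("cbcl_ext_18m", "cbcl_ext_3y", "cbcl_ext_5y"))
    expect_equal(ch[[col]], rep(0.4, 50))
  expect_equal(ch$smfq_dep_8y, rep(0.2, 50))
})

test_that("with no sibling pairs every child has a distinct mother", {
  cfg <- cohort_config(n_children = 500L, sibling_fraction = 0, seed = 2L)
  coh <- generate_cohort(cfg)
  expect_equal(length(unique(coh$children$mother_id)), 500L)
})

test_that("generation is bit-reproducible given the seed", {
  cfg <- cohort_config(n_children = 400L, seed = 77L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$children, c2$children)
  expect_identical(c1$events, c2$events)
})

test_that("class proportions and outcome prevalence match the design at large n", {
  cfg <- cohort_config(n_children = 100000L, seed = 12L)
  coh <- generate_cohort(cfg)
  ch <- coh$children
  props <- design_props()
  emp <- table(factor(ch$class_true,
                      levels = paste0("profile", 1:5))) / nrow(ch)
  for (k in 1:5) {
    se <- sqrt(props[k] * (1 - props[k]) / nrow(ch))
    expect_lt(abs(emp[k] - props[k]), 3 * se)
  }
  ## Monte-Carlo prevalence converges to the logistic-model-implied value
  offs <- vapply(cfg$class_specs, `[[`, numeric(1), "outcome_logit")
  implied <- sum(props * (0.5 * plogis(cfg$base_rate_logit + offs) +
                            0.5 * plogis(cfg$base_rate_logit + offs +
                                           cfg$sex_effect_logit)))
  se <- sqrt(implied * (1 - implied) / nrow(ch))
  expect_lt(abs(mean(ch$emotional_disorder) - implied), 3 * se)
})

test_that("attrition follows configured wave response rates under MCAR", {
  cfg <- cohort_config(n_children = 20000L, seed = 3L)
  ch <- generate_cohort(cfg)$children
  for (w in names(cfg$wave_response_rates)) {
    rate <- cfg$wave_response_rates[[w]]
    se <- sqrt(rate * (1 - rate) / nrow(ch))
    expect_lt(abs(mean(ch[[paste0("attended_", w)]]) - rate), 4 * se)
    ## scores missing exactly when the wave was not attended
  }
  expect_true(all(is.na(ch$cbcl_int_3y[!ch$attended_3y])))
  expect_true(all(!is.na(ch$cbcl_int_3y[ch$attended_3y])))
})

test_that("MAR-on-covariate missingness depends on the maternal covariate", {
  cfg <- cohort_config(n_children = 20000L, seed = 3L,
                       missing_mechanism = "MAR-on-covariate")
  ch <- generate_cohort(cfg)$children
  hi <- ch$maternal_covariate > 0
  expect_gt(mean(ch$attended_5y[!hi]) - mean(ch$attended_5y[hi]), 0.05)
})

test_that("single-code ICD-10 events are classified per the outcome rules", {
  ev <- data.frame(child_id = 1:4,
                   icd10_code = c("F32.1", "F93.1", "F31", "F90.0"),
                   age_years = c(14, 12, 15, 13))
  out <- code_outcomes(ev)
  expect_equal(out$emotional_disorder, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$subcategory[1:3],
               c("depressive_only", "anxiety_only", "other"))
  expect_equal(out$onset_class[1], "adolescent_onset")
})

test_that("childhood codes followed by adolescent codes give persistent onset", {
  ev <- data.frame(child_id = c(1, 1), icd10_code = c("F32.0", "F32.1"),
                   age_years = c(8, 13))
  out <- code_outcomes(ev)
  expect_true(out$emotional_disorder)
  expect_equal(out$onset_class, "childhood_onset_persistent")
  expect_equal(out$age_first_emotional, 8)
  ## a childhood-only code never qualifies
  out2 <- code_outcomes(data.frame(child_id = 1, icd10_code = "F32.0",
                                   age_years = 8))
  expect_false(out2$emotional_disorder)
  expect_equal(out2$onset_class, "none")
})

test_that("depressive range F32-F34.1 has the documented boundary semantics", {
  codes <- c("F32", "F32.9", "F33.2", "F34.0", "F34.1", "F34.2", "F34",
             "F35.0")
  expected_dep <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  got <- vapply(codes, function(cd)
    trajprofile:::is_depressive_code(trajprofile:::parse_icd10(cd)),
    logical(1))
  expect_equal(unname(got), expected_dep)
  ## anxiety: F40-F41 or F93.0/1/2 only
  expect_true(trajprofile:::is_anxiety_code(trajprofile:::parse_icd10("F41.9")))
  expect_true(trajprofile:::is_anxiety_code(trajprofile:::parse_icd10("F93.2")))
  expect_false(trajprofile:::is_anxiety_code(trajprofile:::parse_icd10("F93.3")))
  expect_false(trajprofile:::is_anxiety_code(trajprofile:::parse_icd10("F93")))
})

test_that("unparseable codes are ignored with a warning", {
  ev <- data.frame(child_id = c(1, 1), icd10_code = c("garbage", "F32.1"),
                   age_years = c(11, 12))
  expect_warning(out <- code_outcomes(ev), "unparseable")
  expect_true(out$emotional_disorder)
})

test_that("subcategories partition the diagnosed set for arbitrary event lists", {
  set.seed(99)
  pool <- c("F32.0", "F33.1", "F34.1", "F40.0", "F41.9", "F93.0", "F93.2",
            "F30.0", "F31.9", "F39", "F92.0", "F93.8", "F90.0", "Z00.1")
  for (rep in 1:20) {
    n_ev <- sample(5:60, 1)
    ev <- data.frame(child_id = sample(1:25, n_ev, TRUE),
                     icd10_code = sample(pool, n_ev, TRUE),
                     age_years = round(runif(n_ev, 0, 18), 1))
    out <- code_outcomes(ev, child_ids = 1:25)
    n_diag <- sum(out$emotional_disorder)
    parts <- table(factor(out$subcategory,
                          levels = c("depressive_only", "anxiety_only",
                                     "both", "other")))
    expect_equal(sum(parts), n_diag)
    expect_true(all(out$subcategory[!out$emotional_disorder] == "none"))
  }
})

test_that("cohort CSVs round-trip through write_cohort", {
  cfg <- cohort_config(n_children = 120L, seed = 5L)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  back <- utils::read.csv(paths[1])
  expect_equal(nrow(back), 120L)
  expect_equal(back$cbcl_int_5y, coh$children$cbcl_int_5y)
  ev <- utils::read.csv(paths[2])
  expect_equal(names(ev), c("child_id", "icd10_code", "age_years"))
})

test_that("invalid configurations are rejected", {
  expect_error(class_spec("x", 1.2, rep(0, 4), rep(0, 6), 0), "proportion")
  expect_error(class_spec("x", 0.5, rep(0, 3), rep(0, 6), 0), "length 4")
  expect_error(cohort_config(class_specs = list(
    class_spec("a", 0.6, rep(0, 4), rep(0, 6), 0))), "sum to 1")
  bad_cov <- diag(4); bad_cov[1, 1] <- -1
  expect_error(cohort_config(growth_factor_cov = bad_cov), "definite")
  expect_error(cohort_config(wave_response_rates = rep(1.5, 5)), "rates")
})
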