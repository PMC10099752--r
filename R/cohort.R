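#' Define a latent developmental class
#'
#' A class (profile) is characterized by its population share, the means of
#' the four growth factors driving the early-childhood emotional and
#' behavioral problem trajectories, the means of the six middle-childhood
#' (8-year) symptom scales, and a log-odds offset for the distal adolescent
#' diagnosis.
#'
#' @param label Character label for the class.
#' @param proportion Population share in (0, 1).
#' @param growth_means Numeric 4-vector: emotional intercept, emotional slope
#'   (per year), behavioral intercept, behavioral slope (per year), on the
#'   standardized score scale.
#' @param eight_year_means Numeric 6-vector of standardized means for the
#'   8-year scales (depressive, anxiety, conduct, oppositional-defiant,
#'   hyperactivity, inattention).
#' @param outcome_logit Log-odds offset for the distal diagnosis relative to
#'   the cohort base rate.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(label, proportion, growth_means, eight_year_means,
                       outcome_logit) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!(is.numeric(proportion) && length(proportion) == 1L &&
        proportion > 0 && proportion <= 1))
    stop("`proportion` must be a single number in (0, 1]")
  if (length(growth_means) != 4L)
    stop("`growth_means` must have length 4 (int/slope x emotional/behavioral)")
  if (length(eight_year_means) != 6L)
    stop("`eight_year_means` must have length 6")
  structure(
    list(label = label, proportion = proportion,
         growth_means = as.numeric(growth_means),
         eight_year_means = as.numeric(eight_year_means),
         outcome_logit = as.numeric(outcome_logit)),
    class = "class_spec")
}

#' Default five-class specification
#'
#' Five developmental profiles of early-childhood emotional and behavioral
#' problems. Class proportions are the published profile counts
#' 3087/69522/4045/1074/4158 out of 81,886 (so they sum to one exactly);
#' profile 2 is the large normative reference class. Outcome log-odds offsets
#' equal the logs of the published profile-versus-reference odds ratios
#' (2.15, 1, 3.49, 5.00, 1.37). Trajectory and 8-year means are package
#' defaults chosen to emulate the qualitative profile shapes: profile 1
#' behavioral-dominant and increasing, profile 2 low and decreasing,
#' profile 3 emotionally increasing with elevated 8-year anxiety, profile 4
#' combined increasing emotional and behavioral problems with broadly
#' elevated 8-year symptoms, profile 5 moderate decreasing behavioral
#' problems.
#'
#' @return A list of five [class_spec()] objects.
#' @export
default_class_specs <- function() {
  counts <- c(3087, 69522, 4045, 1074, 4158)
  p <- counts / sum(counts)
  or <- c(2.15, 1, 3.49, 5.00, 1.37)
  list(
    class_spec("profile1", p[1],
               growth_means = c(-0.20, 0.02, 1.20, 0.25),
               eight_year_means = c(0.20, 0.20, 0.40, 0.80, 1.20, 1.20),
               outcome_logit = log(or[1])),
    class_spec("profile2", p[2],
               growth_means = c(-0.10, -0.05, -0.10, -0.05),
               eight_year_means = c(-0.15, -0.10, -0.10, -0.15, -0.15, -0.15),
               outcome_logit = log(or[2])),
    class_spec("profile3", p[3],
               growth_means = c(0.50, 0.45, 0.00, 0.00),
               eight_year_means = c(0.60, 1.30, 0.00, 0.20, 0.10, 0.30),
               outcome_logit = log(or[3])),
    class_spec("profile4", p[4],
               growth_means = c(0.00, 0.35, 1.00, 0.35),
               eight_year_means = c(1.30, 0.70, 1.20, 1.40, 1.40, 1.30),
               outcome_logit = log(or[4])),
    class_spec("profile5", p[5],
               growth_means = c(0.00, 0.00, 0.80, -0.15),
               eight_year_means = c(0.20, 0.10, 0.30, 0.70, 0.80, 0.80),
               outcome_logit = log(or[5]))
  )
}

default_growth_factor_cov <- function() {
  sds <- c(0.30, 0.08, 0.30, 0.08)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- -0.10   # intercept-slope, emotional
  R[3, 4] <- R[4, 3] <- -0.10   # intercept-slope, behavioral
  R[1, 3] <- R[3, 1] <- 0.30    # cross-process intercepts
  R[2, 4] <- R[4, 2] <- 0.15    # cross-process slopes
  diag(sds) %*% R %*% diag(sds)
}

#' Configure a synthetic cohort
#'
#' Bundles and validates everything [generate_cohort()] needs: sample size,
#' sibling structure, the latent class specification, within-class
#' covariance components, wave response rates and the missingness mechanism,
#' covariate effects and the outcome base rate.
#'
#' @param n_children Number of children.
#' @param class_specs List of [class_spec()]; proportions must sum to 1.
#' @param sibling_fraction Fraction of mothers contributing two children.
#' @param sibling_class_corr Probability that a second sibling inherits the
#'   first sibling's latent class rather than drawing independently.
#' @param growth_factor_cov 4x4 positive-definite covariance of the growth
#'   factors within class.
#' @param residual_variances Length-6 positive residual variances for the
#'   CBCL scores (emotional then behavioral, at 18 months, 3 and 5 years).
#' @param eight_year_variances Length-6 positive within-class variances for
#'   the 8-year scales.
#' @param wave_response_rates Named response rates in (0, 1] for waves
#'   `6m`, `18m`, `3y`, `5y`, `8y`.
#' @param missing_mechanism `"MCAR"` or `"MAR-on-covariate"`; under the
#'   latter, wave attendance odds decrease with a maternal covariate and for
#'   non-reference classes.
#' @param mar_strength Log-odds decrease in attendance per SD of the maternal
#'   covariate (MAR mechanism only).
#' @param mar_class_strength Log-odds decrease in attendance for children
#'   outside the largest (reference) class (MAR mechanism only).
#' @param sex_effect_logit Additive log-odds of diagnosis for girls.
#' @param birth_year_range Integer range of birth years.
#' @param base_rate_logit Baseline (reference-class, male) log-odds of the
#'   distal diagnosis.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_children = 10000L,
                          class_specs = default_class_specs(),
                          sibling_fraction = 0.15,
                          sibling_class_corr = 0.3,
                          growth_factor_cov = default_growth_factor_cov(),
                          residual_variances = rep(0.20, 6L),
                          eight_year_variances = rep(0.25, 6L),
                          wave_response_rates = c(`6m` = 0.90, `18m` = 0.77,
                                                  `3y` = 0.59, `5y` = 0.43,
                                                  `8y` = 0.43),
                          missing_mechanism = c("MCAR", "MAR-on-covariate"),
                          mar_strength = 0.5,
                          mar_class_strength = 0.3,
                          sex_effect_logit = 0.14,
                          birth_year_range = c(1999L, 2009L),
                          base_rate_logit = -3.66,
                          seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  props <- vapply(class_specs, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-12)
    stop("class proportions must sum to 1 (got ", format(sum(props)), ")")
  ev <- eigen((growth_factor_cov + t(growth_factor_cov)) / 2,
              symmetric = TRUE, only.values = TRUE)$values
  if (!isTRUE(all.equal(growth_factor_cov, t(growth_factor_cov))) ||
      min(ev) < -1e-10 * max(abs(ev), 1))
    stop("`growth_factor_cov` must be symmetric positive (semi)definite")
  if (length(residual_variances) != 6L || any(residual_variances < 0))
    stop("`residual_variances` must be 6 nonnegative numbers")
  if (length(eight_year_variances) != 6L || any(eight_year_variances < 0))
    stop("`eight_year_variances` must be 6 nonnegative numbers")
  if (length(wave_response_rates) != 5L ||
      any(wave_response_rates <= 0 | wave_response_rates > 1))
    stop("`wave_response_rates` must be 5 rates in (0, 1]")
  if (!(sibling_fraction >= 0 && sibling_fraction <= 1))
    stop("`sibling_fraction` must be in [0, 1]")
  structure(
    list(n_children = as.integer(n_children),
         class_specs = class_specs,
         sibling_fraction = sibling_fraction,
         sibling_class_corr = sibling_class_corr,
         growth_factor_cov = growth_factor_cov,
         residual_variances = as.numeric(residual_variances),
         eight_year_variances = as.numeric(eight_year_variances),
         wave_response_rates = stats::setNames(as.numeric(wave_response_rates),
                                               c("6m", "18m", "3y", "5y", "8y")),
         missing_mechanism = missing_mechanism,
         mar_strength = mar_strength,
         mar_class_strength = mar_class_strength,
         sex_effect_logit = sex_effect_logit,
         birth_year_range = as.integer(birth_year_range),
         base_rate_logit = base_rate_logit,
         seed = as.integer(seed)),
    class = "cohort_config")
}

## ICD-10 code pools used when translating the simulated binary diagnosis
## into registry-style events. Depressive codes fall in F32-F34.1, anxiety
## in F40-F41/F93.0-2, "other" are qualifying emotional codes outside both.
.icd_pools <- list(
  depressive = c("F32.0", "F32.1", "F32.9", "F33.0", "F33.1", "F34.1"),
  anxiety    = c("F40.0", "F40.1", "F41.0", "F41.1", "F41.9",
                 "F93.0", "F93.1", "F93.2"),
  other      = c("F30.0", "F31.9", "F39", "F92.0", "F93.8", "F93.9")
)

## Subcategory mix among the diagnosed, from the published breakdown
## 644 depressive / 1423 anxiety / 259 both / 1013 other of 3339.
.subcat_probs <- c(depressive_only = 644, anxiety_only = 1423,
                   both = 259, other = 1013) / 3339

#' Generate a synthetic cohort
#'
#' Simulates a registry-linked questionnaire cohort with the statistical
#' structure the downstream analyses assume: latent developmental classes,
#' linear growth in early-childhood emotional and behavioral problems,
#' class-shifted 8-year symptom scales, a negative-emotionality continuum
#' across waves, sibling clustering within mothers, wave attrition, and a
#' distal adolescent diagnosis coded as ICD-10 registry events.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: a list with `children` (one row per
#'   child; scored scales at attended waves, covariates, mother id, the
#'   hidden `class_true` label and coded outcome columns) and `events`
#'   (registry-style rows `child_id`, `icd10_code`, `age_years`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_children
  K <- length(config$class_specs)
  props <- vapply(config$class_specs, `[[`, numeric(1), "proportion")
  labels <- vapply(config$class_specs, `[[`, character(1), "label")

  ## mothers: a sibling_fraction of mothers contribute two children
  f <- config$sibling_fraction
  n_mothers <- max(1L, round(n / (1 + f)))
  n_pairs <- n - n_mothers
  if (n_pairs < 0) { n_mothers <- n; n_pairs <- 0L }
  mother_id <- c(seq_len(n_mothers), seq_len(n_pairs))
  mother_id <- sort(mother_id)

  ## latent class: second siblings inherit the first sibling's class with
  ## probability sibling_class_corr, else draw independently
  cls <- sample.int(K, n, replace = TRUE, prob = props)
  dup <- duplicated(mother_id)
  if (any(dup)) {
    first_of <- match(mother_id[dup], mother_id)
    inherit <- stats::runif(sum(dup)) < config$sibling_class_corr
    cls[which(dup)[inherit]] <- cls[first_of[inherit]]
  }

  sex <- sample(c("male", "female"), n, replace = TRUE)
  birth_year <- sample(seq(config$birth_year_range[1],
                           config$birth_year_range[2]), n, replace = TRUE)
  maternal_cov <- stats::rnorm(n_mothers)[mother_id]

  ## growth factors and CBCL scores
  spec <- growth_spec()
  alpha <- t(vapply(config$class_specs, `[[`, numeric(4), "growth_means"))
  eta <- matrix(stats::rnorm(n * 4L), n, 4L) %*%
    psd_sqrt(config$growth_factor_cov) + alpha[cls, , drop = FALSE]
  cbcl <- eta %*% t(spec$loading) +
    matrix(stats::rnorm(n * 6L), n, 6L) %*%
    diag(sqrt(config$residual_variances))
  colnames(cbcl) <- cbcl_columns()

  ## 8-year symptom scales
  nu <- t(vapply(config$class_specs, `[[`, numeric(6), "eight_year_means"))
  y8 <- nu[cls, , drop = FALSE] +
    matrix(stats::rnorm(n * 6L), n, 6L) %*%
    diag(sqrt(config$eight_year_variances))
  colnames(y8) <- eight_year_columns()

  ## negative-emotionality continuum: loads on the emotional growth process
  ## at each wave's age; other temperament dimensions are class-free noise
  ages <- c(`6m` = 0.5, `18m` = 1.5, `3y` = 3, `5y` = 5, `8y` = 8)
  emo_level <- function(age) eta[, 1] + eta[, 2] * (age - 1.5)
  ne <- sapply(ages, function(a) 0.6 * emo_level(a) + stats::rnorm(n, sd = 0.8))
  temperament <- data.frame(
    icq_neg_6m = ne[, "6m"],
    icq_pos_6m = -0.3 * ne[, "6m"] + stats::rnorm(n, sd = 0.95),
    eas_emo_18m = ne[, "18m"], eas_emo_3y = ne[, "3y"], eas_emo_5y = ne[, "5y"],
    nhipic_neur_8y = ne[, "8y"],
    eas_shy_18m = stats::rnorm(n), eas_soc_18m = stats::rnorm(n),
    eas_act_18m = stats::rnorm(n),
    eas_shy_3y = stats::rnorm(n), eas_soc_3y = stats::rnorm(n),
    eas_act_3y = stats::rnorm(n),
    eas_shy_5y = stats::rnorm(n), eas_soc_5y = stats::rnorm(n),
    eas_act_5y = stats::rnorm(n))

  ## wave attendance
  rates <- config$wave_response_rates
  attended <- matrix(NA, n, 5L, dimnames = list(NULL, names(rates)))
  ref_class <- which.max(props)
  for (w in seq_along(rates)) {
    lp <- stats::qlogis(rates[w])
    if (config$missing_mechanism == "MAR-on-covariate")
      lp <- lp - config$mar_strength * maternal_cov -
        config$mar_class_strength * (cls != ref_class)
    attended[, w] <- stats::runif(n) < stats::plogis(lp)
  }
  wave_of <- c(icq_neg_6m = "6m", icq_pos_6m = "6m",
               eas_emo_18m = "18m", eas_shy_18m = "18m", eas_soc_18m = "18m",
               eas_act_18m = "18m",
               eas_emo_3y = "3y", eas_shy_3y = "3y", eas_soc_3y = "3y",
               eas_act_3y = "3y",
               eas_emo_5y = "5y", eas_shy_5y = "5y", eas_soc_5y = "5y",
               eas_act_5y = "5y",
               nhipic_neur_8y = "8y",
               cbcl_int_18m = "18m", cbcl_ext_18m = "18m",
               cbcl_int_3y = "3y", cbcl_ext_3y = "3y",
               cbcl_int_5y = "5y", cbcl_ext_5y = "5y",
               smfq_dep_8y = "8y", scared_anx_8y = "8y",
               rsdbd_cd_8y = "8y", rsdbd_odd_8y = "8y",
               rsdbd_hyp_8y = "8y", rsdbd_inat_8y = "8y")

  children <- data.frame(child_id = seq_len(n), mother_id = mother_id,
                         sex = sex, birth_year = birth_year,
                         maternal_covariate = maternal_cov,
                         class_true = labels[cls],
                         temperament, cbcl, y8,
                         check.names = FALSE)
  for (col in names(wave_of))
    children[[col]][!attended[, wave_of[col]]] <- NA_real_
  for (w in colnames(attended))
    children[[paste0("attended_", w)]] <- attended[, w]

  ## distal diagnosis from the logistic model
  offs <- vapply(config$class_specs, `[[`, numeric(1), "outcome_logit")
  lp <- config$base_rate_logit + offs[cls] +
    config$sex_effect_logit * (sex == "female")
  diagnosed <- stats::runif(n) < stats::plogis(lp)

  ## co-occurring ADHD (hyperkinetic F90 codes; not an emotional disorder)
  p_adhd <- c(0.15, 0.03, 0.04, 0.25, 0.12)[pmin(cls, 5L)]
  if (K != 5L) p_adhd <- rep(0.04, n)
  adhd <- stats::runif(n) < p_adhd

  events <- simulate_events(which(diagnosed), which(adhd), n)
  children$adhd <- adhd

  out <- code_outcomes(events, min_age = 10, n_children = n)
  children <- cbind(children, out[match(children$child_id, out$child_id),
                                  setdiff(names(out), "child_id")])
  rownames(children) <- NULL

  structure(list(children = children, events = events, config = config),
            class = "cohort")
}

## Registry-style ICD-10 events for diagnosed children (plus childhood-only
## codes for a sliver of the undiagnosed, and F90 events for ADHD).
simulate_events <- function(diag_ids, adhd_ids, n) {
  ev <- list()
  if (length(diag_ids)) {
    sub <- sample(names(.subcat_probs), length(diag_ids), replace = TRUE,
                  prob = .subcat_probs)
    for (i in seq_along(diag_ids)) {
      id <- diag_ids[i]
      codes <- switch(sub[i],
        depressive_only = sample(.icd_pools$depressive, 1L),
        anxiety_only    = sample(.icd_pools$anxiety, 1L),
        both            = c(sample(.icd_pools$depressive, 1L),
                            sample(.icd_pools$anxiety, 1L)),
        other           = sample(.icd_pools$other, 1L))
      ages <- round(stats::runif(length(codes), 10, 18), 2)
      ## childhood-onset persistent fraction (461/3339 in the source design)
      if (stats::runif(1) < 461 / 3339) {
        codes <- c(codes[1], codes)
        ages <- c(round(stats::runif(1, 4, 9.9), 2), ages)
      }
      ev[[length(ev) + 1L]] <- data.frame(child_id = id, icd10_code = codes,
                                          age_years = ages)
    }
  }
  ## childhood-only emotional codes among undiagnosed children (never qualify)
  others <- setdiff(seq_len(n), diag_ids)
  n_child_only <- round(0.005 * length(others))
  if (n_child_only > 0) {
    ids <- sample(others, n_child_only)
    ev[[length(ev) + 1L]] <- data.frame(
      child_id = ids,
      icd10_code = sample(unlist(.icd_pools), n_child_only, replace = TRUE),
      age_years = round(stats::runif(n_child_only, 3, 9.9), 2))
  }
  if (length(adhd_ids)) {
    ev[[length(ev) + 1L]] <- data.frame(
      child_id = adhd_ids, icd10_code = "F90.0",
      age_years = round(stats::runif(length(adhd_ids), 6, 18), 2))
  }
  if (!length(ev))
    return(data.frame(child_id = integer(), icd10_code = character(),
                      age_years = numeric()))
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$child_id, ev$age_years), ]
  rownames(ev) <- NULL
  ev
}

#' Write a cohort to tidy CSV files
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files written
#'   (`children.csv`, `events.csv`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("children.csv", "events.csv"))
  utils::write.csv(cohort$children, paths[1], row.names = FALSE, na = "NA")
  utils::write.csv(cohort$events, paths[2], row.names = FALSE, na = "NA")
  invisible(paths)
}

#' @export
print.cohort <- function(x, ...) {
  ch <- x$children
  cat("Synthetic cohort:", nrow(ch), "children,",
      length(unique(ch$mother_id)), "mothers\n")
  cat("Diagnosed with emotional disorder:", sum(ch$emotional_disorder),
      sprintf("(%.2f%%)\n", 100 * mean(ch$emotional_disorder)))
  tab <- table(ch$class_true)
  cat("Latent classes:\n")
  print(round(tab / nrow(ch), 4))
  invisible(x)
}

cbcl_columns <- function() {
  c("cbcl_int_18m", "cbcl_int_3y", "cbcl_int_5y",
    "cbcl_ext_18m", "cbcl_ext_3y", "cbcl_ext_5y")
}

eight_year_columns <- function() {
  c("smfq_dep_8y", "scared_anx_8y", "rsdbd_cd_8y", "rsdbd_odd_8y",
    "rsdbd_hyp_8y", "rsdbd_inat_8y")
}
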