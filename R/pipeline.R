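#' Demographic descriptives by outcome group
#'
#' Counts and percentages for configured fields in the diagnosed,
#' undiagnosed and total groups (percentage = 100 * count / group n, two
#' decimals). Categorical fields are tabulated per level; logical fields
#' report the `TRUE` count.
#'
#' @param cohort A `cohort` or children data frame with the outcome coded.
#' @param fields Character vector of columns to describe.
#' @param outcome Binary outcome column (default `"emotional_disorder"`).
#' @return Data frame with one row per field level and columns `n`/`pct`
#'   for each group.
#' @export
descriptives <- function(cohort, fields = c("sex", "adhd"),
                         outcome = "emotional_disorder") {
  df <- if (inherits(cohort, "cohort")) cohort$children else cohort
  stopifnot(outcome %in% names(df), all(fields %in% names(df)))
  groups <- list(diagnosed = df[df[[outcome]] %in% TRUE, , drop = FALSE],
                 undiagnosed = df[df[[outcome]] %in% FALSE, , drop = FALSE],
                 total = df)
  if (any(vapply(groups[1:2], nrow, integer(1)) == 0))
    stop("empty outcome group")
  rows <- list()
  for (f in fields) {
    v <- df[[f]]
    levels_f <- if (is.logical(v)) TRUE else sort(unique(v[!is.na(v)]))
    for (lev in levels_f) {
      row <- data.frame(field = f, level = as.character(lev))
      for (g in names(groups)) {
        gv <- groups[[g]][[f]]
        cnt <- sum(gv == lev, na.rm = TRUE)
        row[[paste0("n_", g)]] <- cnt
        row[[paste0("pct_", g)]] <-
          round(100 * cnt / nrow(groups[[g]]), 2)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare wave response rates between outcome groups
#'
#' Per-wave response proportions for children with and without the
#' adolescent diagnosis, with a two-proportion z-test (chi-squared without
#' continuity correction) per wave.
#'
#' @param cohort A `cohort` or children data frame containing
#'   `attended_<wave>` indicator columns.
#' @param outcome Binary outcome column.
#' @return Data frame: wave, response proportion in each group, difference,
#'   z statistic and p-value.
#' @export
attrition_check <- function(cohort, outcome = "emotional_disorder") {
  df <- if (inherits(cohort, "cohort")) cohort$children else cohort
  waves <- grep("^attended_", names(df), value = TRUE)
  if (!length(waves)) stop("no attended_<wave> columns found")
  g1 <- df[[outcome]] %in% TRUE
  g0 <- df[[outcome]] %in% FALSE
  if (!sum(g1) || !sum(g0)) stop("empty outcome group")
  rows <- lapply(waves, function(wv) {
    p1 <- mean(df[[wv]][g1]); p0 <- mean(df[[wv]][g0])
    n1 <- sum(g1); n0 <- sum(g0)
    pbar <- (p1 * n1 + p0 * n0) / (n1 + n0)
    se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
    z <- if (se == 0) 0 else (p1 - p0) / se
    data.frame(wave = sub("^attended_", "", wv),
               rate_diagnosed = p1, rate_undiagnosed = p0,
               difference = p1 - p0, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> screen -> growth -> class enumeration ->
#' chosen-K fit -> 3-step distal estimation -> reports, writing tidy CSVs,
#' model JSON and a run manifest (config hash, seeds, versions) to an output
#' directory. Given identical configuration and seeds the result files are
#' byte-identical.
#'
#' @param config List (or path to a YAML file) with entries: `n_children`,
#'   `seed`, `K_range`, `chosen_K` (default: smallest accepted K by BIC),
#'   `n_starts`, `outcome` (`any`, `anxiety`, `depressive`,
#'   `adolescent_onset`, `childhood_onset`), `stratify` (`none` or `sex`),
#'   `traits` (default: a standard trait set), `distal_covariates`
#'   (logical; include sex and birth year in step 3).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results (`cohort`, `screen`,
#'   `growth`, `enumeration`, `mixture`, `distal`, `manifest`).
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set an explicit seed")
  cfg <- list(
    n_children = config$n_children %||% 5000L,
    seed = as.integer(config$seed),
    K_range = config$K_range %||% 1:5,
    chosen_K = config$chosen_K,
    n_starts = config$n_starts %||% 5L,
    outcome = config$outcome %||% "any",
    stratify = config$stratify %||% "none",
    traits = config$traits %||%
      c("icq_neg_6m", "eas_emo_18m", "eas_emo_3y", "eas_emo_5y",
        "nhipic_neur_8y", "cbcl_int_18m", "cbcl_int_3y", "cbcl_int_5y",
        "cbcl_ext_18m", "cbcl_ext_3y", "cbcl_ext_5y",
        "smfq_dep_8y", "scared_anx_8y"),
    distal_covariates = isTRUE(config$distal_covariates))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. cohort
  cohort <- stage("simulate", {
    gc_cfg <- cohort_config(n_children = cfg$n_children, seed = cfg$seed)
    generate_cohort(gc_cfg)
  })
  write_cohort(cohort, file.path(out_dir, "cohort"))
  ch <- cohort$children

  ## 2. outcome variant
  ch$outcome_bin <- stage("outcome", switch(cfg$outcome,
    any = ch$emotional_disorder,
    anxiety = ch$subcategory %in% c("anxiety_only", "both"),
    depressive = ch$subcategory %in% c("depressive_only", "both"),
    adolescent_onset = ch$onset_class == "adolescent_onset",
    childhood_onset = ch$onset_class == "childhood_onset_persistent",
    stop("unknown outcome variant: ", cfg$outcome)))

  ## 3. descriptives and attrition
  desc <- stage("descriptives",
                descriptives(ch, fields = c("sex", "adhd"),
                             outcome = "outcome_bin"))
  utils::write.csv(desc, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  attr_tab <- stage("attrition", attrition_check(ch, outcome = "outcome_bin"))
  utils::write.csv(attr_tab, file.path(out_dir, "attrition.csv"),
                   row.names = FALSE)

  ## 4. association screen
  screen <- stage("screen", run_screen(
    ch, traits = cfg$traits, outcome = "outcome_bin",
    stratify = if (cfg$stratify == "none") NULL else cfg$stratify))
  screen$significant <- screen$p_fdr < 0.05
  utils::write.csv(screen, file.path(out_dir, "screen.csv"),
                   row.names = FALSE)

  ## 5. growth model on standardized CBCL
  Xg <- as.matrix(ch[, cbcl_columns()])
  Xg <- apply(Xg, 2, standardize)
  growth <- stage("growth", fit_growth(Xg))

  ## 6. class enumeration and chosen-K fit
  X8 <- as.matrix(ch[, eight_year_columns()])
  X8 <- apply(X8, 2, standardize)
  Xm <- cbind(Xg, X8)
  keep <- rowSums(!is.na(Xm)) > 0
  enum <- stage("enumeration", enumerate_classes(
    Xm[keep, ], K_range = cfg$K_range, n_starts = cfg$n_starts,
    seed = cfg$seed))
  utils::write.csv(enum, file.path(out_dir, "enumeration.csv"),
                   row.names = FALSE)
  chosen_K <- cfg$chosen_K %||% {
    ok <- enum[enum$accepted & enum$converged, ]
    if (!nrow(ok)) stop("no accepted class solution")
    ok$K[which.min(ok$bic)]
  }
  mixture <- attr(enum, "fits")[[as.character(chosen_K)]] %||%
    stage("mixture", fit_mixture(Xm[keep, ], chosen_K,
                                 n_starts = cfg$n_starts, seed = cfg$seed))
  write_mixture_json(mixture, file.path(out_dir, "mixture.json"))
  utils::write.csv(as.data.frame(mixture$posterior),
                   file.path(out_dir, "posterior.csv"), row.names = FALSE)

  ## 7. 3-step distal estimation
  distal <- stage("distal", {
    Q <- classification_table(mixture)
    covs <- if (cfg$distal_covariates)
      cbind(female = as.numeric(ch$sex[keep] == "female"),
            birth_year = ch$birth_year[keep] -
              mean(ch$birth_year[keep])) else NULL
    fit_distal(mixture$modal, Q, ch$outcome_bin[keep], covariates = covs,
               cluster_ids = ch$mother_id[keep])
  })
  utils::write.csv(distal$or_table, file.path(out_dir, "distal.csv"),
                   row.names = FALSE)

  ## 8. manifest
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed, chosen_K = chosen_K,
    mixture_best_start_seed = mixture$best_start_seed,
    n_children = cfg$n_children,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("trajprofile")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, descriptives = desc, attrition = attr_tab,
                 screen = screen, growth = growth, enumeration = enum,
                 mixture = mixture, distal = distal, manifest = manifest))
}

#' Match fitted mixture classes to design profiles
#'
#' One-to-one greedy assignment of fitted classes to the classes of a
#' generating specification, by distance between the 12-dimensional implied
#' mean vectors (growth-implied CBCL means plus 8-year means).
#'
#' @param fit An `lpa_mixture`.
#' @param specs List of [class_spec()] (e.g. [default_class_specs()]).
#' @return Integer vector: `map[k]` is the spec index matched to fitted
#'   class `k`.
#' @export
match_classes <- function(fit, specs) {
  L <- fit$spec$loading
  fitted_mu <- cbind(fit$alphas %*% t(L), fit$nu)
  truth_mu <- t(vapply(specs, function(s)
    c(drop(L %*% s$growth_means), s$eight_year_means), numeric(12)))
  D <- as.matrix(stats::dist(rbind(fitted_mu, truth_mu)))
  D <- D[seq_len(nrow(fitted_mu)), nrow(fitted_mu) + seq_len(nrow(truth_mu)),
         drop = FALSE]
  map <- integer(nrow(D))
  for (i in seq_len(min(dim(D)))) {
    idx <- which(D == min(D), arr.ind = TRUE)[1, ]
    map[idx[1]] <- idx[2]
    D[idx[1], ] <- Inf
    D[, idx[2]] <- Inf
  }
  map
}

#' Distal-outcome recovery experiment
#'
#' Simulates cohorts from the default five-class design (class outcome
#' offsets equal to the logs of the design odds ratios), fits the K = 5
#' growth-structured profile model, runs the 3-step distal estimator, and
#' returns the recovered odds ratio of a target class versus the reference
#' (largest) class. With `replicates > 1` the log odds ratios are averaged
#' across replicate cohorts to reduce Monte-Carlo error.
#'
#' @param seed Integer seed.
#' @param n Children per cohort (default 10,000).
#' @param replicates Number of replicate cohorts (default 1).
#' @param target_label Class label whose versus-reference OR is reported
#'   (default `"profile4"`, the combined-symptom class).
#' @param n_starts EM starts per fit (default 20).
#' @return List: `odds_ratio` (exp of the mean recovered log-OR),
#'   `per_replicate` ORs, `true_or`, `n`, `replicates`.
#' @export
distal_recovery_experiment <- function(seed, n = 10000L, replicates = 1L,
                                       target_label = "profile4",
                                       n_starts = 20L) {
  specs <- default_class_specs()
  labels <- vapply(specs, `[[`, character(1), "label")
  props <- vapply(specs, `[[`, numeric(1), "proportion")
  ref_lab <- labels[which.max(props)]
  true_or <- exp(specs[[match(target_label, labels)]]$outcome_logit -
                   specs[[which.max(props)]]$outcome_logit)
  seeds <- derive_seeds(seed, replicates)
  ors <- vapply(seq_len(replicates), function(r) {
    cfg <- cohort_config(n_children = n, seed = seeds[r])
    coh <- generate_cohort(cfg)
    ch <- coh$children
    Xm <- as.matrix(ch[, c(cbcl_columns(), eight_year_columns())])
    keep <- rowSums(!is.na(Xm)) > 0
    fit <- fit_mixture(Xm[keep, ], K = 5, n_starts = n_starts,
                       seed = seeds[r], control = list(n_final = 5))
    Q <- classification_table(fit)
    dst <- fit_distal(fit$modal, Q, ch$emotional_disorder[keep],
                      cluster_ids = ch$mother_id[keep])
    map <- match_classes(fit, specs)
    ref_k <- which(map == which.max(props))[1]
    tgt_k <- which(map == match(target_label, labels))[1]
    exp(dst$theta[tgt_k] - dst$theta[ref_k])
  }, numeric(1))
  list(odds_ratio = exp(mean(log(ors))), per_replicate = ors,
       true_or = true_or, n = n, replicates = replicates)
}
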