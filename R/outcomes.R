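## ICD-10 outcome coding.
##
## Adolescent "emotional disorder" comprises mood disorders (F30-F39),
## anxiety disorders (F40-F41) and emotional disorders with childhood onset
## (F92-F93), registered at or after the age cut (10 years by default).
## Non-overlapping subcategories: depressive disorders F32-F34.1 and anxiety
## disorders F40-F41 or F93.0/F93.1/F93.2.

## Parse "F32.1" into chapter letter, category integer and subcategory digit
## (NA when absent). Unparseable codes return NULL.
parse_icd10 <- function(code) {
  m <- regmatches(code, regexec("^([A-Z])([0-9]{2})(?:\\.([0-9]))?$",
                                toupper(trimws(code))))[[1]]
  if (!length(m)) return(NULL)
  list(letter = m[2], category = as.integer(m[3]),
       sub = if (m[4] == "") NA_integer_ else as.integer(m[4]))
}

## Is a parsed code inside the interval [lo, hi] where bounds are given as
## category + optional subcategory (e.g. F32-F34.1)? A bare category code
## (no subcategory digit) counts only when its whole category lies inside
## the interval, since e.g. a bare "F34" cannot be confirmed to be <= F34.1.
icd_in_range <- function(p, letter, lo_cat, hi_cat, hi_sub = NA) {
  if (is.null(p) || p$letter != letter) return(FALSE)
  if (p$category < lo_cat || p$category > hi_cat) return(FALSE)
  if (is.na(hi_sub) || p$category < hi_cat) return(TRUE)
  ## boundary category with a subcategory cap
  if (is.na(p$sub)) return(FALSE)
  p$sub <= hi_sub
}

is_emotional_code <- function(p) {
  icd_in_range(p, "F", 30L, 39L) || icd_in_range(p, "F", 40L, 41L) ||
    icd_in_range(p, "F", 92L, 93L)
}

is_depressive_code <- function(p) icd_in_range(p, "F", 32L, 34L, hi_sub = 1L)

is_anxiety_code <- function(p) {
  icd_in_range(p, "F", 40L, 41L) ||
    (!is.null(p) && p$letter == "F" && p$category == 93L &&
       !is.na(p$sub) && p$sub %in% 0:2)
}

#' Code registry diagnosis events into adolescent outcome records
#'
#' Classifies each child's ICD-10 events into the combined emotional-disorder
#' outcome (mood F30-F39, anxiety F40-F41, childhood-onset emotional F92-F93,
#' registered at age `min_age` or later), the non-overlapping depressive
#' (F32-F34.1) and anxiety (F40-F41, F93.0-F93.2) subcategories, and an
#' onset classification relative to the age cut: children whose first
#' qualifying code predates `min_age` but who also have a qualifying code at
#' or after it are `childhood_onset_persistent`; diagnosed children whose
#' first qualifying code is at or after the cut are `adolescent_onset`.
#'
#' @param events Data frame with columns `child_id`, `icd10_code`,
#'   `age_years`.
#' @param min_age Age cut in years (default 10).
#' @param child_ids Optional vector of ids for which records are wanted;
#'   defaults to the ids present in `events`.
#' @param n_children Convenience alternative to `child_ids`: ids `1:n`.
#' @return Data frame, one row per child: `child_id`, `emotional_disorder`,
#'   `subcategory` (`depressive_only`, `anxiety_only`, `both`, `other`,
#'   `none`), `onset_class` (`adolescent_onset`,
#'   `childhood_onset_persistent`, `none`) and `age_first_emotional`.
#'   Unparseable codes are dropped with a warning naming them.
#' @export
code_outcomes <- function(events, min_age = 10, child_ids = NULL,
                          n_children = NULL) {
  stopifnot(all(c("child_id", "icd10_code", "age_years") %in% names(events)))
  if (nrow(events) && any(events$age_years < 0))
    stop("`age_years` must be nonnegative")
  if (is.null(child_ids))
    child_ids <- if (!is.null(n_children)) seq_len(n_children) else
      sort(unique(events$child_id))

  parsed <- lapply(events$icd10_code, parse_icd10)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    warning("ignoring ", sum(bad), " unparseable ICD-10 code(s): ",
            paste(unique(events$icd10_code[bad]), collapse = ", "))
    events <- events[!bad, , drop = FALSE]
    parsed <- parsed[!bad]
  }
  qual <- vapply(parsed, is_emotional_code, logical(1))
  dep <- vapply(parsed, is_depressive_code, logical(1))
  anx <- vapply(parsed, is_anxiety_code, logical(1))
  adolescent <- nrow(events) > 0 & events$age_years >= min_age

  out <- data.frame(child_id = child_ids, emotional_disorder = FALSE,
                    subcategory = "none", onset_class = "none",
                    age_first_emotional = NA_real_)
  if (nrow(events)) {
    by_child <- split(seq_len(nrow(events)), events$child_id)
    for (id_chr in names(by_child)) {
      i <- by_child[[id_chr]]
      row <- match(events$child_id[i[1L]], out$child_id)
      if (is.na(row)) next
      q <- i[qual[i]]
      qa <- q[adolescent[q]]
      if (!length(qa)) next
      has_dep <- any(dep[qa]); has_anx <- any(anx[qa])
      out$emotional_disorder[row] <- TRUE
      out$subcategory[row] <- if (has_dep && has_anx) "both"
        else if (has_dep) "depressive_only"
        else if (has_anx) "anxiety_only"
        else "other"
      first_age <- min(events$age_years[q])
      out$age_first_emotional[row] <- first_age
      out$onset_class[row] <- if (first_age < min_age)
        "childhood_onset_persistent" else "adolescent_onset"
    }
  }
  rownames(out) <- NULL
  out
}
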