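#' RECIST 1.1 rule configuration
#'
#' Parameters of the rule-based response classifier. Defaults follow RECIST
#' 1.1: lesions are measurable from 10 mm longest axial diameter, at most
#' five target lesions are summed, partial response needs at least a 30%
#' decrease of the diameter sum, progressive disease at least a 20% increase
#' that is also at least 5 mm in absolute terms. The absolute-increase clause
#' can be switched off (`pd_min_absolute_increase_mm = 0`) because simple
#' rule-based implementations sometimes omit it.
#'
#' @param min_measurable_diameter_mm Measurability threshold in mm
#'   (inclusive; default 10).
#' @param max_targets Maximum number of target lesions per timepoint
#'   (default 5).
#' @param pr_threshold_pct Percent change at or below which the case is PR
#'   (default -30).
#' @param pd_threshold_pct Percent change at or above which the case is PD
#'   (default +20).
#' @param pd_min_absolute_increase_mm Minimum absolute increase of the
#'   diameter sum, in mm, additionally required for PD (default 5; set 0 to
#'   disable).
#' @param cr_requires_zero_targets If `TRUE` (default), complete response is
#'   declared when no measurable target remains at follow-up (target sum 0);
#'   if `FALSE`, CR additionally requires the follow-up mask to contain no
#'   lesion of any size.
#' @return A `recist_config` list.
#' @export
recist_config <- function(min_measurable_diameter_mm = 10,
                          max_targets = 5,
                          pr_threshold_pct = -30,
                          pd_threshold_pct = 20,
                          pd_min_absolute_increase_mm = 5,
                          cr_requires_zero_targets = TRUE) {
  stopifnot(min_measurable_diameter_mm > 0,
            max_targets >= 1,
            pr_threshold_pct < 0, pd_threshold_pct > 0,
            pd_min_absolute_increase_mm >= 0)
  structure(
    list(min_measurable_diameter_mm = min_measurable_diameter_mm,
         max_targets = as.integer(max_targets),
         pr_threshold_pct = pr_threshold_pct,
         pd_threshold_pct = pd_threshold_pct,
         pd_min_absolute_increase_mm = pd_min_absolute_increase_mm,
         cr_requires_zero_targets = isTRUE(cr_requires_zero_targets)),
    class = "recist_config"
  )
}

#' RECIST response categories, in severity order
#' @export
RECIST_CATEGORIES <- c("CR", "PR", "SD", "PD")

#' Keep only measurable lesions
#'
#' A lesion is measurable when its longest axial diameter reaches the
#' configured threshold (inclusive boundary: a lesion of exactly 10 mm is
#' measurable under the defaults).
#'
#' @param lesions A `lesion_set` from [extract_lesions()].
#' @param cfg A [recist_config()].
#' @return A `lesion_set` containing only the measurable lesions.
#' @export
filter_measurable <- function(lesions, cfg = recist_config()) {
  stopifnot(inherits(lesions, "lesion_set"))
  keep <- vapply(lesions$lesions, function(l)
    l$longest_axial_diameter_mm >= cfg$min_measurable_diameter_mm, logical(1))
  lesions$lesions <- lesions$lesions[keep]
  lesions
}

#' Select target lesions
#'
#' Chooses up to `cfg$max_targets` of the largest measurable lesions as the
#' targets whose diameters are summed. Ordering is by diameter (descending),
#' ties broken by larger volume, then by smaller lesion id, so selection is
#' deterministic.
#'
#' @param measurable A `lesion_set` that already passed [filter_measurable()].
#' @param cfg A [recist_config()].
#' @return A `target_set`: data frame of the selected targets (`lesion_id`,
#'   `diameter_mm`, `volume_mm3`) plus attribute-free field
#'   `sum_of_diameters_mm`; an empty input gives an empty target set with
#'   sum 0.
#' @export
select_targets <- function(measurable, cfg = recist_config()) {
  stopifnot(inherits(measurable, "lesion_set"))
  if (length(measurable$lesions) == 0L) {
    tab <- data.frame(lesion_id = integer(0), diameter_mm = numeric(0),
                      volume_mm3 = numeric(0))
  } else {
    tab <- data.frame(
      lesion_id = vapply(measurable$lesions, `[[`, 0L, "lesion_id"),
      diameter_mm = vapply(measurable$lesions, `[[`, 0,
                           "longest_axial_diameter_mm"),
      volume_mm3 = vapply(measurable$lesions, `[[`, 0, "volume_mm3"))
    ord <- order(-tab$diameter_mm, -tab$volume_mm3, tab$lesion_id)
    tab <- tab[ord, , drop = FALSE]
    tab <- utils::head(tab, cfg$max_targets)
    rownames(tab) <- NULL
  }
  structure(list(targets = tab, sum_of_diameters_mm = sum(tab$diameter_mm)),
            class = "target_set")
}

#' Percent change of the diameter sum
#'
#' The driver of the size-based response categories: the relative change of
#' the sum of target diameters from baseline to follow-up, in percent.
#'
#' @param baseline_sum,followup_sum Diameter sums in mm; the baseline sum
#'   must be positive (a patient without measurable baseline disease is not
#'   assessable under RECIST).
#' @return `100 * (followup_sum - baseline_sum) / baseline_sum`.
#' @export
percent_change <- function(baseline_sum, followup_sum) {
  if (!is.finite(baseline_sum) || baseline_sum <= 0)
    stop("no measurable baseline disease: baseline diameter sum must be > 0")
  100 * (followup_sum - baseline_sum) / baseline_sum
}

#' Count-based new-lesion detection
#'
#' New lesions are flagged when the follow-up examination yields more target
#' lesions than baseline. This is the count-comparison rule of simple
#' automated pipelines; no spatial matching of lesions between timepoints is
#' attempted (canonical RECIST identifies new lesions by appearance, which
#' requires lesion tracking this rule deliberately avoids).
#'
#' @param n_baseline_targets,n_followup_targets Non-negative target counts.
#' @return `TRUE` iff the follow-up count exceeds the baseline count.
#' @export
detect_new_lesions <- function(n_baseline_targets, n_followup_targets) {
  stopifnot(n_baseline_targets >= 0, n_followup_targets >= 0)
  n_followup_targets > n_baseline_targets
}

#' Classify a baseline/follow-up pair into CR / PR / SD / PD
#'
#' Applies the response rules in fixed order: (1) new lesions force PD;
#' (2) a follow-up target sum of zero is CR; (3) an increase of at least
#' `pd_threshold_pct` percent that is also at least
#' `pd_min_absolute_increase_mm` mm is PD; (4) a decrease of at least
#' `|pr_threshold_pct|` percent is PR; (5) anything else is SD. Every rule
#' consulted is recorded in `rule_trace`, so a classification can be audited.
#'
#' @param baseline,followup `target_set` objects from [select_targets()].
#' @param new_lesions Logical flag, normally from [detect_new_lesions()].
#' @param cfg A [recist_config()].
#' @param followup_has_any_lesion Optional logical; only consulted when
#'   `cfg$cr_requires_zero_targets` is `FALSE`, in which case CR additionally
#'   requires it to be `FALSE`.
#' @return A `response_assessment`: baseline/follow-up target sets, percent
#'   change, new-lesion flag, `category` and `rule_trace`.
#' @export
classify_response <- function(baseline, followup, new_lesions,
                              cfg = recist_config(),
                              followup_has_any_lesion = NA) {
  stopifnot(inherits(baseline, "target_set"), inherits(followup, "target_set"))
  bsum <- baseline$sum_of_diameters_mm
  fsum <- followup$sum_of_diameters_mm
  change <- percent_change(bsum, fsum)
  trace <- character(0)
  category <- NULL

  if (isTRUE(new_lesions)) {
    trace <- c(trace, "new lesions detected -> PD")
    category <- "PD"
  } else {
    trace <- c(trace, "no new lesions")
    if (fsum == 0 &&
        (cfg$cr_requires_zero_targets || isFALSE(followup_has_any_lesion))) {
      trace <- c(trace, "follow-up target sum is 0 -> CR")
      category <- "CR"
    } else if (change >= cfg$pd_threshold_pct &&
               (fsum - bsum) >= cfg$pd_min_absolute_increase_mm) {
      trace <- c(trace, sprintf(
        "change %+.1f%% >= %+g%% and increase %.1f mm >= %g mm -> PD",
        change, cfg$pd_threshold_pct, fsum - bsum,
        cfg$pd_min_absolute_increase_mm))
      category <- "PD"
    } else if (change <= cfg$pr_threshold_pct) {
      trace <- c(trace, sprintf("change %+.1f%% <= %+g%% -> PR",
                                change, cfg$pr_threshold_pct))
      category <- "PR"
    } else {
      trace <- c(trace, sprintf("change %+.1f%% within (%+g%%, %+g%%) -> SD",
                                change, cfg$pr_threshold_pct,
                                cfg$pd_threshold_pct))
      category <- "SD"
    }
  }

  structure(
    list(baseline_targets = baseline,
         followup_targets = followup,
         percent_change = change,
         new_lesions = isTRUE(new_lesions),
         category = category,
         rule_trace = trace,
         config = cfg),
    class = "response_assessment"
  )
}

#' End-to-end response assessment of a mask pair
#'
#' The full automated pipeline for one patient: per timepoint, lesions are
#' extracted from the tumour mask within the liver mask, filtered for
#' measurability and reduced to targets; the two target sets then feed the
#' new-lesion rule, the percent change and the classifier. Targets are
#' re-derived independently at follow-up (no lesion identity tracking across
#' timepoints). The whole chain is deterministic.
#'
#' @param baseline_tumor,baseline_liver,followup_tumor,followup_liver
#'   [label_volume] masks; liver masks may be `NULL` to skip organ gating.
#'   Each timepoint's tumour/liver pair must share a grid.
#' @param cfg A [recist_config()].
#' @param connectivity Connectivity passed to [extract_lesions()].
#' @return A `response_assessment` (see [classify_response()]) with the two
#'   per-timepoint `lesion_set`s attached as `baseline_lesions` /
#'   `followup_lesions`.
#' @export
assess_pair <- function(baseline_tumor, baseline_liver,
                        followup_tumor, followup_liver,
                        cfg = recist_config(), connectivity = 26) {
  b_all <- extract_lesions(baseline_tumor, baseline_liver, connectivity)
  f_all <- extract_lesions(followup_tumor, followup_liver, connectivity)
  b_meas <- filter_measurable(b_all, cfg)
  f_meas <- filter_measurable(f_all, cfg)
  b_tgt <- select_targets(b_meas, cfg)
  f_tgt <- select_targets(f_meas, cfg)
  if (b_tgt$sum_of_diameters_mm <= 0)
    stop("not assessable under RECIST (no measurable baseline disease)")
  newles <- detect_new_lesions(nrow(b_tgt$targets), nrow(f_tgt$targets))
  res <- classify_response(b_tgt, f_tgt, newles, cfg,
                           followup_has_any_lesion = length(f_all$lesions) > 0L)
  res$baseline_lesions <- b_all
  res$followup_lesions <- f_all
  res
}

#' @export
print.response_assessment <- function(x, ...) {
  cat(sprintf("RECIST response: %s\n", x$category))
  cat(sprintf("  baseline sum: %.1f mm over %d target(s)\n",
              x$baseline_targets$sum_of_diameters_mm,
              nrow(x$baseline_targets$targets)))
  cat(sprintf("  follow-up sum: %.1f mm over %d target(s)\n",
              x$followup_targets$sum_of_diameters_mm,
              nrow(x$followup_targets$targets)))
  cat(sprintf("  percent change: %+.1f%%; new lesions: %s\n",
              x$percent_change, x$new_lesions))
  cat("  rule trace:\n")
  for (r in x$rule_trace) cat("    -", r, "\n")
  invisible(x)
}
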