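#' Confusion matrix of response assessments
#'
#' Counts reference-vs-rater category pairs in the fixed severity order
#' CR, PR, SD, PD (reference on rows, rater on columns). Labels are matched
#' case-insensitively.
#'
#' @param pairs Data frame with columns `reference` and `rater` (values among
#'   CR/PR/SD/PD; a `case_id` column is allowed and used in error messages).
#' @return A 4x4 integer matrix with dimnames `reference` x `rater`.
#' @export
response_confusion <- function(pairs) {
  pairs <- normalize_pairs(pairs)
  tab <- table(factor(pairs$reference, levels = RECIST_CATEGORIES),
               factor(pairs$rater, levels = RECIST_CATEGORIES))
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(reference = RECIST_CATEGORIES,
                              rater = RECIST_CATEGORIES))
  m
}

normalize_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0,
            all(c("reference", "rater") %in% names(pairs)))
  ids <- if ("case_id" %in% names(pairs)) pairs$case_id else seq_len(nrow(pairs))
  for (col in c("reference", "rater")) {
    v <- toupper(trimws(as.character(pairs[[col]])))
    bad <- !v %in% RECIST_CATEGORIES
    if (any(bad))
      stop(sprintf("unknown %s label '%s' for case %s",
                   col, pairs[[col]][which(bad)[1]], ids[which(bad)[1]]))
    pairs[[col]] <- v
  }
  pairs
}

#' Accuracy with an exact binomial confidence interval
#'
#' Overall agreement proportion (the diagonal mass of the confusion matrix)
#' with a Clopper-Pearson exact interval, the construction whose asymmetric
#' bounds are typically quoted alongside small-cohort accuracies. A Wilson
#' score interval is available as an alternative.
#'
#' @param confusion A square count matrix (reference rows, rater columns),
#'   e.g. from [response_confusion()].
#' @param alpha Significance level; default 0.05 for a 95% interval.
#' @param method `"clopper-pearson"` (default, exact) or `"wilson"`.
#' @return List with `accuracy`, `ci` (length-2), `n_correct`, `n_total`.
#' @export
accuracy_ci <- function(confusion, alpha = 0.05,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  correct <- sum(diag(confusion))
  if (method == "clopper-pearson") {
    ci <- as.numeric(stats::binom.test(correct, total,
                                       conf.level = 1 - alpha)$conf.int)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- correct / total
    den <- 1 + z^2 / total
    center <- (p + z^2 / (2 * total)) / den
    half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / den
    ci <- c(max(0, center - half), min(1, center + half))
  }
  list(accuracy = correct / total, ci = ci,
       n_correct = correct, n_total = total)
}

#' Cohen's kappa with an asymptotic confidence interval
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' categorical raters, with `p_e` from the marginal products. The interval
#' uses the standard large-sample variance of the unweighted kappa (the
#' Fleiss-Cohen-Everitt asymptotic formula), clipped to `[-1, 1]`; linear or
#' quadratic weights are available for ordinal use. The degenerate case of
#' two identical constant raters has `p_e = 1`; agreement is then perfect
#' and kappa is returned as 1 with a zero-width interval and a warning.
#'
#' @param pairs Data frame with `reference` and `rater` columns (CR/PR/SD/PD).
#' @param alpha Significance level; default 0.05.
#' @param weights `"unweighted"` (default), `"linear"` or `"quadratic"`.
#' @return List with `kappa`, `ci`, `se`, `p_observed`, `p_expected`, `n`.
#' @export
cohen_kappa_ci <- function(pairs, alpha = 0.05,
                           weights = c("unweighted", "linear", "quadratic")) {
  weights <- match.arg(weights)
  pairs <- normalize_pairs(pairs)
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 pairs")
  k <- length(RECIST_CATEGORIES)
  p <- response_confusion(pairs) / n
  w <- kappa_weight_matrix(k, weights)
  r_marg <- rowSums(p); c_marg <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r_marg, c_marg))
  if (1 - pe < .Machine$double.eps^0.5) {
    warning("both raters constant and identical: kappa degenerate, returned as 1")
    return(list(kappa = 1, ci = c(1, 1), se = 0,
                p_observed = po, p_expected = pe, n = n))
  }
  kap <- (po - pe) / (1 - pe)
  # large-sample variance of weighted kappa (Fleiss, Cohen & Everitt 1969)
  wbar_i <- as.numeric(w %*% c_marg)   # row-conditional expected weights
  wbar_j <- as.numeric(t(w) %*% r_marg)
  term <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    term <- term + p[i, j] *
      (w[i, j] - (wbar_i[i] + wbar_j[j]) * (1 - kap))^2
  }
  var_k <- (term - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - alpha / 2)
  ci <- pmin(pmax(kap + c(-1, 1) * z * se, -1), 1)
  list(kappa = kap, ci = ci, se = se, p_observed = po, p_expected = pe, n = n)
}

kappa_weight_matrix <- function(k, weights) {
  d <- abs(outer(seq_len(k), seq_len(k), `-`))
  switch(weights,
         unweighted = (d == 0) * 1,
         linear = 1 - d / (k - 1),
         quadratic = 1 - (d / (k - 1))^2)
}

#' AUC of a categorical response assessment against a reference
#'
#' Reduces the four-category assessment to a single discrimination number.
#' In `ordinal` mode (default) the rater's category is scored by its
#' severity rank (CR < PR < SD < PD) and the AUC is the Mann-Whitney
#' concordance of that score against the binarized reference responder
#' status (responders CR/PR vs non-responders SD/PD), with the usual 1/2
#' convention for ties. In `macro_ovr` mode a one-vs-rest AUC is computed
#' per reference category present and macro-averaged. Both constructions
#' are common reductions for multi-class assessments; they are not
#' interchangeable and the mode is always explicit in results.
#'
#' @param pairs Data frame with `reference` and `rater` columns.
#' @param mode `"ordinal"` (default) or `"macro_ovr"`.
#' @return The AUC in `[0, 1]`.
#' @export
response_auc <- function(pairs, mode = c("ordinal", "macro_ovr")) {
  mode <- match.arg(mode)
  pairs <- normalize_pairs(pairs)
  sev <- match(pairs$rater, RECIST_CATEGORIES)
  if (mode == "ordinal") {
    nonresp <- pairs$reference %in% c("SD", "PD")
    if (all(nonresp) || !any(nonresp))
      stop("AUC undefined: reference has a single responder class")
    r <- pROC::roc(response = nonresp, predictor = sev,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
  } else {
    present <- intersect(RECIST_CATEGORIES, unique(pairs$reference))
    if (length(present) < 2)
      stop("AUC undefined: reference has a single class")
    aucs <- vapply(present, function(cls) {
      pos <- pairs$reference == cls
      # score: how strongly the rater asserts this class (negative rank
      # distance keeps higher = more likely positive)
      score <- -abs(sev - match(cls, RECIST_CATEGORIES))
      r <- pROC::roc(response = pos, predictor = score,
                     levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
      as.numeric(pROC::auc(r))
    }, numeric(1))
    mean(aucs)
  }
}

#' Full agreement summary for a set of response pairs
#'
#' @param pairs Data frame with `reference` and `rater` columns.
#' @param alpha Significance level for both intervals.
#' @param auc_mode Mode passed to [response_auc()].
#' @return An `agreement_result`: `confusion`, `accuracy` (with CI), `kappa`
#'   (with CI) and `auc` (`NA` when undefined for the given labels).
#' @export
agreement_summary <- function(pairs, alpha = 0.05, auc_mode = "ordinal") {
  conf <- response_confusion(pairs)
  auc <- tryCatch(response_auc(pairs, auc_mode), error = function(e) NA_real_)
  structure(
    list(confusion = conf,
         accuracy = accuracy_ci(conf, alpha),
         kappa = cohen_kappa_ci(pairs, alpha),
         auc = auc, auc_mode = auc_mode),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("confusion (reference rows x rater columns):\n")
  print(x$confusion)
  cat(sprintf("accuracy %.3f (95%%CI %.3f-%.3f)\n",
              x$accuracy$accuracy, x$accuracy$ci[1], x$accuracy$ci[2]))
  cat(sprintf("kappa    %.3f (95%%CI %.3f-%.3f)\n",
              x$kappa$kappa, x$kappa$ci[1], x$kappa$ci[2]))
  cat(sprintf("AUC      %s (%s)\n",
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc), x$auc_mode))
  invisible(x)
}
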