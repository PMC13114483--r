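#' Coefficient of variation of a reduced scattering map
#'
#' `CV = sd / mean` computed over all valid pixels of the global mu_s_prime
#' map, using the population standard deviation. Bruising increases tissue
#' heterogeneity and therefore the CV, making it the step-1 discriminator
#' between non-bruised and bruised samples.
#'
#' @param mu_s_prime_map Matrix of reduced scattering values, mm^-1.
#' @param mask Optional logical matrix of pixels to include (defaults to
#'   all finite pixels).
#' @param population Use the population (divide by N) standard deviation;
#'   set `FALSE` for the sample (N-1) convention.
#' @return Scalar CV (unitless).
#' @export
coefficient_of_variation <- function(mu_s_prime_map, mask = NULL,
                                     population = TRUE) {
  v <- if (is.null(mask)) as.numeric(mu_s_prime_map) else mu_s_prime_map[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no valid pixels in the mask")
  m <- mean(v)
  if (!(m > 0)) stop("mean must be > 0 for a coefficient of variation")
  s <- if (population) sqrt(mean((v - m)^2)) else stats::sd(v)
  s / m
}

#' Bruised-to-sound mean ratio
#'
#' `M = mean(mu_s_prime over bruised region) / mean(mu_s_prime over the
#' adjacent sound region)` of the same sample. Severe bruising depresses
#' mu_s_prime strongly, so lower M indicates a more severe bruise.
#'
#' @param mu_s_prime_map Matrix of reduced scattering values, mm^-1.
#' @param bruise_mask,sound_mask Non-empty, disjoint logical matrices.
#' @return Scalar mean ratio M.
#' @export
mean_ratio <- function(mu_s_prime_map, bruise_mask, sound_mask) {
  if (!any(bruise_mask) || !any(sound_mask)) stop("both masks must be non-empty")
  if (any(bruise_mask & sound_mask)) stop("masks must be disjoint")
  md <- mean(mu_s_prime_map[bruise_mask], na.rm = TRUE)
  mn <- mean(mu_s_prime_map[sound_mask], na.rm = TRUE)
  if (!(mn > 0)) stop("sound-region mean must be > 0")
  md / mn
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over the unique scores and computes sensitivity (TPR)
#' and 1 - specificity (FPR) at each, with the AUC obtained by trapezoidal
#' integration — numerically identical to concordant-pair counting with
#' ties counted 1/2. The `orientation` states whether a *lower* score
#' indicates the positive class (the convention for the mean ratio, where
#' lower M means severe).
#'
#' @param scores Numeric scores, one per sample.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class.
#' @param orientation `"lower"` if smaller scores indicate positives,
#'   `"higher"` otherwise.
#' @return Object of class `roc_analysis`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, plus the inputs.
#' @export
roc_curve <- function(scores, labels, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  s <- if (orientation == "lower") -scores else scores
  # sweep: classify positive when s > t; thresholds between consecutive
  # unique scores plus sentinels give every attainable operating point
  us <- sort(unique(s))
  thr <- c(-Inf, us, Inf)
  tpr <- fpr <- numeric(length(thr))
  np <- sum(labels)
  nn <- sum(!labels)
  for (i in seq_along(thr)) {
    call_pos <- s > thr[i]
    tpr[i] <- sum(call_pos & labels) / np
    fpr[i] <- sum(call_pos & !labels) / nn
  }
  # ties at a score are handled by the mid-point correction of the
  # trapezoid rule over the (fpr, tpr) staircase
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                                 utils::tail(tpr[ord], -1)) / 2)
  thr_out <- if (orientation == "lower") -thr else thr
  structure(list(thresholds = thr_out, tpr = tpr, fpr = fpr,
                 auc = abs(auc), scores = scores, labels = labels,
                 orientation = orientation),
            class = "roc_analysis")
}

#' Youden index of an operating point
#'
#' `Youden = sensitivity + specificity - 1`.
#'
#' @param sensitivity,specificity Operating-point rates in `[0, 1]` (or
#'   percentages in `[0, 100]`, detected and rescaled).
#' @return Youden index in `[-1, 1]`.
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity > 1) || any(specificity > 1)) {
    sensitivity <- sensitivity / 100
    specificity <- specificity / 100
  }
  sensitivity + specificity - 1
}

#' Youden-optimal threshold of a ROC sweep
#'
#' Maximizes sensitivity + specificity - 1 over the sweep. Ties are broken
#' toward higher sensitivity, then toward the lower threshold value.
#'
#' @param roc A `roc_analysis` from [roc_curve()].
#' @return List with `threshold`, `youden`, `sensitivity`, `specificity`.
#' @export
youden_optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_analysis"))
  yj <- roc$tpr + (1 - roc$fpr) - 1
  best <- which(yj == max(yj))
  if (length(best) > 1) {
    best <- best[roc$tpr[best] == max(roc$tpr[best])]
  }
  if (length(best) > 1) {
    vals <- roc$thresholds[best]
    best <- best[which.min(vals)]
  }
  list(threshold = roc$thresholds[best], youden = yj[best],
       sensitivity = roc$tpr[best], specificity = 1 - roc$fpr[best])
}

#' Step-1 bruised / non-bruised call from a CV score
#'
#' Samples with CV strictly above the threshold are called bruised;
#' boundary equality is called non-bruised.
#'
#' @param cv CV score(s).
#' @param threshold Decision threshold.
#' @return Character vector `"bruised"` / `"non-bruised"`.
#' @export
classify_bruised <- function(cv, threshold) {
  ifelse(cv > threshold, "bruised", "non-bruised")
}

#' Step-2 severity grade from a mean ratio
#'
#' Mean ratios strictly below the threshold are graded severe; boundary
#' equality is graded mild.
#'
#' @param m Mean ratio(s).
#' @param threshold Decision threshold.
#' @return Character vector `"severe"` / `"mild"`.
#' @export
classify_severity <- function(m, threshold) {
  ifelse(m < threshold, "severe", "mild")
}

#' Misclassification arithmetic of a severity confusion table
#'
#' Given fault counts per grade and the per-grade sample totals, computes
#' per-grade and overall misclassification rates (faults / totals).
#'
#' @param faults Named numeric vector of misclassified counts per grade.
#' @param totals Named numeric vector of sample counts per grade (same
#'   names).
#' @return Data frame with per-grade rows plus a `total` row; rates as
#'   fractions.
#' @export
misclassification_rates <- function(faults, totals) {
  stopifnot(all(names(faults) == names(totals)), all(faults <= totals))
  out <- data.frame(grade = c(names(faults), "total"),
                    n = c(unname(totals), sum(totals)),
                    faults = c(unname(faults), sum(faults)))
  out$rate <- out$faults / out$n
  out
}

#' Two-step bruise discrimination pipeline
#'
#' Step 1 classifies each sample as bruised / non-bruised from the global
#' CV of its mu_s_prime map, with the CV threshold selected by maximizing
#' the Youden index on the same cohort (or supplied fixed). Step 2 grades
#' the samples *called* bruised as mild / severe from the bruised-to-sound
#' mean ratio, again with a Youden-selected (or fixed) threshold, and
#' reports confusion counts and misclassification rates.
#'
#' @param samples List of per-sample lists with elements `mu_s_prime`
#'   (matrix), `bruise_mask`, `sound_mask`, `truth_bruised` (logical) and
#'   `truth_severity` (`"mild"`/`"severe"`/`NA`), optional `valid` mask.
#' @param cv_threshold,m_threshold Fixed thresholds; `NULL` selects them by
#'   Youden on this cohort.
#' @return List with per-sample `scores` (data frame), the two thresholds,
#'   the two `roc_analysis` objects (where computable), step-1 accuracy and
#'   the step-2 misclassification table.
#' @export
two_step_pipeline <- function(samples, cv_threshold = NULL,
                              m_threshold = NULL) {
  cv <- vapply(samples, function(s) {
    coefficient_of_variation(s$mu_s_prime, s$valid)
  }, numeric(1))
  truth_bruised <- vapply(samples, function(s) isTRUE(s$truth_bruised),
                          logical(1))
  roc1 <- NULL
  if (is.null(cv_threshold)) {
    roc1 <- roc_curve(cv, truth_bruised, orientation = "higher")
    cv_threshold <- youden_optimal_threshold(roc1)$threshold
  }
  call1 <- classify_bruised(cv, cv_threshold)
  acc1 <- mean((call1 == "bruised") == truth_bruised)

  called_idx <- which(call1 == "bruised")
  scores <- data.frame(sample = seq_along(samples), cv = cv,
                       truth_bruised = truth_bruised, call = call1,
                       mean_ratio = NA_real_, grade = NA_character_,
                       stringsAsFactors = FALSE)
  roc2 <- NULL
  mis <- NULL
  if (length(called_idx) == 0) {
    note <- "no samples called bruised; severity grading skipped"
  } else {
    note <- NULL
    m <- vapply(called_idx, function(i) {
      s <- samples[[i]]
      mean_ratio(s$mu_s_prime, s$bruise_mask, s$sound_mask)
    }, numeric(1))
    scores$mean_ratio[called_idx] <- m
    sev_truth <- vapply(samples[called_idx],
                        function(s) identical(s$truth_severity, "severe"),
                        logical(1))
    has_truth <- vapply(samples[called_idx],
                        function(s) !is.null(s$truth_severity) &&
                          !is.na(s$truth_severity), logical(1))
    if (is.null(m_threshold) && length(unique(sev_truth[has_truth])) == 2) {
      roc2 <- roc_curve(m[has_truth], sev_truth[has_truth],
                        orientation = "lower")
      m_threshold <- youden_optimal_threshold(roc2)$threshold
    }
    if (!is.null(m_threshold)) {
      scores$grade[called_idx] <- classify_severity(m, m_threshold)
      if (any(has_truth)) {
        truth_grade <- ifelse(sev_truth[has_truth], "severe", "mild")
        pred_grade <- scores$grade[called_idx][has_truth]
        faults <- c(mild = sum(truth_grade == "mild" & pred_grade != "mild"),
                    severe = sum(truth_grade == "severe" &
                                   pred_grade != "severe"))
        totals <- c(mild = sum(truth_grade == "mild"),
                    severe = sum(truth_grade == "severe"))
        mis <- misclassification_rates(faults, totals)
      }
    }
  }
  list(scores = scores, cv_threshold = cv_threshold,
       m_threshold = m_threshold, roc_step1 = roc1, roc_step2 = roc2,
       step1_accuracy = acc1, misclassification = mis, note = note)
}
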