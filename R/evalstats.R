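## Diagnostic-accuracy evaluation and paired comparison machinery: ROC/AUC
## with DeLong variance, Youden cutoffs, confusion-matrix metrics with exact
## binomial CIs, DeLong / McNemar / Kosinski paired tests, calibration
## tables, decision-curve net benefit, and subgroup AUC comparisons.

.check_binary <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
}

## DeLong structural components: V10[i] = mean_j psi(x_i, y_j) over negatives,
## V01[j] likewise over positives; psi = 1, 1/2, 0.
.delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n, 0)
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m, 0)
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney estimator (ties count 1/2); the 95% CI uses the
#' DeLong structural-components variance with a normal approximation,
#' clipped to `[0, 1]`.
#'
#' @param scores numeric scores (higher = more disease-like)
#' @param labels 0/1 reference labels
#' @param conf confidence level
#' @return `roc_result` list: `auc`, `ci`, `se`, `curve` (data.frame with
#'   threshold/sensitivity/specificity at every distinct score), `scores`,
#'   `labels`
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  .check_binary(labels)
  stopifnot(length(scores) == length(labels))
  cmp <- .delong_components(scores, labels)
  vr <- var(cmp$v10) / cmp$m + var(cmp$v01) / cmp$n
  se <- sqrt(vr)
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, cmp$auc - z * se), min(1, cmp$auc + z * se))
  thr <- sort(unique(scores))
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[labels == 1] >= t), 0),
    specificity = vapply(thr, function(t) mean(scores[labels == 0] < t), 0))
  structure(list(auc = cmp$auc, ci = ci, se = se, curve = curve,
                 scores = scores, labels = labels), class = "roc_result")
}

#' Youden-optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the observed scores
#' under the "positive if score >= threshold" convention; ties are broken
#' toward the higher (more specific) threshold.
#'
#' @param roc `roc_result` from [roc_auc()]
#' @return the cutoff value
#' @export
youden_cutoff <- function(roc) {
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  best <- max(j)
  max(roc$curve$threshold[j >= best - 1e-12])
}

#' Confusion matrix at a cutoff
#'
#' Positive call iff `score >= cutoff`.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels
#' @param cutoff threshold
#' @return `confusion_matrix` list with tp, fp, fn, tn
#' @export
confusion_at <- function(scores, labels, cutoff) {
  stopifnot(is.finite(cutoff))
  call_pos <- scores >= cutoff
  structure(list(tp = sum(call_pos & labels == 1),
                 fp = sum(call_pos & labels == 0),
                 fn = sum(!call_pos & labels == 1),
                 tn = sum(!call_pos & labels == 0)),
            class = "confusion_matrix")
}

#' Confusion matrix from explicit counts
#' @param tp,fp,fn,tn counts
#' @return `confusion_matrix`
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_matrix")
}

.cp_interval <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  lo <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

#' Diagnostic metrics with exact binomial confidence intervals
#'
#' Sensitivity, specificity, PPV, NPV and accuracy with Clopper-Pearson 95%
#' CIs. `percent` columns report values rounded half-up to integer percent
#' (table display convention); a metric with a zero denominator is `NA` and
#' flagged in `undefined`.
#'
#' @param cm `confusion_matrix`
#' @param cutoff optional threshold annotation
#' @param conf confidence level
#' @return `metric_set` data.frame: metric, estimate, lower, upper, percent
#' @export
metrics_with_ci <- function(cm, cutoff = NA, conf = 0.95) {
  num <- c(sensitivity = cm$tp, specificity = cm$tn, ppv = cm$tp,
           npv = cm$tn, accuracy = cm$tp + cm$tn)
  den <- c(sensitivity = cm$tp + cm$fn, specificity = cm$tn + cm$fp,
           ppv = cm$tp + cm$fp, npv = cm$tn + cm$fn,
           accuracy = cm$tp + cm$fp + cm$fn + cm$tn)
  rows <- lapply(names(num), function(m) {
    if (den[[m]] == 0)
      return(data.frame(metric = m, estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, percent = NA_real_))
    p <- num[[m]] / den[[m]]
    ci <- .cp_interval(num[[m]], den[[m]], conf)
    data.frame(metric = m, estimate = p, lower = ci[1], upper = ci[2],
               percent = round_half_up(100 * p))
  })
  out <- do.call(rbind, rows)
  attr(out, "cutoff") <- cutoff
  attr(out, "undefined") <- out$metric[is.na(out$estimate)]
  class(out) <- c("metric_set", "data.frame")
  out
}

#' DeLong test for two paired (or unpaired) AUCs
#'
#' Paired form: covariance of the structural components on the shared cases.
#' Unpaired form (`paired = FALSE`, for subgroup comparisons): independent
#' variances.
#'
#' @param scores_a,scores_b scores of the two procedures
#' @param labels 0/1 labels (paired) or list of two label vectors (unpaired)
#' @param paired logical
#' @return `comparison_result` list: statistic (z), p_value, method, aucs
#' @export
delong_test <- function(scores_a, scores_b, labels, paired = TRUE) {
  if (paired) {
    .check_binary(labels)
    stopifnot(length(scores_a) == length(labels),
              length(scores_b) == length(labels))
    ca <- .delong_components(scores_a, labels)
    cb <- .delong_components(scores_b, labels)
    ## components are aligned case-by-case because label order is shared
    v10d <- ca$v10 - cb$v10
    v01d <- ca$v01 - cb$v01
    vr <- var(v10d) / ca$m + var(v01d) / ca$n
    d <- ca$auc - cb$auc
    if (vr <= 0) {
      z <- 0; p <- 1
    } else {
      z <- d / sqrt(vr); p <- 2 * pnorm(-abs(z))
    }
    structure(list(statistic = z, p_value = p, method = "delong",
                   auc_a = ca$auc, auc_b = cb$auc, sides = 2),
              class = "comparison_result")
  } else {
    la <- labels[[1]]; lb <- labels[[2]]
    .check_binary(la); .check_binary(lb)
    ca <- .delong_components(scores_a, la)
    cb <- .delong_components(scores_b, lb)
    vr <- var(ca$v10) / ca$m + var(ca$v01) / ca$n +
      var(cb$v10) / cb$m + var(cb$v01) / cb$n
    d <- ca$auc - cb$auc
    if (vr <= 0) {
      z <- 0; p <- 1
    } else {
      z <- d / sqrt(vr); p <- 2 * pnorm(-abs(z))
    }
    structure(list(statistic = z, p_value = p, method = "delong_unpaired",
                   auc_a = ca$auc, auc_b = cb$auc, sides = 2),
              class = "comparison_result")
  }
}

#' McNemar test for paired sensitivities, specificities, or accuracies
#'
#' Restricted to the metric's case subset (positives for sensitivity,
#' negatives for specificity, all for accuracy), the test compares the two
#' procedures' correctness indicators: exact two-sided binomial when the
#' discordant count b + c < 25, else chi-square with continuity correction.
#'
#' @param calls_a,calls_b 0/1 calls of the two procedures (paired)
#' @param labels 0/1 reference labels
#' @param metric one of "sensitivity", "specificity", "accuracy"
#' @return `comparison_result` with discordant counts `b`, `c`
#' @export
mcnemar_test <- function(calls_a, calls_b, labels,
                         metric = c("accuracy", "sensitivity", "specificity")) {
  metric <- match.arg(metric)
  stopifnot(length(calls_a) == length(labels), length(calls_b) == length(labels))
  keep <- switch(metric, sensitivity = labels == 1, specificity = labels == 0,
                 accuracy = rep(TRUE, length(labels)))
  corr_a <- calls_a[keep] == labels[keep]
  corr_b <- calls_b[keep] == labels[keep]
  b <- sum(corr_a & !corr_b)    # A right, B wrong
  cc <- sum(!corr_a & corr_b)
  n <- b + cc
  if (n == 0) {
    stat <- 0; p <- 1; exact <- TRUE
  } else if (n < 25) {
    p <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
    stat <- min(b, cc); exact <- TRUE
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    exact <- FALSE
  }
  structure(list(statistic = stat, p_value = p, method = "mcnemar",
                 metric = metric, b = b, c = cc, exact = exact, sides = 2),
            class = "comparison_result")
}

#' Weighted generalized score test for paired predictive values
#'
#' Compares PPV (or NPV) of two diagnostic procedures on the same cases
#' (Kosinski's weighted generalized score statistic). Each subject
#' contributes an observation to procedure j's predictive value when that
#' procedure calls it positive (negative for NPV); under H0 the common
#' predictive value is the call-count-weighted pooled estimate and the
#' variance is the clustered (sandwich) score variance, giving a chi-square
#' statistic on 1 df.
#'
#' @param calls_a,calls_b 0/1 calls (paired)
#' @param labels 0/1 reference labels
#' @param which "ppv" or "npv"
#' @return `comparison_result`; `undefined` flag when a procedure makes no
#'   qualifying call
#' @export
kosinski_test <- function(calls_a, calls_b, labels, which = c("ppv", "npv")) {
  which <- match.arg(which)
  stopifnot(length(calls_a) == length(labels), length(calls_b) == length(labels))
  if (which == "ppv") {
    ga <- calls_a == 1; gb <- calls_b == 1; d <- as.numeric(labels == 1)
  } else {
    ga <- calls_a == 0; gb <- calls_b == 0; d <- as.numeric(labels == 0)
  }
  na <- sum(ga); nb <- sum(gb)
  if (na == 0 || nb == 0)
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          method = "kosinski_wgs", which = which,
                          undefined = TRUE, sides = 2),
                     class = "comparison_result"))
  pa <- sum(d[ga]) / na
  pb <- sum(d[gb]) / nb
  p0 <- (na * pa + nb * pb) / (na + nb)       # weighted pooled value
  h <- ga * (d - p0) / na - gb * (d - p0) / nb
  v0 <- sum(h^2)
  if (v0 <= 0) {
    stat <- 0; p <- 1
  } else {
    stat <- (pa - pb)^2 / v0
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p, method = "kosinski_wgs",
                 which = which, pv_a = pa, pv_b = pb, undefined = FALSE,
                 sides = 2),
            class = "comparison_result")
}

#' Calibration table by equal-frequency bins
#'
#' @param scores predicted probabilities in `[0, 1]`
#' @param labels 0/1 outcomes
#' @param n_bins number of bins (reduced with a warning when `n < n_bins`
#'   or scores have too few distinct values)
#' @return data.frame: bin, n, mean_predicted, observed_rate
#' @export
calibration_bins <- function(scores, labels, n_bins = 10) {
  stopifnot(all(scores >= 0 & scores <= 1))
  n <- length(scores)
  if (n < n_bins) {
    warning("fewer cases than bins; reducing to ", n, " bins")
    n_bins <- max(1, n)
  }
  ndist <- length(unique(scores))
  if (ndist < n_bins) {
    ## degenerate score sets collapse to their distinct values
    grp <- match(scores, sort(unique(scores)))
  } else {
    ord <- order(scores)
    grp <- integer(n)
    grp[ord] <- rep(seq_len(n_bins), times = diff(floor(seq(0, n, length.out = n_bins + 1))))
  }
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    data.frame(bin = g, n = sum(grp == g),
               mean_predicted = mean(scores[grp == g]),
               observed_rate = mean(labels[grp == g]))
  }))
  out$bin <- seq_len(nrow(out))
  out
}

#' Decision-curve net benefit
#'
#' `NB(pt) = TP/n - FP/n * pt / (1 - pt)` with a positive call iff
#' `score >= pt`; `NB_all` treats everyone as positive, `NB_none = 0`.
#'
#' @param scores predicted probabilities in `[0, 1]`
#' @param labels 0/1 outcomes
#' @param thresholds probability thresholds in (0, 1)
#' @return data.frame: threshold, nb_model, nb_all, nb_none
#' @export
net_benefit <- function(scores, labels, thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(scores >= 0 & scores <= 1), all(thresholds > 0 & thresholds < 1))
  n <- length(scores)
  prev <- mean(labels == 1)
  do.call(rbind, lapply(thresholds, function(pt) {
    w <- pt / (1 - pt)
    pos <- scores >= pt
    tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
    data.frame(threshold = pt,
               nb_model = tp / n - fp / n * w,
               nb_all = prev - (1 - prev) * w,
               nb_none = 0)
  }))
}

#' Per-stratum AUCs with pairwise unpaired DeLong comparisons
#'
#' Strata containing a single class are excluded with a warning.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels
#' @param strata stratum tag per case
#' @return list with `auc` (data.frame stratum/n/auc/lower/upper),
#'   `comparisons` (data.frame stratum_a/stratum_b/z/p_value), `excluded`
#' @export
subgroup_auc <- function(scores, labels, strata) {
  stopifnot(length(scores) == length(labels), length(strata) == length(labels))
  tags <- unique(strata)
  ok <- character(0); excluded <- character(0)
  per <- list()
  for (s in tags) {
    sel <- strata == s
    if (length(unique(labels[sel])) < 2) {
      warning("stratum ", s, " has a single class; excluded")
      excluded <- c(excluded, as.character(s))
      next
    }
    r <- roc_auc(scores[sel], labels[sel])
    per[[as.character(s)]] <- data.frame(stratum = as.character(s), n = sum(sel),
                                         auc = r$auc, lower = r$ci[1],
                                         upper = r$ci[2])
    ok <- c(ok, as.character(s))
  }
  cmps <- list()
  if (length(ok) >= 2) {
    for (i in seq_along(ok)) for (j in seq_along(ok)) {
      if (i >= j) next
      sa <- strata == ok[i]; sb <- strata == ok[j]
      ct <- delong_test(scores[sa], scores[sb],
                        list(labels[sa], labels[sb]), paired = FALSE)
      cmps[[length(cmps) + 1]] <- data.frame(
        stratum_a = ok[i], stratum_b = ok[j],
        z = ct$statistic, p_value = ct$p_value)
    }
  }
  list(auc = do.call(rbind, per),
       comparisons = if (length(cmps)) do.call(rbind, cmps) else NULL,
       excluded = excluded)
}
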