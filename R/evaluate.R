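# Evaluation metrics for a vector of per-taxon p-values against the known
# ground truth: FPR/TPR at a fixed threshold, power at the threshold where
# the empirical FPR reaches a target, and partial ROC area up to a maximum
# FPR.

#' False and true positive rate at a threshold
#'
#' FPR = fraction of null taxa with p < gamma; TPR = fraction of truly DA
#' taxa with p < gamma (strict inequality). Taxa with missing p-values
#' (failed fits) are excluded from both numerator and denominator. With no
#' null (or no DA) taxa the corresponding rate is `NA`, not 0.
#'
#' @param pvalues numeric vector of per-taxon p-values.
#' @param truth logical (or 0/1) vector: taxon truly differentially abundant.
#' @param gamma significance threshold in (0, 1).
#' @return named vector `c(fpr, tpr)`.
#' @examples
#' fpr_tpr(c(0.01, 0.20, 0.03, 0.80), c(0, 0, 1, 1), 0.05)  # 0.5, 0.5
#' @export
fpr_tpr <- function(pvalues, truth, gamma = 0.05) {
  if (length(pvalues) != length(truth)) stop("length mismatch")
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)")
  truth <- as.logical(truth)
  keep <- !is.na(pvalues)
  p <- pvalues[keep]; t <- truth[keep]
  c(fpr = if (any(!t)) mean(p[!t] < gamma) else NA_real_,
    tpr = if (any(t)) mean(p[t] < gamma) else NA_real_)
}

#' Power at a fixed empirical false positive rate
#'
#' Chooses the largest achievable threshold (among the sorted null p-values)
#' whose empirical FPR does not exceed `target_fpr`, and returns the TPR at
#' that threshold. Ties are broken toward the smaller threshold, so the
#' constraint FPR <= target always holds exactly.
#'
#' @inheritParams fpr_tpr
#' @param target_fpr the empirical FPR to calibrate to (default 0.05).
#' @return the power (TPR) at the calibrated threshold.
#' @export
power_at_fpr <- function(pvalues, truth, target_fpr = 0.05) {
  truth <- as.logical(truth)
  keep <- !is.na(pvalues)
  p <- pvalues[keep]; t <- truth[keep]
  if (!any(t) || !any(!t)) stop("need at least one null and one DA taxon")
  p0 <- sort(p[!t]); n0 <- length(p0)
  cand <- unique(p0)
  fprs <- vapply(cand, function(th) sum(p0 < th) / n0, numeric(1))
  thr <- max(cand[fprs <= target_fpr])
  mean(p[t] < thr)
}

#' Partial AUC up to a maximum FPR
#'
#' Traces the ROC curve by thresholding the p-values (smaller = called DA),
#' integrates TPR over FPR in `[0, max_fpr]` by the trapezoid rule, and
#' normalizes. The default normalization divides by `max_fpr` (the maximum
#' attainable area); `standardized = TRUE` applies the McClish
#' transformation, which maps a chance-level ranking to 0.5 instead.
#'
#' @inheritParams fpr_tpr
#' @param max_fpr upper FPR limit of the partial area (default 0.10).
#' @param standardized use the McClish standardization.
#' @return normalized partial AUC in `[0, 1]`.
#' @export
auc_at_fpr <- function(pvalues, truth, max_fpr = 0.10, standardized = FALSE) {
  truth <- as.logical(truth)
  keep <- !is.na(pvalues)
  p <- pvalues[keep]; t <- truth[keep]
  if (!any(t) || !any(!t)) stop("need at least one null and one DA taxon")
  u <- sort(unique(p))
  # inclusive thresholds: reject p <= u[k]
  fpr <- vapply(u, function(th) mean(p[!t] <= th), numeric(1))
  tpr <- vapply(u, function(th) mean(p[t] <= th), numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  # clip the curve at max_fpr (linear interpolation on the segment crossing it)
  if (max(fpr) < max_fpr) {
    fpr <- c(fpr, max_fpr); tpr <- c(tpr, tpr[length(tpr)])
  } else if (!any(fpr == max_fpr)) {
    i <- which(fpr > max_fpr)[1]
    w <- (max_fpr - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    fpr <- c(fpr[1:(i - 1)], max_fpr)
    tpr <- c(tpr[1:(i - 1)], tpr[i - 1] + w * (tpr[i] - tpr[i - 1]))
  } else {
    i <- which(fpr == max_fpr)[1]
    fpr <- fpr[1:i]; tpr <- tpr[1:i]
  }
  pauc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (standardized) {
    amin <- max_fpr^2 / 2; amax <- max_fpr
    0.5 * (1 + (pauc - amin) / (amax - amin))
  } else {
    pauc / max_fpr
  }
}

#' All four comparison metrics for one run
#'
#' Power (TPR) and FPR at the `gamma` threshold, power at the threshold where
#' the empirical FPR equals 0.05, and the normalized partial AUC up to FPR
#' 0.10.
#'
#' @inheritParams fpr_tpr
#' @return one-row data.frame with columns `power`, `fpr`, `power_at_0.05`,
#'   `auc_at_0.10`.
#' @export
evaluate_metrics <- function(pvalues, truth, gamma = 0.05) {
  ft <- fpr_tpr(pvalues, truth, gamma)
  # threshold-calibrated metrics need both classes; report NA when degenerate
  pw <- tryCatch(power_at_fpr(pvalues, truth, 0.05), error = function(e) NA_real_)
  au <- tryCatch(auc_at_fpr(pvalues, truth, 0.10), error = function(e) NA_real_)
  data.frame(power = unname(ft["tpr"]), fpr = unname(ft["fpr"]),
             power_at_0.05 = pw, auc_at_0.10 = au)
}

#' Summarize metrics over repetitions
#'
#' Mean and standard error of each metric across repetitions, per
#' (family, test type), formatted as `"mean (±se)"` to two decimals alongside
#' the numeric columns.
#'
#' @param metrics data.frame with columns `family`, `test_type`, and one row
#'   per repetition of the metric columns from [evaluate_metrics()].
#' @return data.frame with one row per (family, test_type).
#' @export
summarize_repetitions <- function(metrics) {
  mcols <- intersect(c("power", "fpr", "power_at_0.05", "auc_at_0.10"),
                     names(metrics))
  if (!length(mcols)) stop("no metric columns found")
  keys <- unique(metrics[c("family", "test_type")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- metrics[metrics$family == keys$family[i] &
                     metrics$test_type == keys$test_type[i], , drop = FALSE]
    if (nrow(sub) < 2)
      warning("fewer than 2 repetitions for ", keys$family[i],
              "(", keys$test_type[i], "); standard error is NA")
    out <- keys[i, , drop = FALSE]
    for (mc in mcols) {
      v <- sub[[mc]]
      mu <- mean(v, na.rm = TRUE)
      se <- if (sum(!is.na(v)) >= 2) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))) else NA_real_
      out[[mc]] <- sprintf("%.2f (±%.2f)", mu, se)
      out[[paste0("mean_", mc)]] <- mu
      out[[paste0("se_", mc)]] <- se
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
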