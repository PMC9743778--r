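# The permutation-of-regressor-residuals (PRR) test, in three stages:
# 1. replace the interest columns by their least-squares residuals against the
#    nuisance columns (same maximized likelihood, but now permutable);
# 2. for each resampling iteration, permute the residual rows (one index set
#    shared by the count and zero components) and recompute the
#    full-vs-reduced likelihood-ratio p-value;
# 3. report the standard LRT p-value and the permutation p-value
#    p = (1/B) #\{b : p_b < p_hat\}.

#' Likelihood-ratio test p-value
#'
#' Upper-tail chi-squared probability of the deviance
#' \eqn{-2(\ell_{reduced} - \ell_{full})}. Small negative deviances (numerical
#' noise from two separate maximizations) are clamped to zero.
#'
#' @param loglik_full,loglik_reduced maximized log-likelihoods of the nested
#'   pair.
#' @param df positive integer degrees of freedom (number of constrained
#'   parameters).
#' @return p-value in `[0, 1]`.
#' @examples
#' lrt_pvalue(-10, -10, df = 1)           # 1
#' lrt_pvalue(-10, -10 - 3.841 / 2, 1)    # ~0.05
#' @export
lrt_pvalue <- function(loglik_full, loglik_reduced, df) {
  if (!is.numeric(df) || length(df) != 1 || df < 1 || df != round(df))
    stop("df must be a positive integer")
  stat <- 2 * (loglik_full - loglik_reduced)
  if (stat < 0) stat <- 0
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Generate reproducible permutation index sets
#'
#' `B` uniformly random permutations of `1:n`; the same index set is applied
#' to the residual rows of both the count and zero components within an
#' iteration.
#'
#' @param n number of samples (>= 2).
#' @param B number of resampling iterations (>= 1).
#' @param seed integer seed.
#' @return list of `B` integer permutation vectors.
#' @export
permutation_indices <- function(n, B, seed) {
  if (n < 2) stop("need at least 2 samples to permute")
  if (B < 1) stop("B must be >= 1")
  with_seed(seed, replicate(B, sample.int(n), simplify = FALSE))
}

#' Permutation p-value from per-iteration p-values
#'
#' \eqn{p = (1/B) \sum_b I(p_b < \hat p)} with strict inequality. The
#' optional add-one smoothing \eqn{(1 + \#\{p_b \le \hat p\})/(1 + B)} avoids
#' exact zeros for downstream FDR procedures but is not the default.
#'
#' @param p_hat observed LRT p-value.
#' @param perm_pvalues vector of per-permutation p-values.
#' @param smooth logical; use add-one smoothing.
#' @return the permutation p-value.
#' @examples
#' prr_pvalue(0.5, c(0.1, 0.9))  # 0.5
#' @export
prr_pvalue <- function(p_hat, perm_pvalues, smooth = FALSE) {
  if (length(perm_pvalues) == 0) stop("empty permutation p-value vector")
  if (any(c(p_hat, perm_pvalues) < 0 | c(p_hat, perm_pvalues) > 1))
    stop("p-values must lie in [0, 1]")
  if (smooth)
    (1 + sum(perm_pvalues <= p_hat)) / (1 + length(perm_pvalues))
  else
    mean(perm_pvalues < p_hat)
}

.prr_failure <- function(status, reason, df = NA_integer_, B = NA_integer_,
                         seed = NA_integer_) {
  structure(list(p_hat = NA_real_, p_perm = NA_real_,
                 perm_pvalues = numeric(), df = df, B = B,
                 n_failed = NA_integer_, seed = seed, converged = FALSE,
                 status = status, reason = reason),
            class = "prr_result")
}

#' Run the PRR test for one taxon
#'
#' Fits the reduced model (nuisance only) and the full model with residualized
#' interest columns, computes the standard LRT p-value with
#' `df = ncol(X_interest) + ncol(Z_interest)` (zero-component interest counts
#' only for zero-inflated families), then refits the full model on each of `B`
#' row-permutations of the residuals and reports the permutation p-value.
#' Permutation refits that do not converge (or fall below the reduced-model
#' likelihood) are dropped and counted in `n_failed`; if more than
#' `max_fail_frac` of the `B` iterations fail, the taxon is failed rather than
#' silently renormalized.
#'
#' @param y count vector for one taxon.
#' @param design a [design_spec()] object.
#' @param family a `prr_family` or its name.
#' @param s library sizes.
#' @param B number of resampling iterations.
#' @param seed integer seed for the permutation stream.
#' @param smooth passed to [prr_pvalue()].
#' @param max_fail_frac maximum tolerated fraction of failed permutation fits
#'   (default 0.1).
#' @param permute set `FALSE` to skip the permutation stage and report only
#'   the standard LRT p-value (used for likelihood-only comparisons).
#' @param control passed to [fit_ml()].
#' @return a `prr_result`: `p_hat` (standard LRT), `p_perm`, `perm_pvalues`,
#'   `df`, `B`, `n_failed`, `seed`, `converged`, `status`
#'   (`"ok"`/`"skip"`/`"failed"`), `reason`.
#' @export
run_prr_test <- function(y, design, family, s, B = 1000, seed = 1L,
                         smooth = FALSE, max_fail_frac = 0.1, permute = TRUE,
                         control = list()) {
  fam <- as_family(family)
  stopifnot(inherits(design, "prr_design"))
  n <- length(y)
  if (n != design$n) stop("length(y) does not match the design")
  if (all(y == 0))
    return(.prr_failure("skip", "all-zero taxon: no information for any family",
                        seed = seed))

  Xt <- residualize(design$X_interest, design$X_nuisance)$resid
  Xn <- design$X_nuisance
  use_zero <- fam$zero_inflated
  if (use_zero) {
    Zt <- residualize(design$Z_interest, design$Z_nuisance)$resid
    Zn <- design$Z_nuisance
  }
  df <- ncol(Xt) + if (use_zero) ncol(Zt) else 0L
  if (df == 0) stop("design has no interest columns to test")

  fit_red <- fit_ml(fam, y, Xn, Z = if (use_zero) Zn, s, control = control)
  if (!fit_red$converged)
    return(.prr_failure("failed", paste("reduced model did not converge:",
                                        paste(fit_red$messages, collapse = "; ")),
                        df = df, B = B, seed = seed))
  # warm start: zero interest coefficients spliced into the reduced solution
  init_full <- splice_init(fam, fit_red, p = ncol(Xt),
                           s_int = if (use_zero) ncol(Zt) else 0L)
  X0 <- cbind(Xt, Xn)
  Z0 <- if (use_zero) cbind(Zt, Zn)
  fit_full <- fit_ml(fam, y, X0, Z0, s, init = init_full, control = control)
  if (!fit_full$converged)
    return(.prr_failure("failed", paste("full model did not converge:",
                                        paste(fit_full$messages, collapse = "; ")),
                        df = df, B = B, seed = seed))
  p_hat <- lrt_pvalue(fit_full$loglik, fit_red$loglik, df)

  perm_p <- numeric(0)
  n_failed <- 0L
  p_perm <- NA_real_
  if (permute) {
    idx <- permutation_indices(n, B, seed)
    perm_p <- rep(NA_real_, B)
    # warm start from the reduced solution with zeroed interest coefficients
    # (under permutation the interest effect is near null, so this is closer
    # to the permuted optimum than the observed-residual solution); extreme
    # near-boundary coefficients are pulled back into a well-behaved region
    init_perm <- init_full
    ncoef <- length(init_perm) - fam$overdispersed
    init_perm[seq_len(ncoef)] <- pmin(pmax(init_perm[seq_len(ncoef)], -4), 4)
    # permutation refits only feed the LR statistic (needed to ~1e-4), so a
    # slightly looser stopping rule than the observed fits' is sufficient
    perm_control <- utils::modifyList(list(reltol = 1e-9, grad_tol = 1e-4), control)
    for (b in seq_len(B)) {
      Xb <- cbind(Xt[idx[[b]], , drop = FALSE], Xn)
      Zb <- if (use_zero) cbind(Zt[idx[[b]], , drop = FALSE], Zn)
      fb <- fit_ml(fam, y, Xb, Zb, s, init = init_perm, control = perm_control)
      if (fb$converged && fb$loglik >= fit_red$loglik - 1e-6)
        perm_p[b] <- lrt_pvalue(fb$loglik, fit_red$loglik, df)
    }
    n_failed <- sum(is.na(perm_p))
    perm_p <- perm_p[!is.na(perm_p)]
    if (n_failed > max_fail_frac * B || length(perm_p) == 0)
      return(.prr_failure("failed",
                          sprintf("%d/%d permutation fits failed", n_failed, B),
                          df = df, B = B, seed = seed))
    if (n_failed > 0)
      warning(sprintf("%d of %d permutation fits dropped (non-convergence)",
                      n_failed, B))
    p_perm <- prr_pvalue(p_hat, perm_p, smooth = smooth)
  }

  structure(list(p_hat = p_hat, p_perm = p_perm, perm_pvalues = perm_p,
                 df = df, B = if (permute) B else 0L, n_failed = n_failed,
                 seed = seed, converged = TRUE, status = "ok", reason = NA_character_),
            class = "prr_result")
}

splice_init <- function(fam, fit_red, p, s_int) {
  aux <- if (fam$overdispersed) unname(fit_red$aux) else NULL
  c(rep(0, p), unname(fit_red$alpha),
    if (fam$zero_inflated) c(rep(0, s_int), unname(fit_red$beta)),
    aux)
}

#' @export
print.prr_result <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<prr_result> %s: %s\n", x$status, x$reason))
  } else {
    cat(sprintf("<prr_result> df = %d, p_lrt = %.4g, p_perm = %s (B = %d, %d failed)\n",
                x$df, x$p_hat,
                if (is.na(x$p_perm)) "NA" else sprintf("%.4g", x$p_perm),
                x$B, x$n_failed))
  }
  invisible(x)
}

#' Run the PRR test across all taxa of a count table
#'
#' Applies [run_prr_test()] to every taxon column for each requested family.
#' Each taxon carries a pre-assigned seed derived from the master seed, so
#' results are identical for any worker count.
#'
#' @param counts a [count_table].
#' @param covariates data.frame of per-sample covariates (rows aligned with
#'   the count table's samples).
#' @param interest,count_formula,zero_formula passed to [design_spec()].
#' @param families list from [prr_families()] (or a character vector of family
#'   names); default all eight.
#' @param B,smooth,max_fail_frac,permute,control passed to [run_prr_test()].
#' @param seed master seed.
#' @param workers number of parallel workers (forked; 1 = serial).
#' @param adjust add a Benjamini-Hochberg adjusted column `p_perm_bh` (and
#'   `p_lrt_bh`), computed per family. Never applied silently: raw p-values
#'   are always reported.
#' @return data.frame with one row per taxon x family: `taxon_id`, `family`,
#'   `df`, `p_lrt`, `p_perm`, `n_failed`, `converged`, `skip_reason`.
#' @export
prr_test_table <- function(counts, covariates, interest, families = prr_families(),
                           count_formula = NULL, zero_formula = NULL,
                           B = 1000, seed = 1L, workers = 1L, smooth = FALSE,
                           max_fail_frac = 0.1, permute = TRUE, adjust = FALSE,
                           control = list()) {
  stopifnot(inherits(counts, "count_table"))
  if (is.character(families)) families <- prr_families(families)
  if (inherits(families, "prr_family")) families <- list(families)
  if (nrow(covariates) != length(counts$sample_ids))
    stop("covariate rows do not match count-table samples")
  design <- design_spec(covariates, interest, count_formula, zero_formula)
  s <- counts$library_sizes
  m <- length(counts$taxon_ids)
  seeds <- vapply(seq_len(m), function(j) derive_seed(seed, j), integer(1))

  one_taxon <- function(j) {
    y <- counts$counts[, j]
    rows <- lapply(families, function(fam) {
      r <- tryCatch(
        suppressWarnings(run_prr_test(y, design, fam, s, B = B, seed = seeds[j],
                                      smooth = smooth, max_fail_frac = max_fail_frac,
                                      permute = permute, control = control)),
        error = function(e) .prr_failure("failed", conditionMessage(e), seed = seeds[j]))
      data.frame(taxon_id = counts$taxon_ids[j], family = as_family(fam)$name,
                 df = r$df, p_lrt = r$p_hat, p_perm = r$p_perm,
                 n_failed = r$n_failed, converged = r$converged,
                 skip_reason = if (r$status == "ok") NA_character_ else r$reason,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  res <- if (workers > 1) {
    parallel::mclapply(seq_len(m), one_taxon, mc.cores = workers)
  } else {
    lapply(seq_len(m), one_taxon)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (adjust) {
    for (f in unique(out$family)) {
      i <- out$family == f
      out$p_lrt_bh[i] <- stats::p.adjust(out$p_lrt[i], "BH")
      out$p_perm_bh[i] <- stats::p.adjust(out$p_perm[i], "BH")
    }
  }
  out
}
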