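# Design handling: split the model matrices of the count and zero components
# into an interest block (the covariate(s) being tested) and a nuisance block
# (everything else, including the intercept), and residualize the interest
# block against the nuisance block.

#' Encode a covariate of interest as model-matrix columns
#'
#' A continuous covariate contributes a single unchanged column; a categorical
#' covariate with m observed levels contributes m-1 treatment-coded indicator
#' columns against a fixed reference level.
#'
#' @param x numeric vector, factor, or character vector.
#' @param reference optional reference level for categorical `x` (default:
#'   first factor level).
#' @param name column-name stem.
#' @return a numeric matrix with one row per observation.
#' @examples
#' encode_interest(c(1.2, 3.4, 5.6))                      # identity column
#' encode_interest(factor(c("a", "b", "c", "a")))          # 2 dummies
#' @export
encode_interest <- function(x, reference = NULL, name = deparse(substitute(x))) {
  if (is.numeric(x)) {
    m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, name))
    return(m)
  }
  x <- as.factor(x)
  x <- droplevels(x)
  if (nlevels(x) < 2)
    stop("covariate of interest has a single observed level; design is degenerate")
  if (!is.null(reference)) x <- stats::relevel(x, ref = reference)
  mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
  colnames(mm) <- paste0(name, levels(x)[-1])
  mm
}

#' Residualize interest columns against nuisance columns
#'
#' Solves the least-squares problem
#' \eqn{\hat\Sigma = argmin_\Sigma ||X^* - X^\dagger \Sigma||^2} column-wise
#' and returns the residual \eqn{\tilde X = X^* - X^\dagger \hat\Sigma}. The
#' residual is exactly orthogonal to every nuisance column, and the maximized
#' likelihood of the full model is unchanged when \eqn{X^*} is replaced by
#' \eqn{\tilde X} (they span the same column space together with
#' \eqn{X^\dagger}).
#'
#' @param X_interest n x p matrix of interest columns.
#' @param X_nuisance n x q full-column-rank nuisance matrix (includes the
#'   intercept).
#' @return list with `resid` (the n x p residual matrix) and `Sigma` (the
#'   q x p least-squares coefficient matrix).
#' @examples
#' residualize(cbind(1:3), cbind(rep(1, 3)))$resid  # centering: -1, 0, 1
#' @export
residualize <- function(X_interest, X_nuisance) {
  Xi <- as.matrix(X_interest)
  Xn <- as.matrix(X_nuisance)
  if (nrow(Xi) != nrow(Xn)) stop("row count mismatch")
  qrN <- qr(Xn)
  if (qrN$rank < ncol(Xn)) {
    bad <- colnames(Xn)[qrN$pivot[-seq_len(qrN$rank)]] %||% "unnamed"
    stop("nuisance block is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (ncol(Xi) == 0)
    return(list(resid = Xi, Sigma = matrix(0, ncol(Xn), 0)))
  Sigma <- qr.coef(qrN, Xi)
  resid <- Xi - Xn %*% Sigma
  list(resid = resid, Sigma = Sigma)
}

#' Build a partitioned design for the PRR test
#'
#' Constructs the count-component matrix \eqn{X = (X^*, X^\dagger)} and the
#' zero-component matrix \eqn{Z = (Z^*, Z^\dagger)} from formulas over a
#' covariate table, with the columns generated by the interest variable(s)
#' split out of each. A categorical interest variable with m levels
#' contributes m-1 treatment-coded columns to the interest block.
#'
#' @param covariates data.frame of per-sample covariates.
#' @param interest character vector of covariate names under test; must appear
#'   as main-effect terms of `count_formula` (and of `zero_formula` to be
#'   tested in the zero component).
#' @param count_formula right-hand-side formula for the count component;
#'   default `~ interest`.
#' @param zero_formula right-hand-side formula for the zero component, used by
#'   zero-inflated families; `NULL` (default) means an intercept-only zero
#'   component with no interest columns.
#' @return a `prr_design` with `X_interest`, `X_nuisance`, `Z_interest`,
#'   `Z_nuisance`, `interest`.
#' @examples
#' cov <- data.frame(diet = factor(rep(c("a", "b"), 5)), age = 1:10)
#' d <- design_spec(cov, "diet", ~ diet + age)
#' colnames(d$X_interest)   # "dietb"
#' colnames(d$X_nuisance)   # intercept and age
#' @export
design_spec <- function(covariates, interest, count_formula = NULL,
                        zero_formula = NULL) {
  covariates <- as.data.frame(covariates)
  if (is.null(count_formula)) count_formula <- stats::reformulate(interest)
  miss <- setdiff(interest, names(covariates))
  if (length(miss))
    stop("interest variable(s) not in covariate table: ", paste(miss, collapse = ", "))
  xb <- split_terms(count_formula, covariates, interest, require_interest = TRUE)
  if (is.null(zero_formula)) {
    n <- nrow(covariates)
    zb <- list(interest = matrix(numeric(), n, 0),
               nuisance = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  } else {
    zb <- split_terms(zero_formula, covariates, interest, require_interest = FALSE)
  }
  structure(list(X_interest = xb$interest, X_nuisance = xb$nuisance,
                 Z_interest = zb$interest, Z_nuisance = zb$nuisance,
                 interest = interest, n = nrow(covariates)),
            class = "prr_design")
}

split_terms <- function(formula, data, interest, require_interest) {
  tt <- stats::terms(formula, data = data)
  labs <- attr(tt, "term.labels")
  if (require_interest && !all(interest %in% labs))
    stop("interest variable(s) must appear as main-effect terms of the formula")
  mm <- stats::model.matrix(tt, data)
  asgn <- attr(mm, "assign")
  int_terms <- which(labs %in% interest)
  is_int <- asgn %in% int_terms
  list(interest = mm[, is_int, drop = FALSE],
       nuisance = mm[, !is_int, drop = FALSE])
}

#' @export
print.prr_design <- function(x, ...) {
  cat(sprintf("<prr_design> n = %d; interest: %s\n", x$n,
              paste(x$interest, collapse = ", ")))
  cat(sprintf("count component: %d interest + %d nuisance column(s)\n",
              ncol(x$X_interest), ncol(x$X_nuisance)))
  cat(sprintf("zero component: %d interest + %d nuisance column(s)\n",
              ncol(x$Z_interest), ncol(x$Z_nuisance)))
  invisible(x)
}
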