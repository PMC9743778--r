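# The eight count-regression families: {Poisson, NegBin, Binomial, BetaBin}
# crossed with plain / zero-inflated. Poisson-type families model the mean on
# a log link with an additive log(library size) offset; binomial-type families
# treat the count as successes out of s_i trials on a logit link. Auxiliary
# parameters are kept on an unconstrained internal scale (log dispersion,
# logit overdispersion) so the optimizer never hits a hard boundary.

.prr_base_names <- c(poisson = "Poisson", negbin = "NegativeBinomial",
                     binomial = "Binomial", betabinomial = "BetaBinomial")

#' Specify a count-regression family
#'
#' One of the eight families in the 2 (Poisson/Binomial type) x 2
#' (overdispersed or not) x 2 (zero-inflated or not) grid:
#' Poisson, NegativeBinomial, Binomial, BetaBinomial and their ZI versions.
#'
#' * Poisson type (`poisson`, `negbin`): mean \eqn{\mu_i = s_i e^{x_i'\alpha}}
#'   (log link, log library-size offset).
#' * Binomial type (`binomial`, `betabinomial`): \eqn{Y_i} successes out of
#'   \eqn{s_i} trials, \eqn{logit(p_i) = x_i'\alpha}.
#' * Negative binomial uses mean/size parameterization,
#'   \eqn{Var = \mu + \mu^2/\theta}; internal scale \eqn{\log\theta}.
#' * Beta-binomial uses mean probability p and overdispersion
#'   \eqn{\rho \in (0,1)} (intra-class correlation); internal scale
#'   \eqn{logit(\rho)}.
#' * Zero inflation adds a logistic zero component:
#'   \eqn{f(y) = \pi_i 1[y=0] + (1-\pi_i) g(y)} with
#'   \eqn{logit(\pi_i) = z_i'\beta}.
#'
#' @param base one of `"poisson"`, `"negbin"`, `"binomial"`, `"betabinomial"`.
#' @param zero_inflated logical.
#' @return a `prr_family` object.
#' @examples
#' family_spec("negbin", zero_inflated = TRUE)$name  # "ZINegativeBinomial"
#' @export
family_spec <- function(base = c("poisson", "negbin", "binomial", "betabinomial"),
                        zero_inflated = FALSE) {
  base <- match.arg(base)
  structure(list(
    base = base,
    name = paste0(if (isTRUE(zero_inflated)) "ZI" else "", .prr_base_names[[base]]),
    zero_inflated = isTRUE(zero_inflated),
    overdispersed = base %in% c("negbin", "betabinomial"),
    binomial_type = base %in% c("binomial", "betabinomial"),
    exposure_mode = if (base %in% c("poisson", "negbin")) "offset" else "trials"
  ), class = "prr_family")
}

#' @export
print.prr_family <- function(x, ...) {
  cat(sprintf("<prr_family> %s (%s exposure%s%s)\n", x$name, x$exposure_mode,
              if (x$overdispersed) ", overdispersed" else "",
              if (x$zero_inflated) ", zero-inflated" else ""))
  invisible(x)
}

#' List the eight supported families
#'
#' @param names optional character vector of family names (e.g.
#'   `"ZINegativeBinomial"`) to select a subset.
#' @return a named list of `prr_family` objects.
#' @export
prr_families <- function(names = NULL) {
  all <- list()
  for (zi in c(FALSE, TRUE))
    for (b in names(.prr_base_names)) {
      f <- family_spec(b, zi)
      all[[f$name]] <- f
    }
  # order as in the family grid: Poisson block then Binomial block
  ord <- c("Poisson", "NegativeBinomial", "ZIPoisson", "ZINegativeBinomial",
           "Binomial", "BetaBinomial", "ZIBinomial", "ZIBetaBinomial")
  all <- all[ord]
  if (is.null(names)) return(all)
  miss <- setdiff(names, ord)
  if (length(miss)) stop("unknown family: ", paste(miss, collapse = ", "))
  all[names]
}

as_family <- function(x) {
  if (inherits(x, "prr_family")) return(x)
  if (is.character(x) && length(x) == 1) return(prr_families(x)[[1]])
  stop("not a family specification")
}

# number of parameters for a family given design matrices
n_params <- function(fam, X, Z = NULL) {
  ncol(X) + (if (fam$zero_inflated) ncol(Z) else 0L) + (fam$overdispersed)
}

# Per-observation base log-density and (optionally) its derivatives with
# respect to the linear predictor eta and the internal auxiliary parameter.
base_parts <- function(fam, y, eta, s, aux, grad = TRUE) {
  switch(fam$base,
    poisson = {
      mu <- s * exp(eta)
      lg <- stats::dpois(y, mu, log = TRUE)
      if (grad) list(lg = lg, deta = y - mu, daux = NULL) else list(lg = lg)
    },
    negbin = {
      theta <- exp(aux)
      mu <- s * exp(eta)
      lg <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
      if (!grad) return(list(lg = lg))
      deta <- theta * (y - mu) / (theta + mu)
      dtheta <- digamma(y + theta) - digamma(theta) + log(theta) -
        log(theta + mu) + 1 - (y + theta) / (theta + mu)
      list(lg = lg, deta = deta, daux = theta * dtheta)
    },
    binomial = {
      p <- stats::plogis(eta)
      lg <- stats::dbinom(y, s, p, log = TRUE)
      if (grad) list(lg = lg, deta = y - s * p, daux = NULL) else list(lg = lg)
    },
    betabinomial = {
      # a = p*gamma, b = (1-p)*gamma with gamma = (1-rho)/rho = exp(-logit(rho))
      gam <- exp(-aux)
      p <- stats::plogis(eta)
      a <- p * gam
      b <- gam - a
      lg <- lchoose(s, y) + lbeta(y + a, s - y + b) - lbeta(a, b)
      if (!grad) return(list(lg = lg))
      common <- digamma(gam) - digamma(s + gam)
      dla <- digamma(y + a) - digamma(a) + common
      dlb <- digamma(s - y + b) - digamma(b) + common
      # da/d logit(rho) = -a, db/d logit(rho) = -b
      list(lg = lg, deta = (dla - dlb) * gam * p * (1 - p),
           daux = -(a * dla + b * dlb))
    })
}

# Joint log-likelihood and analytic gradient for any of the eight families.
# params layout: alpha (ncol X), then beta (ncol Z, ZI only), then aux (one
# internal-scale value, overdispersed only). The hot path is the compiled
# kernel; ll_grad_r is the plain-R reference it is tested against.
.family_codes <- c(poisson = 0L, negbin = 1L, binomial = 2L, betabinomial = 3L)

ll_grad <- function(fam, params, y, X, Z = NULL, s, grad = TRUE, lconst = NULL) {
  out <- .ll_grad_cpp(.family_codes[[fam$base]], fam$zero_inflated,
                      as.numeric(y), X, Z, as.numeric(s),
                      as.numeric(params), grad, lconst)
  if (grad && is.null(out$grad)) out$grad <- rep(NA_real_, length(params))
  out
}

# per-observation additive constant reused across evaluations of one fit
ll_const <- function(fam, y, s) {
  if (fam$base == "betabinomial") lchoose(s, y) else NULL
}

ll_grad_r <- function(fam, params, y, X, Z = NULL, s, grad = TRUE) {
  k <- ncol(X)
  alpha <- params[seq_len(k)]
  pos <- k
  beta <- NULL
  if (fam$zero_inflated) {
    kz <- ncol(Z)
    beta <- params[pos + seq_len(kz)]
    pos <- pos + kz
  }
  aux <- if (fam$overdispersed) params[pos + 1L] else NULL
  eta <- drop(X %*% alpha)
  bp <- base_parts(fam, y, eta, s, aux, grad = grad)

  if (!fam$zero_inflated) {
    ll <- sum(bp$lg)
    if (!grad) return(list(ll = ll))
    g <- c(drop(crossprod(X, bp$deta)),
           if (fam$overdispersed) sum(bp$daux))
    return(list(ll = ll, grad = unname(g)))
  }

  etaz <- drop(Z %*% beta)
  logpi <- stats::plogis(etaz, log.p = TRUE)
  log1mpi <- stats::plogis(-etaz, log.p = TRUE)
  z0 <- y == 0
  ll_i <- log1mpi + bp$lg
  if (any(z0)) ll_i[z0] <- logspace_add(logpi[z0], log1mpi[z0] + bp$lg[z0])
  ll <- sum(ll_i)
  if (!grad) return(list(ll = ll))

  pi <- stats::plogis(etaz)
  w <- rep(1, length(y))        # weight on the count-component score
  dz <- -pi                     # d ll_i / d etaz for y > 0
  if (any(z0)) {
    # posterior weight of the count component given y = 0
    w0 <- exp(log1mpi[z0] + bp$lg[z0] - ll_i[z0])
    w[z0] <- w0
    G0 <- exp(bp$lg[z0])
    dz[z0] <- pi[z0] * (1 - pi[z0]) * (1 - G0) / exp(ll_i[z0])
  }
  g <- c(drop(crossprod(X, w * bp$deta)),
         drop(crossprod(Z, dz)),
         if (fam$overdispersed) sum(w * bp$daux))
  list(ll = ll, grad = unname(g))
}

#' Log-likelihood of a count-regression family
#'
#' Evaluates \eqn{\sum_i \log f(Y_i \mid x_i, z_i, s_i)} for one taxon under
#' any of the eight families. For zero-inflated families the density is the
#' mixture \eqn{\pi_i 1[y=0] + (1-\pi_i) g(y)} with logistic
#' \eqn{\pi_i}. Returns `-Inf` for data impossible under the parameters
#' rather than erroring.
#'
#' @param family a `prr_family` or its name.
#' @param params parameter vector on the internal scale: count coefficients,
#'   then zero-component coefficients (ZI families), then the auxiliary
#'   parameter (log dispersion for NegBin, logit overdispersion for BetaBin).
#' @param y integer count vector for one taxon.
#' @param X count-component model matrix.
#' @param Z zero-component model matrix (ZI families only).
#' @param s library sizes (offset for Poisson type, trials for binomial type).
#' @return scalar log-likelihood.
#' @examples
#' # Poisson, intercept 0, s = 1, y = 1: log f = -1
#' log_likelihood("Poisson", 0, y = 1, X = matrix(1), s = 1)
#' @export
log_likelihood <- function(family, params, y, X, Z = NULL, s) {
  fam <- as_family(family)
  X <- as.matrix(X)
  if (fam$zero_inflated) {
    if (is.null(Z)) stop("zero-inflated family needs a zero-component matrix Z")
    Z <- as.matrix(Z)
    if (nrow(Z) != length(y)) stop("Z row count does not match length(y)")
  }
  if (nrow(X) != length(y)) stop("X row count does not match length(y)")
  if (length(s) != length(y)) stop("library sizes length does not match length(y)")
  if (!is_wholenumber(y) || any(y < 0)) stop("counts must be non-negative integers")
  if (fam$binomial_type && any(y > s)) stop("binomial-type family requires y <= s")
  np <- n_params(fam, X, Z)
  if (length(params) != np)
    stop(sprintf("expected %d parameters, got %d", np, length(params)))
  v <- ll_grad(fam, params, y, X, Z, s, grad = FALSE)$ll
  if (!is.finite(v)) -Inf else v
}
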