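# Synthetic microbiome experiments with known ground truth. The base table is
# a zero-inflated negative-binomial stand-in for a real 16S count matrix
# (overdispersed, zero-inflated, heterogeneous library sizes); signal is then
# injected into counts (multiplying non-zero counts of affected samples)
# and/or zeros (raising the odds of a non-zero observation and reshuffling
# the existing non-zero values).

.diet_levels <- c("meateater", "fisheater", "vegetarian", "vegan")

# joint probability of urbanization and diet (rows: low/high; columns sum to
# the 25% marginal of each diet group)
.urban_diet_joint <- matrix(
  c(20, 15, 10, 5,
     5, 10, 15, 20) / 100, nrow = 2, byrow = TRUE,
  dimnames = list(c("low", "high"), .diet_levels))

# conditional probability of age decade given diet (columns sum to 1)
.age_decades <- c(20, 30, 40, 50, 60)
.age_given_diet <- matrix(
  c( 0, 10, 30, 40,
    10, 15, 25, 30,
    20, 20, 20, 20,
    30, 25, 15, 10,
    40, 30, 10,  0) / 100, nrow = 5, byrow = TRUE,
  dimnames = list(paste0("[", .age_decades, ",", .age_decades + 10, ")"),
                  .diet_levels))

#' Configuration for a simulated differential-abundance experiment
#'
#' Defaults reproduce the study conditions of the simulation design this
#' package evaluates: 149 samples x 531 taxa, 10% of taxa differentially
#' abundant per factor, a +100% (x2) multiplicative diet effect, +200% (x3)
#' urbanization effect and a linear age effect ramping from +0% at age 20 to
#' +400% (x5) at age 69 in the confounded design. The base generator draws
#' per-taxon means, negative-binomial dispersions and zero-inflation
#' probabilities from the stated ranges and scales them by log-normal
#' per-sample library-size factors, spanning the overdispersed, zero-inflated
#' regime of real 16S data (a taxon with mean 30 has variance in the
#' thousands).
#'
#' @param n_samples,n_taxa table dimensions.
#' @param da_fraction fraction of taxa differentially abundant per factor.
#' @param effect_size multiplier applied to the counts (and odds of non-zero)
#'   of affected samples; the study grid is {1.25, 1.5, 2, 3, 5}.
#' @param signal_mode `"counts"` (multiply non-zero counts only) or
#'   `"counts_zeros"` (also raise the odds of a non-zero observation).
#' @param confounded add urbanization and age covariates correlated with diet
#'   and carrying their own signal.
#' @param urban_effect,age_max_effect multipliers for the confounded design.
#' @param mean_range,dispersion_range,zero_range per-taxon parameter ranges of
#'   the zero-inflated negative-binomial base generator.
#' @param libsize_sdlog log-sd of the log-normal per-sample library-size
#'   factors.
#' @param seed integer seed.
#' @return a `prr_sim_config` list.
#' @export
simulation_config <- function(n_samples = 149, n_taxa = 531, da_fraction = 0.10,
                              effect_size = 2,
                              signal_mode = c("counts", "counts_zeros"),
                              confounded = FALSE, urban_effect = 3,
                              age_max_effect = 5,
                              mean_range = c(1, 100),
                              dispersion_range = c(0.1, 2),
                              zero_range = c(0, 0.6),
                              libsize_sdlog = 0.5, seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(n_samples >= 1, n_taxa >= 1,
            da_fraction > 0, da_fraction < 1,
            effect_size > 1, urban_effect > 1, age_max_effect > 1,
            mean_range[1] > 0, diff(mean_range) >= 0,
            dispersion_range[1] > 0, zero_range[1] >= 0, zero_range[2] < 1,
            libsize_sdlog >= 0)
  structure(list(n_samples = n_samples, n_taxa = n_taxa,
                 da_fraction = da_fraction, effect_size = effect_size,
                 signal_mode = signal_mode, confounded = confounded,
                 urban_effect = urban_effect, age_max_effect = age_max_effect,
                 mean_range = mean_range, dispersion_range = dispersion_range,
                 zero_range = zero_range, libsize_sdlog = libsize_sdlog,
                 seed = as.integer(seed)),
            class = "prr_sim_config")
}

#' Generate the synthetic base count table
#'
#' Per taxon j: mean \eqn{m_j} log-uniform in `mean_range`, dispersion
#' \eqn{\theta_j} uniform in `dispersion_range`, structural-zero probability
#' \eqn{\pi_j} uniform in `zero_range`. Per sample i: library-size factor
#' \eqn{\lambda_i} log-normal. Counts are zero-inflated negative binomial
#' with mean \eqn{\lambda_i m_j}.
#'
#' @param config a [simulation_config()].
#' @param seed seed (defaults to the config's).
#' @return a [count_table].
#' @export
generate_base_counts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "prr_sim_config"))
  n <- config$n_samples; m <- config$n_taxa
  with_seed(seed, {
    mu_j <- exp(stats::runif(m, log(config$mean_range[1]), log(config$mean_range[2])))
    theta_j <- stats::runif(m, config$dispersion_range[1], config$dispersion_range[2])
    pi_j <- stats::runif(m, config$zero_range[1], config$zero_range[2])
    lambda_i <- stats::rlnorm(n, 0, config$libsize_sdlog)
    mu <- outer(lambda_i, mu_j)
    y <- stats::rnbinom(n * m, size = rep(theta_j, each = n), mu = mu)
    y <- y * (stats::runif(n * m) >= rep(pi_j, each = n))
    Y <- matrix(y, n, m)
    # a sample with an all-zero row has no library size; give it one read
    empty <- rowSums(Y) == 0
    if (any(empty)) Y[empty, sample.int(m, sum(empty), replace = TRUE)] <- 1
    count_table(Y, sprintf("S%03d", seq_len(n)), sprintf("taxon%04d", seq_len(m)))
  })
}

#' Assign diet groups uniformly
#'
#' Each sample is assigned one of the four diet groups (meateater, fisheater,
#' vegetarian, vegan) independently with equal 25% probability.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return a factor with `meateater` as reference level.
#' @export
assign_diet_groups <- function(n, seed) {
  stopifnot(n >= 1)
  with_seed(seed, factor(sample(.diet_levels, n, replace = TRUE),
                         levels = .diet_levels))
}

#' Assign confounded urbanization and age given diet
#'
#' Urbanization is drawn so the joint (diet, urbanization) distribution
#' matches the configured confounding table (e.g. P(low | meateater) = 20/25);
#' an age decade is drawn from the diet-conditional decade table and the age
#' is then uniform over the integers of that decade, giving ages 20-69. No
#' vegan is ever assigned an age of 60 or more.
#'
#' @param diet factor of diet labels.
#' @param seed integer seed.
#' @param independent if `TRUE`, ignore diet and assign urbanization 50/50 and
#'   age uniform on 20-69 (the non-confounded design).
#' @return data.frame with `urbanization` (factor low/high) and `age`
#'   (integer).
#' @export
assign_confounders <- function(diet, seed, independent = FALSE) {
  diet <- factor(diet, levels = .diet_levels)
  if (anyNA(diet)) stop("unknown diet label")
  stopifnot(abs(colSums(.age_given_diet) - 1) < 1e-12,
            abs(sum(.urban_diet_joint) - 1) < 1e-12)
  n <- length(diet)
  with_seed(seed, {
    if (independent) {
      urb <- sample(c("low", "high"), n, replace = TRUE)
      age <- sample(20:69, n, replace = TRUE)
    } else {
      p_low <- .urban_diet_joint["low", ] / colSums(.urban_diet_joint)
      urb <- ifelse(stats::runif(n) < p_low[as.integer(diet)], "low", "high")
      decade <- integer(n)
      for (d in seq_along(.diet_levels)) {
        i <- which(as.integer(diet) == d)
        if (length(i))
          decade[i] <- sample.int(5, length(i), replace = TRUE,
                                  prob = .age_given_diet[, d])
      }
      age <- .age_decades[decade] + sample.int(10, n, replace = TRUE) - 1L
    }
    data.frame(urbanization = factor(urb, levels = c("low", "high")),
               age = as.integer(age))
  })
}

#' Select differentially abundant taxa per factor
#'
#' For each factor an independent uniform random subset of
#' `round(da_fraction * n_taxa)` taxa.
#'
#' @param n_taxa number of taxa.
#' @param da_fraction fraction in (0, 1).
#' @param factors character vector of factor names (e.g. the four diet
#'   groups).
#' @param seed integer seed.
#' @return logical matrix, factors x taxa.
#' @export
select_da_taxa <- function(n_taxa, da_fraction, factors, seed) {
  stopifnot(da_fraction > 0, da_fraction < 1, length(factors) >= 1)
  k <- round(da_fraction * n_taxa)
  mask <- matrix(FALSE, length(factors), n_taxa,
                 dimnames = list(factors, NULL))
  with_seed(seed, {
    for (f in seq_along(factors))
      mask[f, sample.int(n_taxa, k)] <- TRUE
  })
  mask
}

#' Multiply non-zero counts of affected samples
#'
#' Affected samples with a non-zero count get `round(y * multiplier)`
#' (round-half-to-even, so the injection is unbiased for fractional
#' multipliers such as 1.25); zeros and unaffected samples are untouched.
#'
#' @param y count vector for one taxon.
#' @param affected logical vector of affected samples.
#' @param multiplier scalar > 1, or a per-sample vector (used for the linear
#'   age effect).
#' @return the modified count vector.
#' @examples
#' inject_count_signal(c(10, 0, 3), c(TRUE, TRUE, FALSE), 2)  # 20, 0, 3
#' @export
inject_count_signal <- function(y, affected, multiplier) {
  m <- rep_len(multiplier, length(y))
  if (any(m[affected] < 1)) stop("multiplier must be >= 1")
  i <- affected & y > 0
  y[i] <- round(y[i] * m[i])
  y
}

#' Shift signal into the zeros of a taxon
#'
#' The baseline odds of a non-zero count, o = #nonzero / #zero, is assigned
#' to every sample; affected samples get odds `o * multiplier`. Each sample's
#' non-zero status is then redrawn with probability odds/(1+odds), and
#' non-zero draws receive a value sampled without replacement from the
#' taxon's original non-zero counts (in sample order); once that pool is
#' depleted the remaining samples get zeros. The non-zero values are thus
#' conserved but reshuffled towards affected samples.
#'
#' @param y count vector with at least one zero and one non-zero entry.
#' @param affected logical vector.
#' @param multiplier scalar > 1 or per-sample vector.
#' @param seed integer seed.
#' @return the shuffled count vector (a skip warning and the unchanged vector
#'   if the column is all-zero or all-non-zero).
#' @export
inject_zero_signal <- function(y, affected, multiplier, seed) {
  n <- length(y)
  nz <- y > 0
  if (!any(nz) || all(nz)) {
    warning("all-zero or all-non-zero taxon: zero-odds signal skipped")
    return(y)
  }
  m <- rep_len(1, n)
  m[affected] <- rep_len(multiplier, n)[affected]
  if (any(m < 1)) stop("multiplier must be >= 1")
  odds <- (sum(nz) / sum(!nz)) * m
  prob <- odds / (1 + odds)
  with_seed(seed, {
    draw <- stats::runif(n) < prob
    pool <- sample(y[nz])
    out <- numeric(n)
    take <- which(draw)
    k <- min(length(take), length(pool))
    if (k > 0) out[take[seq_len(k)]] <- pool[seq_len(k)]
    out
  })
}

#' Linear age multiplier
#'
#' Ramps from x1 (no effect) at age 20 to `max_effect` (x5, i.e. +400%) at
#' age 69.
#'
#' @param age numeric ages in `[20, 69]`.
#' @param max_effect multiplier at age 69.
#' @return per-sample multipliers.
#' @export
age_multiplier <- function(age, max_effect = 5) {
  if (any(age < 20 | age > 69)) stop("ages must lie in [20, 69]")
  1 + (max_effect - 1) * (age - 20) / (69 - 20)
}

#' Inject the age-dependent signal
#'
#' For every age-DA taxon, all samples are affected with the per-sample
#' multiplier [age_multiplier()]; in `"counts_zeros"` mode the zero-odds
#' scheme runs first (with the same per-sample multiplier), then the non-zero
#' counts are multiplied.
#'
#' @param counts sample x taxon count matrix.
#' @param ages integer ages in `[20, 69]`.
#' @param da_taxa logical vector marking the age-DA taxa.
#' @param signal_mode `"counts"` or `"counts_zeros"`.
#' @param seed integer seed.
#' @param max_effect multiplier at age 69.
#' @return the modified count matrix.
#' @export
inject_age_signal <- function(counts, ages, da_taxa,
                              signal_mode = c("counts", "counts_zeros"),
                              seed, max_effect = 5) {
  signal_mode <- match.arg(signal_mode)
  mult <- age_multiplier(ages, max_effect)
  all_aff <- rep(TRUE, length(ages))
  for (j in which(da_taxa)) {
    yj <- counts[, j]
    if (signal_mode == "counts_zeros" && any(yj > 0) && any(yj == 0))
      yj <- suppressWarnings(inject_zero_signal(yj, all_aff, mult,
                                                derive_seed(seed, j)))
    counts[, j] <- inject_count_signal(yj, all_aff, mult)
  }
  counts
}

#' Build a complete simulated experiment
#'
#' Composes the generator and injection steps: base ZINB table, uniform diet
#' groups, (optionally confounded) urbanization and age, an independent DA
#' taxon set per factor, then per-factor signal injection in the configured
#' mode. Library sizes are recomputed after injection (they are row sums by
#' definition).
#'
#' @param config a [simulation_config()].
#' @param seed seed (defaults to the config's).
#' @return a `prr_simulation` list: `counts` ([count_table]), `covariates`
#'   (data.frame: sample_id, diet, urbanization, age), `truth` (list with the
#'   factor x taxon `da_mask` and the multipliers), `config`.
#' @export
build_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "prr_sim_config"))
  base <- generate_base_counts(config, derive_seed(seed, 1))
  n <- config$n_samples; m <- config$n_taxa
  diet <- assign_diet_groups(n, derive_seed(seed, 2))
  conf <- assign_confounders(diet, derive_seed(seed, 3),
                             independent = !config$confounded)
  factors <- .diet_levels
  if (config$confounded) factors <- c(factors, "urban_low", "urban_high", "age")
  mask <- select_da_taxa(m, config$da_fraction, factors, derive_seed(seed, 4))

  Y <- base$counts
  zero_mode <- config$signal_mode == "counts_zeros"
  apply_group <- function(Y, affected, taxa, multiplier, tag) {
    for (j in which(taxa)) {
      yj <- Y[, j]
      if (zero_mode && any(yj > 0) && any(yj == 0))
        yj <- suppressWarnings(inject_zero_signal(
          yj, affected, multiplier, derive_seed(seed, 1000L * tag + j)))
      Y[, j] <- inject_count_signal(yj, affected, multiplier)
    }
    Y
  }
  for (g in seq_along(.diet_levels))
    Y <- apply_group(Y, diet == .diet_levels[g], mask[.diet_levels[g], ],
                     config$effect_size, g)
  if (config$confounded) {
    Y <- apply_group(Y, conf$urbanization == "low", mask["urban_low", ],
                     config$urban_effect, 5L)
    Y <- apply_group(Y, conf$urbanization == "high", mask["urban_high", ],
                     config$urban_effect, 6L)
    Y <- inject_age_signal(Y, conf$age, mask["age", ], config$signal_mode,
                           derive_seed(seed, 7000), config$age_max_effect)
  }
  empty <- rowSums(Y) == 0
  if (any(empty)) Y[empty, 1] <- 1   # keep library sizes positive

  counts <- count_table(Y, base$sample_ids, base$taxon_ids)
  covariates <- data.frame(sample_id = base$sample_ids, diet = diet,
                           urbanization = conf$urbanization, age = conf$age)
  multipliers <- c(stats::setNames(rep(config$effect_size, 4), .diet_levels),
                   if (config$confounded)
                     c(urban_low = config$urban_effect,
                       urban_high = config$urban_effect,
                       age = config$age_max_effect))
  structure(list(counts = counts, covariates = covariates,
                 truth = list(da_mask = mask, multipliers = multipliers),
                 config = config, seed = seed),
            class = "prr_simulation")
}

#' Ground-truth DA indicator for one tested factor
#'
#' A taxon counts as truly differentially abundant for the diet comparison if
#' it was made DA in any of the four diet groups (similarly for
#' urbanization's two groups).
#'
#' @param sim a `prr_simulation`.
#' @param factor `"diet"`, `"urbanization"` or `"age"`.
#' @return logical vector over taxa.
#' @export
da_truth <- function(sim, factor = c("diet", "urbanization", "age")) {
  factor <- match.arg(factor)
  mask <- sim$truth$da_mask
  rows <- switch(factor,
                 diet = .diet_levels,
                 urbanization = c("urban_low", "urban_high"),
                 age = "age")
  if (!all(rows %in% rownames(mask)))
    stop("factor '", factor, "' carries no signal in this simulation")
  apply(mask[rows, , drop = FALSE], 2, any)
}

#' Write a simulated experiment to tab-delimited files
#'
#' Emits `counts.tsv` (samples x taxa), `covariates.tsv` and `truth.tsv`
#' (taxon_id, factor, is_da, multiplier) into `dir`.
#'
#' @param sim a `prr_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "prr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write_covariates(sim$covariates, file.path(dir, "covariates.tsv"))
  mask <- sim$truth$da_mask
  truth <- do.call(rbind, lapply(rownames(mask), function(f)
    data.frame(taxon_id = sim$counts$taxon_ids, factor = f,
               is_da = mask[f, ],
               multiplier = ifelse(mask[f, ], sim$truth$multipliers[[f]], 1))))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.prr_simulation <- function(x, ...) {
  cat(sprintf("<prr_simulation> %d samples x %d taxa; %s signal x%.2f%s\n",
              x$config$n_samples, x$config$n_taxa, x$config$signal_mode,
              x$config$effect_size,
              if (x$config$confounded) " (confounded)" else ""))
  invisible(x)
}
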