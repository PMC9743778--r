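# The synthetic-data generator and signal-injection schemes.

test_that("base generator spans the Poisson limit and the overdispersed regime", {
  # near-Poisson configuration: index of dispersion close to 1
  cfg <- simulation_config(n_samples = 2000, n_taxa = 3,
                           mean_range = c(5, 5), dispersion_range = c(1e6, 1e6),
                           zero_range = c(0, 1e-9), libsize_sdlog = 0, seed = 2)
  ct <- generate_base_counts(cfg)
  iod <- apply(ct$counts, 2, var) / colMeans(ct$counts)
  expect_true(all(iod > 0.5 & iod < 2))
  # overdispersed regime: a taxon tuned to mean ~30 has variance far above it
  cfg2 <- simulation_config(n_samples = 2000, n_taxa = 2,
                            mean_range = c(30, 30), dispersion_range = c(0.8, 0.8),
                            zero_range = c(0.2, 0.2), libsize_sdlog = 0.5, seed = 3)
  ct2 <- generate_base_counts(cfg2)
  expect_true(all(apply(ct2$counts, 2, var) / colMeans(ct2$counts) > 5))
  # determinism
  expect_identical(generate_base_counts(cfg2)$counts,
                   generate_base_counts(cfg2)$counts)
})

test_that("diet groups are uniform over the four labels", {
  d <- assign_diet_groups(4e5, seed = 5)
  expect_equal(levels(d),
               c("meateater", "fisheater", "vegetarian", "vegan"))
  expect_true(all(abs(table(d) / 4e5 - 0.25) < 0.005))
  expect_length(assign_diet_groups(1, 1), 1)
  expect_identical(assign_diet_groups(50, 7), assign_diet_groups(50, 7))
})

test_that("confounder assignment matches the configured joint and conditional laws", {
  n <- 1e5
  diet <- assign_diet_groups(n, seed = 11)
  conf <- assign_confounders(diet, seed = 13)
  # joint P(meateater, low) = 20%
  p_joint <- mean(diet == "meateater" & conf$urbanization == "low")
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(p_joint - 0.20), 3 * se)
  # joint P(vegan, low) = 5%
  p_vl <- mean(diet == "vegan" & conf$urbanization == "low")
  expect_lt(abs(p_vl - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # no vegan is ever 60 or older; meateaters never in their twenties
  expect_equal(sum(conf$age >= 60 & diet == "vegan"), 0)
  expect_equal(sum(conf$age < 30 & diet == "meateater"), 0)
  # conditional P(age in [60,70) | meateater) = 40%
  i <- diet == "meateater"
  p60 <- mean(conf$age[i] >= 60)
  expect_lt(abs(p60 - 0.40), 3 * sqrt(0.4 * 0.6 / sum(i)))
  expect_true(all(conf$age >= 20 & conf$age <= 69))
  # independent mode breaks the association
  conf2 <- assign_confounders(diet, seed = 13, independent = TRUE)
  tab <- table(diet, conf2$urbanization)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 1e-4)
})

test_that("DA taxa counts are exact per factor and masks independent", {
  mask <- select_da_taxa(531, 0.10, c("a", "b"), seed = 17)
  expect_equal(unname(rowSums(mask)), c(53, 53))
  expect_identical(mask, select_da_taxa(531, 0.10, c("a", "b"), seed = 17))
  # expected overlap of two independent 10% masks is ~ m * f^2
  overlaps <- vapply(1:40, function(r) {
    m <- select_da_taxa(531, 0.10, c("a", "b"), seed = r)
    sum(m["a", ] & m["b", ])
  }, numeric(1))
  expect_equal(mean(overlaps), 53 * 53 / 531, tolerance = 0.2)
})

test_that("count signal multiplies non-zero counts with banker's rounding", {
  expect_equal(inject_count_signal(c(10, 0, 7), c(TRUE, TRUE, FALSE), 2),
               c(20, 0, 7))
  # x1.25 of 10 is 12.5 -> 12 under round-half-to-even
  expect_equal(inject_count_signal(10, TRUE, 1.25), 12)
  expect_equal(inject_count_signal(6, TRUE, 1.25), 8)   # 7.5 -> 8
  # overflow-safe for large counts
  expect_equal(inject_count_signal(1e9, TRUE, 5), 5e9)
  expect_error(inject_count_signal(5, TRUE, 0.5), "multiplier")
})

test_that("zero signal conserves the non-zero multiset and honors the odds", {
  withr::local_seed(19)
  y <- c(rpois(50, 20) + 1, rep(0, 50))   # 50 non-zero, 50 zero: odds 1
  aff <- rep(c(TRUE, FALSE), 50)
  out <- inject_zero_signal(y, aff, 2, seed = 23)
  # conservation: non-zero values are a sub-multiset of the originals
  tin <- table(y[y > 0]); tout <- table(out[out > 0])
  expect_true(all(names(tout) %in% names(tin)))
  expect_true(all(tout <= tin[names(tout)]))
  # odds arithmetic: baseline odds 1 -> affected probability 2/3,
  # unaffected 1/2; probe the first two positions, which are filled before
  # the without-replacement pool can deplete
  draws <- vapply(1:400, function(r) {
    o <- inject_zero_signal(y, aff, 2, seed = r)
    c(o[1] > 0, o[2] > 0)
  }, logical(2))
  expect_lt(abs(mean(draws[1, ]) - 2 / 3), 3 * sqrt(2/9 / 400))
  expect_lt(abs(mean(draws[2, ]) - 1 / 2), 3 * sqrt(0.25 / 400))
  # saturation: a huge multiplier places exactly the pool size of non-zeros
  out2 <- inject_zero_signal(y, rep(TRUE, 100), 1e6, seed = 29)
  expect_equal(sum(out2 > 0), 50)
  # degenerate columns are skipped with a warning
  expect_warning(r <- inject_zero_signal(rep(0, 10), rep(TRUE, 10), 2, 1),
                 "skipped")
  expect_equal(r, rep(0, 10))
})

test_that("age effect ramps linearly from x1 at 20 to x5 at 69", {
  expect_equal(age_multiplier(20), 1)
  expect_equal(age_multiplier(69), 5)
  expect_equal(age_multiplier(44.5), 3)
  expect_error(age_multiplier(75), "20, 69")
  # age 20 means no effect on that sample's counts
  counts <- matrix(c(5, 8, 0, 3), 2, 2)
  out <- inject_age_signal(counts, ages = c(20, 69), da_taxa = c(TRUE, FALSE),
                           signal_mode = "counts", seed = 1)
  expect_equal(out[1, ], counts[1, ])
  expect_equal(out[2, 1], 8 * 5)
  expect_equal(out[, 2], counts[, 2])     # non-DA taxon untouched
})

test_that("experiment bookkeeping: only DA x affected cells change", {
  sim <- small_sim(seed = 43, n = 50, m = 20, mode = "counts")
  cfg <- sim$config
  base <- generate_base_counts(cfg, derive_seed(sim$seed, 1))
  mask <- sim$truth$da_mask
  diet <- sim$covariates$diet
  changed <- sim$counts$counts != base$counts
  for (j in seq_len(cfg$n_taxa)) {
    if (!any(mask[, j])) {
      expect_identical(sim$counts$counts[, j], base$counts[, j])
    } else {
      affected <- diet %in% rownames(mask)[mask[, j]]
      expect_true(all(!changed[!affected, j]))
    }
  }
  # library sizes recomputed after injection
  expect_equal(sim$counts$library_sizes, unname(rowSums(sim$counts$counts)))
})

test_that("confounded mode couples diet with urbanization and injects age signal", {
  cfg <- simulation_config(n_samples = 1e4, n_taxa = 2, confounded = TRUE,
                           seed = 47)
  diet <- assign_diet_groups(1e4, derive_seed(47, 2))
  conf <- assign_confounders(diet, derive_seed(47, 3))
  tab <- table(diet, conf$urbanization)
  expect_lt(chisq.test(tab)$p.value, 1e-6)
  sim <- small_sim(seed = 49, n = 60, m = 15, confounded = TRUE)
  expect_setequal(rownames(sim$truth$da_mask),
                  c("meateater", "fisheater", "vegetarian", "vegan",
                    "urban_low", "urban_high", "age"))
  expect_length(da_truth(sim, "age"), 15)
})

test_that("mean count of affected DA cells is non-decreasing in effect size", {
  means <- vapply(c(1.25, 2, 5), function(e) {
    sim <- small_sim(seed = 53, n = 80, m = 20, mode = "counts",
                     effect_size = e)
    mask <- sim$truth$da_mask
    diet <- sim$covariates$diet
    tot <- 0; cnt <- 0
    for (g in rownames(mask)) for (j in which(mask[g, ])) {
      v <- sim$counts$counts[diet == g, j]
      tot <- tot + sum(v); cnt <- cnt + length(v)
    }
    tot / cnt
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("simulated experiments round-trip through the text interface", {
  sim <- small_sim(seed = 59, n = 30, m = 6)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  ct <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(ct$counts, sim$counts$counts)
  expect_equal(ct$library_sizes, sim$counts$library_sizes)
  cov <- read_covariates(file.path(dir, "covariates.tsv"))
  expect_equal(as.character(cov$diet), as.character(sim$covariates$diet))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 6 * 4)
  expect_equal(sum(truth$is_da), sum(sim$truth$da_mask))
})
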