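test_that("default configuration matches the reference design and is deterministic", {
  cfg <- sim_config(seed = 3)
  st <- simulate_complete_matrix(cfg)
  expect_equal(dim(st$complete$values), c(6105L, 61L))
  expect_equal(sum(st$dep$is_dep), 3000L)
  # 8 donors in fractions 1-7, 5 in fraction 8
  tab <- table(st$complete$design$fraction)
  expect_equal(as.integer(tab), c(rep(8L, 7), 5L))
  expect_false(anyNA(st$complete$values))

  a <- simulate_study(reduced_config(seed = 11))
  b <- simulate_study(reduced_config(seed = 11))
  expect_identical(a$observed$values, b$observed$values)
  expect_identical(a$missingness, b$missingness)
  expect_identical(a$dep, b$dep)
})

test_that("planted DEP shifts are recovered by a direct group-mean oracle", {
  cfg <- sim_config(n_proteins = 100, n_dep = 20, dep_effect_mean = 2,
                    dep_effect_sd = 0, seed = 1)
  st <- simulate_complete_matrix(cfg)
  des <- st$complete$design
  dep <- st$dep[st$dep$is_dep, ]
  shifts <- vapply(seq_len(nrow(dep)), function(i) {
    x <- st$complete$values[dep$protein[i], ]
    g <- as.character(dep$dep_group[i])
    mean(x[des$group == g]) - mean(x[des$group != g])
  }, numeric(1))
  # |shift| = 2 exactly up to sampling noise of the group means
  expect_equal(mean(abs(shifts)), 2, tolerance = 0.05)
  expect_equal(sign(shifts), sign(dep$dep_effect))

  cfg0 <- sim_config(n_proteins = 200, n_dep = 100, dep_effect_mean = 0,
                     dep_effect_sd = 0, seed = 2)
  st0 <- simulate_complete_matrix(cfg0)
  des0 <- st0$complete$design
  dep0 <- st0$dep[st0$dep$is_dep, ]
  shifts0 <- vapply(seq_len(nrow(dep0)), function(i) {
    x <- st0$complete$values[dep0$protein[i], ]
    g <- as.character(dep0$dep_group[i])
    mean(x[des0$group == g]) - mean(x[des0$group != g])
  }, numeric(1))
  expect_gt(t.test(shifts0)$p.value, 0.01)
})

test_that("missingness truth bookkeeping conserves cells and respects rates", {
  st <- simulate_study(reduced_config(seed = 5))
  lab <- st$missingness
  n <- length(lab)
  expect_equal(sum(lab == "observed") + sum(lab == "MNAR") + sum(lab == "MAR"), n)
  expect_identical(is.na(st$observed$values), lab != "observed")
  cfg <- st$config
  expect_equal(sum(lab == "MNAR") / n, cfg$mnar_rate, tolerance = 1e-3)
  expect_equal(sum(lab == "MAR") / n, cfg$mar_rate, tolerance = 1e-3)
  # observed cells untouched relative to complete matrix
  keep <- lab == "observed"
  expect_identical(st$observed$values[keep], st$complete$values[keep])
})

test_that("zero rates are a no-op and MNAR censoring stays below the threshold", {
  st0 <- simulate_study(reduced_config(seed = 2, mnar_rate = 0, mar_rate = 0))
  expect_identical(st0$observed$values, st0$complete$values)
  expect_true(all(st0$missingness == "observed"))

  st1 <- simulate_study(reduced_config(seed = 2, mnar_rate = 0.1,
                                       mnar_censor_quantile = 0.12,
                                       mar_rate = 0))
  x0 <- quantile(st1$complete$values, 0.12, names = FALSE)
  miss_vals <- st1$complete$values[st1$missingness == "MNAR"]
  expect_true(all(miss_vals < x0))
})

test_that("MNAR cells are stochastically lower-intensity than MAR cells", {
  st <- simulate_study(reduced_config(seed = 9))
  mnar_v <- st$complete$values[st$missingness == "MNAR"]
  mar_v <- st$complete$values[st$missingness == "MAR"]
  expect_gt(length(mnar_v), 1000)
  expect_gt(length(mar_v), 1000)
  w <- wilcox.test(mnar_v, mar_v, alternative = "less")
  expect_lt(w$p.value, 0.01)
})

test_that("injected truth labels match a transcription of the sampling scheme", {
  cfg <- sim_config(n_proteins = 20, n_dep = 5, fractions = c(1, 4, 7),
                    n_donors = 2, mnar_rate = 0.1, mar_rate = 0.1,
                    mnar_censor_quantile = 0.2, seed = 31)
  st <- simulate_complete_matrix(cfg)
  got <- inject_missingness(st)$missingness

  m <- st$complete$values
  set.seed(cfg$seed + 1L)
  exp_lab <- matrix("observed", nrow(m), ncol(m), dimnames = dimnames(m))
  n_mnar <- round(cfg$mnar_rate * length(m))
  x0 <- quantile(m, cfg$mnar_censor_quantile, names = FALSE)
  pool <- which(m < x0)
  w <- plogis((x0 - m[pool]) / cfg$mnar_steepness)
  keys <- rexp(length(pool)) / w
  exp_lab[pool[order(keys)[seq_len(min(n_mnar, length(pool)))]]] <- "MNAR"
  n_mar <- round(cfg$mar_rate * length(m))
  n_mar_prot <- max(1L, round(cfg$mar_protein_frac * nrow(m)))
  eligible <- which(rowMeans(m) >= x0 + cfg$mar_margin)
  if (length(eligible) < n_mar_prot) eligible <- seq_len(nrow(m))
  mar_rows <- eligible[sample.int(length(eligible),
                                  min(n_mar_prot, length(eligible)))]
  cand <- which(exp_lab == "observed" & row(m) %in% mar_rows)
  exp_lab[sample(cand, min(n_mar, length(cand)))] <- "MAR"
  expect_identical(got, exp_lab)
})

test_that("rate validation refuses unusable configurations", {
  expect_error(sim_config(mnar_rate = 0.5, mar_rate = 0.5), "sparse")
  expect_error(sim_config(n_proteins = 10, n_dep = 11), "n_dep")
  expect_error(sim_config(mnar_rate = 0.2, mnar_censor_quantile = 0.1),
               "censor")
})

test_that("simulated peptide tables have valid spans and fixed-seed determinism", {
  expect_equal(nrow(simulate_peptide_table(0)), 0)
  p1 <- simulate_peptide_table(40, seed = 4)
  p2 <- simulate_peptide_table(40, seed = 4)
  expect_identical(p1, p2)
  expect_true(all(p1$start >= 1 & p1$end <= 441 & p1$start <= p1$end))
  expect_error(simulate_peptide_table(5, protein_length = 5))
})

test_that("simulated NTA readings follow the requested size law", {
  pt <- simulate_nta_readings(1000, dist = "point", at = 130, dilution = 10,
                              replicates = 2, seed = 1)
  expect_true(all(pt$bin_center_nm == 130))
  expect_equal(sum(pt$concentration), 2 * 1000 / 10)

  ln <- simulate_nta_readings(50000, dist = "lognormal", meanlog = log(130),
                              sdlog = 0.25, dilution = 1, replicates = 1,
                              seed = 2)
  binned_mean <- sum(ln$bin_center_nm * ln$concentration) / sum(ln$concentration)
  expect_equal(binned_mean, 130 * exp(0.25^2 / 2), tolerance = 0.01)
  expect_error(simulate_nta_readings(10, dilution = 0), "dilution")
})
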