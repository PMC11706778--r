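test_that("classification equals exhaustive evaluation of the stated rule", {
  m <- make_cls_toy()
  cutoffs <- c(`1` = 14.0, `4` = 14.3, `7` = 15.0)
  cls <- classify_missingness(m, cutoffs)

  # independent double-loop evaluation
  des <- m$design
  expected <- list()
  for (p in rownames(m$values)) for (f in unique(des$fraction)) {
    cols <- des$fraction == f
    x <- m$values[p, cols]
    if (!anyNA(x)) next
    lab <- if (all(is.na(x))) "MNAR"
           else if (mean(x, na.rm = TRUE) < cutoffs[as.character(f)]) "MNAR"
           else "MAR"
    for (s in des$sample[cols][is.na(x)]) {
      expected[[paste(p, s)]] <- lab
    }
  }
  got <- setNames(cls$label, paste(cls$protein, cls$sample))
  expect_mapequal(as.list(got), expected)
  expect_true(all(cls$absent[cls$protein == "P1"]))
  expect_equal(nrow(cls), sum(is.na(m$values)))
})

test_that("a fraction mean below its printed cutoff yields MNAR, above yields MAR", {
  des <- tiny_design(n_donors = 2, fractions = c(1, 4, 7))
  vals <- rbind(P1 = c(16, 16, 13.0, NA, 16, 16),   # F4 mean 13.0 < 14.3
                P2 = c(16, 16, 15.0, NA, 16, 16))   # F4 mean 15.0 > 14.3
  colnames(vals) <- des$sample
  cls <- classify_missingness(toy_lfq(vals, des), default_fraction_cutoffs())
  expect_equal(cls$label[cls$protein == "P1"], "MNAR")
  expect_equal(cls$label[cls$protein == "P2"], "MAR")
  expect_error(classify_missingness(toy_lfq(vals, des), c(`1` = 14)),
               "fraction")
})

test_that("raising a cutoff only ever converts MAR labels to MNAR", {
  st <- simulate_study(reduced_config(seed = 3))
  key <- function(cls) paste(cls$protein, cls$sample)
  lo <- classify_missingness(st$observed, 10)
  hi <- classify_missingness(st$observed, 13)
  mnar_lo <- key(lo)[lo$label == "MNAR"]
  mnar_hi <- key(hi)[hi$label == "MNAR"]
  expect_true(all(mnar_lo %in% mnar_hi))
  expect_gt(length(mnar_hi), length(mnar_lo))
})

test_that("MNAR draws match their stated distribution and a seeded transcription", {
  set.seed(88)
  des <- tiny_design(n_donors = 2, fractions = c(1, 4, 7))
  n <- 20000
  vals <- matrix(rnorm(n * nrow(des), 14, 2), nrow = n,
                 dimnames = list(sprintf("P%05d", 1:n), NULL))
  colnames(vals) <- des$sample
  vals[seq_len(10000), 1] <- NA  # many MNAR cells in sample 1
  m <- toy_lfq(vals, des)
  cls <- classify_missingness(m, cutoffs = 100)  # everything MNAR
  imp <- impute_mnar(m, cls, seed = 5)
  expect_identical(imp$values[!is.na(vals)], vals[!is.na(vals)])

  mu <- mean(vals[, 1], na.rm = TRUE)
  sig <- sd(vals[, 1], na.rm = TRUE)
  drawn <- imp$values[is.na(vals[, 1]), 1]
  mc_se <- 0.3 * sig / sqrt(length(drawn))
  expect_lt(abs(mean(drawn) - (mu - 1.8 * sig)), 3 * mc_se)

  # transcription of the documented draw order: per sample, proteins in
  # name order, one rnorm per cell
  set.seed(5)
  expected <- rnorm(length(drawn), mu - 1.8 * sig, 0.3 * sig)
  expect_identical(unname(drawn), expected)
})

test_that("kNN MAR imputation equals a brute-force oracle on a toy matrix", {
  des <- tiny_design(n_donors = 2, fractions = c(1, 4))
  vals <- rbind(P1 = c(10, 11, 12, NA),
                P2 = c(10, 11, 12, 13),
                P3 = c(10.2, 11.2, 12.2, 13.4),
                P4 = c(20, 21, 22, 23))
  colnames(vals) <- des$sample
  m <- toy_lfq(vals, des)
  cls <- classify_missingness(m, cutoffs = 0)  # nothing below cutoff -> MAR
  expect_equal(cls$label, "MAR")
  imp <- impute_mar(m, cls, k = 2)
  # neighbours of P1 on jointly observed columns 1:3 are P2, P3 (then P4)
  expect_equal(imp$values["P1", 4], mean(c(13, 13.4)))
  expect_identical(imp$values[-1, ], vals[-1, ])

  # all k neighbours carrying the same value v impute exactly v
  imp1 <- impute_mar(m, cls, k = 1)
  expect_equal(imp1$values["P1", 4], 13)
  expect_identical(impute_mar(m, cls[0, ], k = 2)$values, vals)
})

test_that("hybrid imputation satisfies its contracts on a simulated study", {
  st <- simulate_study(reduced_config(seed = 13))
  res <- hybrid_impute(st$observed, cutoffs = 12, seed = 2)
  obs_mask <- !is.na(st$observed$values)
  expect_identical(res$imputed$values[obs_mask], st$observed$values[obs_mask])
  expect_false(anyNA(res$imputed$values))
  expect_equal(res$report$n_missing, sum(!obs_mask))
  expect_equal(sum(res$report$counts_by_fraction), sum(!obs_mask))

  # MNAR-imputed values sit stochastically below MAR-imputed ones
  cls <- res$classification
  j <- st$observed$design$sample[1]
  pick <- function(lab) {
    sel <- cls[cls$label == lab & cls$sample == j, ]
    res$imputed$values[cbind(match(sel$protein, rownames(res$imputed$values)),
                             match(sel$sample, colnames(res$imputed$values)))]
  }
  mnar_v <- pick("MNAR"); mar_v <- pick("MAR")
  expect_gt(length(mnar_v), 100)
  expect_lt(wilcox.test(mnar_v, mar_v, alternative = "less")$p.value, 1e-6)

  # complete input is returned unchanged
  complete <- simulate_study(reduced_config(seed = 13, mnar_rate = 0,
                                            mar_rate = 0))
  res0 <- hybrid_impute(complete$observed, cutoffs = 12, seed = 2)
  expect_identical(res0$imputed$values, complete$observed$values)
  expect_equal(res0$report$n_missing, 0L)
})

test_that("classification agrees with the injected truth on seeded simulations", {
  for (s in c(1, 5)) {
    st <- simulate_study(reduced_config(seed = s))
    cls <- classify_missingness(st$observed, cutoffs = 12)
    truth <- st$missingness[cbind(match(cls$protein, rownames(st$missingness)),
                                  match(cls$sample, colnames(st$missingness)))]
    expect_gte(mean(cls$label == truth), 0.80)
  }
})
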