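# small analysis-like table with controllable missingness
sim_table <- function(n = 120, miss = 0, seed = 1, mar = FALSE) {
  set.seed(seed)
  x <- rnorm(n, 5, 1)
  y <- 0.6 * x + rnorm(n, 0, 0.8)
  z <- rbinom(n, 1, 0.6)
  df <- tibble::tibble(respondent_id = seq_len(n), x = x, y = y, z = z)
  if (miss > 0) {
    if (mar) {
      # missingness in y depends on the observed covariate x
      p <- plogis(scale(x)[, 1] * 1.2 + qlogis(miss))
      df$y[runif(n) < p] <- NA
    } else {
      df$y[sample(n, round(miss * n))] <- NA
    }
  }
  df
}

test_that("a complete table imputes to m identical copies of itself", {
  df <- sim_table(60, miss = 0)
  mids <- impute_fcs(df, m = 3, maxit = 3, seed = 42)
  for (i in 1:3) expect_equal(complete_table(mids, i), df)
})

test_that("imputation is seed-deterministic and never edits observed cells", {
  df <- sim_table(100, miss = 0.3, seed = 2)
  m1 <- impute_fcs(df, m = 3, maxit = 5, seed = 7)
  m2 <- impute_fcs(df, m = 3, maxit = 5, seed = 7)
  expect_equal(m1$imputations, m2$imputations)
  m3 <- impute_fcs(df, m = 3, maxit = 5, seed = 8)
  expect_false(isTRUE(all.equal(m1$imputations, m3$imputations)))

  obs <- !is.na(df$y)
  for (i in 1:3) {
    done <- complete_table(m1, i)
    expect_equal(done$y[obs], df$y[obs])
    expect_equal(done$x, df$x)
    expect_false(anyNA(done$y))
  }
})

test_that("binary variables impute to the binary support", {
  df <- sim_table(150, seed = 3)
  df$z[sample(150, 40)] <- NA
  mids <- impute_fcs(df, m = 2, maxit = 4, seed = 5)
  for (i in 1:2) expect_true(all(complete_table(mids, i)$z %in% c(0, 1)))
})

test_that("imputation guards its preconditions", {
  df <- sim_table(30)
  expect_error(impute_fcs(df, m = 1, seed = 1), "m must be")
  expect_error(impute_fcs(df, m = 2, maxit = 2), "seed")
  df_all_na <- df; df_all_na$y <- NA_real_
  expect_error(impute_fcs(df_all_na, m = 2, seed = 1), "entirely missing")
})

test_that("Rubin's rules reproduce the worked two-imputation example", {
  p <- pool_estimates(c(1.0, 2.0), c(0.5, 0.5))
  expect_equal(p$estimate, 1.5)
  expect_equal(p$W, 0.25)
  expect_equal(p$B, 0.5)
  expect_equal(p$T, 0.25 + (1 + 1 / 2) * 0.5)
  expect_equal(p$df, (2 - 1) * (1 + 0.25 / ((1 + 1 / 2) * 0.5))^2)
})

test_that("pooling degenerates gracefully and ignores order", {
  same <- pool_estimates(c(2, 2, 2), c(.3, .3, .3))
  expect_equal(same$B, 0)
  expect_equal(same$se, .3)
  expect_equal(same$df, Inf)

  a <- pool_estimates(c(1, 3, 2), c(.2, .4, .3))
  b <- pool_estimates(c(3, 2, 1), c(.4, .3, .2))
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$T, b$T)

  expect_error(pool_estimates(1, .5), "at least 2")
  expect_error(pool_estimates(c(1, 2), .5), "differ in length")
})

test_that("Barnard-Rubin df never exceeds the classic df and stays positive", {
  set.seed(21)
  for (i in 1:10) {
    est <- rnorm(5); se <- runif(5, .2, .5)
    old <- pool_estimates(est, se, df_com = Inf)
    br <- pool_estimates(est, se, df_com = 50)
    expect_gt(br$df, 0)
    expect_lte(br$df, old$df)
    expect_lte(br$df, 50 + 1)
    expect_gte(old$T, old$W)
  }
})

test_that("pooled_analysis equals hand pooling and collapses on complete data", {
  df <- sim_table(100, miss = 0.25, seed = 4)
  mids <- impute_fcs(df, m = 5, maxit = 5, seed = 11)
  mean_diff <- function(dat) {
    tt <- paired_t(dat$x, dat$y)
    tibble::tibble(term = "x_minus_y", estimate = tt$estimate, se = tt$se)
  }
  pooled <- pooled_analysis(mids, mean_diff)
  est <- vapply(mids$imputations,
                function(d) paired_t(d$x, d$y)$estimate, numeric(1))
  se <- vapply(mids$imputations,
               function(d) paired_t(d$x, d$y)$se, numeric(1))
  hand <- pool_estimates(est, se)
  expect_equal(pooled$estimate, hand$estimate)
  expect_equal(pooled$se, hand$se)
  expect_equal(pooled$p.value, hand$p.value)

  full <- sim_table(100, miss = 0)
  mids0 <- impute_fcs(full, m = 3, maxit = 2, seed = 1)
  pooled0 <- pooled_analysis(mids0, mean_diff)
  single <- paired_t(full$x, full$y)
  expect_equal(pooled0$estimate, single$estimate)
  expect_equal(pooled0$se, single$se)
  rng <- fit_stat_range(mids0, function(d) cor(d$x, d$y), "r")
  expect_equal(rng$min, rng$max)
})

test_that("complete-case and MI agree exactly when nothing is missing", {
  lex <- demo_lexicon()
  resp <- make_responses(list(
    r1 = list(self_t1 = c("sad", "fear", "peace"),
              other_t1 = c("fear", "scary", "sad"),
              self_t2 = c("peace", "peaceful", "natural")),
    r2 = list(self_t1 = c("death", "die", "sad"),
              other_t1 = c("sad", "fear", "fear"),
              self_t2 = c("natural", "peace", "sad")),
    r3 = list(self_t1 = c("peaceful", "natural", "peace"),
              other_t1 = c("scary", "die", "death"),
              self_t2 = c("peace", "sad", "peaceful"))
  ))
  at <- build_analysis_table(resp, NULL, lex)
  mids <- impute_fcs(at, m = 3, maxit = 2, seed = 9)
  cc <- compare_activities(at, mode = "complete")
  mi <- compare_activities(at, mode = "mi", mids = mids)
  expect_equal(mi$estimate, cc$estimate)
  expect_equal(mi$mean_a, cc$mean_a)
  # with B = 0 the pooled SE reduces to the within SE
  expect_equal(mi$se, cc$se)
})

test_that("pooled means cover the generating truth under MCAR missingness", {
  hits <- 0L
  reps <- 40
  for (r in seq_len(reps)) {
    df <- sim_table(150, miss = 0.3, seed = 100 + r)
    mids <- impute_fcs(df, m = 5, maxit = 5, seed = 200 + r)
    res <- pooled_analysis(mids, function(dat) {
      tibble::tibble(term = "mean_y", estimate = mean(dat$y),
                     se = sd(dat$y) / sqrt(nrow(dat)),
                     df_com = nrow(dat) - 1)
    })
    truth <- 0.6 * 5  # E[y] under the generator
    if (res$conf.low <= truth && truth <= res$conf.high) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})
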