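test_that("reference transforms reproduce the published predictions", {
  tr <- k5m_transforms()
  expect_equal(apply_transform(0, tr[["0.5"]]), 8.73)
  expect_equal(apply_transform(100, tr[["0.5"]]), 73.73)
  expect_equal(apply_transform(0, tr[["1"]]), 11.27)
  expect_equal(apply_transform(0, tr[["2"]]), 11.01)
  simple <- k5m_transforms(simplified = TRUE)
  expect_equal(apply_transform(50, simple[["0.5"]]), 40)
  expect_equal(simple[["1"]]$slope, 0.6)
})

test_that("OLS recovers exact coefficients from noiseless linear data", {
  pre <- seq(15, 120, length.out = 20)
  for (cf in list(c(0.65, 8.73), c(0.58, 11.27), c(0.55, 11.01))) {
    m <- fit_transform(pre, cf[1] * pre + cf[2], t_s = 0.5)
    expect_equal(m$slope, cf[1], tolerance = 1e-10)
    expect_equal(m$intercept, cf[2], tolerance = 1e-10)
    # fit-then-apply is the identity on the training relation
    expect_equal(apply_transform(pre, m), cf[1] * pre + cf[2],
                 tolerance = 1e-10)
  }
})

test_that("OLS slope is recovered within 0.05 at n = 28 with 2-nm noise", {
  set.seed(28)
  pre <- runif(28, 15, 120)
  post <- 0.65 * pre + 8.73 + rnorm(28, 0, 2)
  m <- fit_transform(pre, post, t_s = 0.5)
  expect_lt(abs(m$slope - 0.65), 0.05)
})

test_that("constant predictors are a singular fit", {
  expect_error(fit_transform(rep(50, 5), rnorm(5)), "singular")
  expect_error(fit_transform(1:5, 1:4), "equal length")
})

test_that("Pearson correlation handles exact and random cases", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    want <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_r(a, b)$r, want, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("paired t matches the textbook formula", {
  b <- c(10, 20, 30)
  a <- b + c(1, 2, 3)
  res <- paired_t(a, b)
  expect_equal(res$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  set.seed(6)
  for (i in 1:50) {
    x <- rnorm(12, 50, 10); y <- x + rnorm(12, 3, 2)
    d <- x - y
    want_t <- mean(d) / (sd(d) / sqrt(length(d)))
    res <- paired_t(x, y)
    expect_equal(res$t_stat, want_t, tolerance = 1e-12)
    expect_equal(res$p_value,
                 2 * pt(-abs(want_t), length(d) - 1), tolerance = 1e-12)
  }
})

test_that("paired t sign flips under argument swap; p is unchanged", {
  set.seed(8)
  a <- rnorm(10, 60, 5); b <- a + rnorm(10, 4, 1)
  r1 <- paired_t(a, b); r2 <- paired_t(b, a)
  expect_equal(r1$t_stat, -r2$t_stat, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_error(paired_t(a, a), "degenerate")
})

test_that("ICC(2,1) is 1 for perfect agreement and ~0 for independent noise", {
  subj <- c(40, 55, 70, 90, 120)
  expect_equal(icc(cbind(subj, subj))$icc, 1)
  set.seed(9)
  noise <- cbind(rnorm(500), rnorm(500))
  expect_lt(abs(icc(noise)$icc), 0.1)
})

test_that("ICC(2,1) matches an independent ANOVA decomposition", {
  worked <- matrix(c(9, 6, 8, 7, 2, 1, 4, 3), ncol = 2)
  expect_equal(icc(worked)$icc, icc21_aov(worked), tolerance = 1e-10)
  set.seed(10)
  for (i in 1:20) {
    m <- matrix(rnorm(8 * 3, 60, 15), 8, 3) +
      rnorm(8, 0, 10)              # subject effects
    expect_equal(icc(m)$icc, icc21_aov(m), tolerance = 1e-10)
  }
})

test_that("ICC is shift-invariant and decreases monotonically with noise", {
  set.seed(12)
  base <- rnorm(30, 60, 20)
  m0 <- cbind(base, base + rnorm(30, 0, 1))
  expect_equal(icc(m0)$icc, icc(m0 + 100)$icc, tolerance = 1e-12)
  sds <- c(0.5, 2, 8, 25)
  iccs <- vapply(sds, function(s) {
    set.seed(42)
    icc(cbind(base + rnorm(30, 0, s), base + rnorm(30, 0, s)))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
})

test_that("icc rejects incomplete or undersized designs", {
  m <- matrix(c(1, 2, NA, 4), 2, 2)
  expect_error(icc(m), "incomplete")
  expect_error(icc(matrix(1:2, 1, 2)), ">= 2")
})

test_that("reliability report computes per-kind, per-timepoint ICCs", {
  set.seed(13)
  subjects <- sprintf("s%02d", 1:6)
  base <- runif(6, 30, 110)
  rows <- list()
  for (kd in c("roi", "blink")) for (tp in c(0.5, 1, 2)) for (rep_ in 1:2)
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = subjects, t_s = tp, kind = kd, replicate = rep_,
      mean_llt_nm = base + rnorm(6, 0, 0.5))
  runs <- do.call(rbind, rows)
  rel <- reliability_report(runs)
  expect_equal(nrow(rel), 6)
  expect_true(all(rel$icc > 0.9))
  # identical replicates give ICC exactly 1
  runs2 <- runs
  runs2$mean_llt_nm <- rep(base, nrow(runs2) / 6)
  expect_true(all(reliability_report(runs2)$icc == 1))
  # a single subject is an incomplete design
  expect_error(reliability_report(runs[runs$subject_id == "s01", ]),
               "incomplete")
})
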