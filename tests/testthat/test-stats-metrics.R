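test_that("R2 is the squared Pearson correlation", {
  obs <- c(0, 1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, -obs), 1)
  pred <- c(0, 1, 2, 2)
  expect_equal(r_squared(obs, pred), cor(obs, pred)^2)
  expect_warning(z <- r_squared(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_equal(z, 0)
})

test_that("Fisher F reproduces the printed table cells after rounding", {
  cells <- list(
    list(r2 = 0.4396, n = 31, f = 23),
    list(r2 = 0.8346, n = 23, f = 106),
    list(r2 = 0.8037, n = 30, f = 115),
    list(r2 = 0.2617, n = 24, f = 8)
  )
  for (cell in cells) {
    expect_equal(round(fisher_f(cell$r2, cell$n)), cell$f)
  }
  expect_equal(fisher_f(0, 10), 0)
  expect_identical(fisher_f(1, 10), Inf)
  expect_error(fisher_f(1.2, 10), class = "coral_invalid_parameter")
})

test_that("RMSE and MAE follow the standard residual definitions", {
  expect_equal(rmse_mae(c(1, 2, 3), c(1, 2, 3)), c(rmse = 0, mae = 0))
  expect_equal(rmse_mae(c(1, -1), c(0, 0)), c(rmse = 1, mae = 1))
  expect_equal(rmse_mae(c(3, 0, 0, 0), c(0, 0, 0, 0)),
               c(rmse = 1.5, mae = 0.75))
  expect_error(rmse_mae(1:3, 1:4), class = "coral_input_error")
})

test_that("Q2 equals an explicit leave-one-out refit oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- 1 + 0.8 * x + rnorm(n, 0, 0.5)
    press <- 0
    for (i in seq_len(n)) {
      fit <- lm(y[-i] ~ x[-i])
      pred_i <- unname(coef(fit)[1] + coef(fit)[2] * x[i])
      press <- press + (y[i] - pred_i)^2
    }
    q2_oracle <- unname(1 - press / sum((y - mean(y))^2))
    expect_equal(q2_loo(x, y), q2_oracle, tolerance = 1e-10)
  }
})

test_that("Q2 is 1 for collinear data, typically negative for pure noise, and <= R2", {
  x <- 1:10
  expect_equal(q2_loo(x, 2 * x - 3), 1)
  set.seed(21)
  neg <- replicate(20, {
    x <- rnorm(20); y <- rnorm(20)
    q2_loo(x, y) <= 0
  })
  expect_gt(mean(neg), 0.6)
  set.seed(22)
  for (rep in 1:10) {
    x <- rnorm(12); y <- 0.5 * x + rnorm(12)
    fit <- lm(y ~ x)
    expect_lte(q2_loo(x, y), summary(fit)$r.squared + 1e-12)
  }
  expect_error(q2_loo(c(1, 1, 1, 2), c(1, 2, 3, 4)),
               class = "coral_degenerate_descriptor")
})

test_that("IIC damps the correlation by residual-class MAE asymmetry", {
  # symmetric residuals: equal class MAEs, IIC = r
  obs <- c(0, 1, 2, 3)
  pred <- c(0.5, 0.5, 2.5, 2.5)  # residuals -0.5, +0.5, -0.5, +0.5
  expect_equal(iic(obs, pred), cor(obs, pred))
  # one-signed residuals: empty class convention gives 0
  expect_equal(iic(obs, obs - 1), 0)
  # exact fit: ratio 1, IIC = r = 1
  expect_equal(iic(obs, obs), 1)
  # hand-computed arithmetic oracle
  obs2 <- c(0, 1, 2, 3, 4)
  pred2 <- c(0.1, 1.1, 2.1, 2.8, 3.9)
  res <- obs2 - pred2                      # -0.1 -0.1 -0.1 +0.2 +0.1
  mae_neg <- mean(abs(res[res < 0]))       # 0.1
  mae_pos <- mean(res[res >= 0])           # 0.15
  manual <- cor(obs2, pred2) * min(mae_neg, mae_pos) / max(mae_neg, mae_pos)
  expect_equal(iic(obs2, pred2), manual, tolerance = 1e-12)
})

test_that("|IIC| never exceeds |r|", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    obs <- rnorm(n); pred <- 0.5 * obs + rnorm(n)
    expect_lte(abs(iic(obs, pred)), abs(cor(obs, pred)) + 1e-12)
  }
})

test_that("CII equals the naive leave-one-out correlation oracle", {
  naive_cii <- function(obs, pred) {
    r <- cor(obs, pred)
    gains <- vapply(seq_along(obs), function(k) {
      max(0, cor(obs[-k], pred[-k]) - r)
    }, numeric(1))
    1 - sum(gains)
  }
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(6:25, 1)
    obs <- rnorm(n); pred <- 0.7 * obs + rnorm(n, 0, 0.5)
    expect_equal(cii(obs, pred), naive_cii(obs, pred), tolerance = 1e-12)
  }
})

test_that("CII is 1 on collinear data, below 1 with a gross outlier, and affine-invariant", {
  x <- 1:12
  expect_equal(cii(x, 3 * x + 2), 1)
  obs <- c(1:10, 30)
  pred <- c(1:10 + c(0.2, -0.1, 0.1, -0.2, 0.15, -0.15, 0.1, -0.1, 0.2, -0.2), 14)
  expect_lt(cii(obs, pred), 1)
  set.seed(55)
  obs2 <- rnorm(15); pred2 <- obs2 + rnorm(15)
  expect_equal(cii(obs2, pred2), cii(obs2, 5 * pred2 - 7), tolerance = 1e-10)
  expect_error(cii(c(1, 1, 1, 2), c(1, 2, 3, 4)),
               class = "coral_degenerate_statistic")
})

test_that("the statistics panel degrades to NA instead of failing", {
  st <- fit_statistics(rep(1, 5), rep(2, 5), x = rep(0, 5))
  expect_true(is.na(st$iic) || st$iic == 0)
  expect_true(is.na(st$q2))
  expect_equal(st$n, 5)
  # prediction affine in the descriptor, as in the one-descriptor model
  x2 <- c(1, 2, 3, 4.5)
  obs2 <- c(1.2, 1.8, 3.3, 4.1)
  st2 <- fit_statistics(obs2, 0.9 * x2 + 0.1, x = x2)
  expect_true(all(is.finite(unlist(st2))))
  expect_lte(st2$q2, st2$r2)
})
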