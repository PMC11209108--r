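test_that("target function follows the stated arithmetic", {
  expect_equal(target_function(0.5, 0.5, 0, 0), 1.0)
  expect_equal(target_function(0.6, 0.4, 0.5, 0.5), 1.28)
  expect_equal(target_function(0, 0, 0, 0), 0)
  set.seed(8)
  for (rep in 1:20) {
    v <- runif(4, -1, 1)
    expect_equal(target_function(v[1], v[2], v[3], v[4]),
                 v[1] + v[2] - abs(v[1] - v[2]) * 0.1 + (v[3] + v[4]) * 0.3)
  }
})

test_that("optimizer configuration is validated", {
  expect_error(optimizer_config(epochs_N = 0), class = "coral_invalid_parameter")
  expect_error(optimizer_config(step_size = 0), class = "coral_invalid_parameter")
})

test_that("accepted-move TF is non-decreasing within a probe and runs are reproducible", {
  rec <- toy_records(n = 24, seed = 17)
  rec <- assign_split(rec, seed = 2)
  reg <- build_registry(rec$smiles[rec$subset == "active_training"],
                        threshold_T = 1)
  cfg <- optimizer_config(threshold_T = 1, epochs_N = 4, seed = 3, n_probes = 2)
  opt1 <- optimize_weights(rec, reg, cfg)
  opt2 <- optimize_weights(rec, reg, cfg)
  expect_identical(opt1$weight_table$weights, opt2$weight_table$weights)
  for (p in unique(opt1$trace$probe)) {
    tf_seq <- opt1$trace$tf[opt1$trace$probe == p & opt1$trace$event == "accept"]
    if (length(tf_seq) > 1) expect_true(all(diff(tf_seq) >= 0))
  }
  # trace carries one epoch_end row per epoch per probe
  expect_equal(sum(opt1$trace$event == "epoch_end"), 4L * 2L)
})

test_that("inactive attributes keep weight exactly 0 through optimization", {
  rec <- toy_records(n = 24, seed = 23)
  rec <- assign_split(rec, seed = 5)
  reg <- build_registry(rec$smiles[rec$subset == "active_training"],
                        threshold_T = 4)
  expect_true(any(!reg$table$active))  # fixture guarantees blocked attributes
  cfg <- optimizer_config(threshold_T = 4, epochs_N = 5, seed = 1)
  opt <- optimize_weights(rec, reg, cfg)
  w <- opt$weight_table$weights
  inactive <- reg$table$key[!reg$table$active]
  expect_true(all(w[inactive] == 0))
  expect_true(all(is.finite(w)))
})

test_that("hill climbing reaches the grid-search optimum on a frozen toy problem", {
  # C/O chains only; T = 3 on the 4 active-training compounds leaves four
  # active attributes (C, O, C|C, C|O)
  rec <- data.frame(
    id = as.character(1:16),
    smiles = c("CCCO", "COOO", "CCOO", "CCCC",   # active training
               "CO", "CC", "COO", "CCC",         # passive training
               "CCO", "OO", "OCCC", "OCO",       # calibration
               "C", "O", "CCCOO", "OC"),         # validation
    endpoint_log = NA_real_,
    subset = rep(c("active_training", "passive_training", "calibration",
                   "validation"), each = 4),
    stringsAsFactors = FALSE
  )
  w_true <- c(C = 0.8, O = -0.4)
  dcw_true <- vapply(rec$smiles, function(s) {
    toks <- oracle_tokens(s)
    sum(w_true[toks[toks %in% c("C", "O")]])
  }, numeric(1))
  rec$endpoint_log <- 1 + 2 * dcw_true
  reg <- build_registry(rec$smiles[rec$subset == "active_training"],
                        threshold_T = 3)
  active <- reg$table$key[reg$table$active]
  expect_setequal(active, c("C", "O", "C|C", "C|O"))

  cfg <- optimizer_config(threshold_T = 3, epochs_N = 30, seed = 7,
                          step_size = 0.4, n_probes = 4)
  opt <- optimize_weights(rec, reg, cfg)

  # exhaustive lattice oracle over the active-weight box
  y <- rec$endpoint_log
  at <- rec$subset == "active_training"; pt <- rec$subset == "passive_training"
  cal <- rec$subset == "calibration"
  ms <- lapply(rec$smiles, function(s) extract_attributes(tokenize_smiles(s)))
  M <- t(vapply(ms, function(m) {
    vapply(active, function(k) if (k %in% names(m)) as.numeric(m[[k]]) else 0,
           numeric(1))
  }, numeric(length(active))))
  tf_of <- function(w) {
    dcw <- as.vector(M %*% w)
    r_at <- suppressWarnings(cor(dcw[at], y[at]))
    r_pt <- suppressWarnings(cor(dcw[pt], y[pt]))
    if (is.na(r_at)) r_at <- 0
    if (is.na(r_pt)) r_pt <- 0
    line <- coralcw:::ols_line(dcw[cal], y[cal])
    pc <- line[1] + line[2] * dcw[cal]
    i <- tryCatch(suppressWarnings(iic(y[cal], pc)), error = function(e) 0)
    ci <- tryCatch(cii(y[cal], pc), error = function(e) 0)
    target_function(r_at, r_pt, i, ci)
  }
  grid <- seq(-2, 4, by = 1)
  best_grid <- -Inf
  for (w1 in grid) for (w2 in grid) for (w3 in grid) for (w4 in grid) {
    tf <- tf_of(setNames(c(w1, w2, w3, w4), active))
    if (tf > best_grid) best_grid <- tf
  }
  expect_gte(opt$tf_best, best_grid - 0.05)
})

test_that("run_split produces the full per-subset report", {
  rec <- toy_records(n = 28, seed = 3)
  cfg <- optimizer_config(threshold_T = 2, epochs_N = 4)
  run <- run_split(rec, split_id = 1, seed = 6, config = cfg,
                   endpoint_name = "logEC50")
  expect_s3_class(run$model, "coral_model")
  expect_equal(run$stats$subset,
               c("active_training", "passive_training", "calibration",
                 "validation"))
  expect_equal(names(run$stats),
               c("subset", "n", "r2", "iic", "cii", "q2", "rmse", "mae", "f"))
  expect_equal(sum(run$stats$n), 28)
  # training predictions are c0 + c1 * stored DCW
  expect_equal(run$records$endpoint_log_pred,
               run$model$c0 + run$model$c1 * run$records$dcw)
})

test_that("degenerate endpoints are handled without hard failure", {
  rec <- toy_records(n = 16, seed = 5)
  rec$endpoint_log <- 1  # constant endpoint everywhere
  cfg <- optimizer_config(threshold_T = 1, epochs_N = 2)
  run <- suppressWarnings(
    run_split(rec, split_id = 1, seed = 2, config = cfg)
  )
  expect_true(all(run$stats$n > 0))
})
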