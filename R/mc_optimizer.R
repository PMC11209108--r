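# Monte Carlo optimization of the correlation weights.
#
# The weights of all active attributes are adjusted by coordinate-wise
# stochastic hill climbing to maximize the target function
#
#   TF = r_AT + r_PT - |r_AT - r_PT| * 0.1 + (IIC_C + CII_C) * 0.3
#
# where r_AT and r_PT are the Pearson correlations of DCW with the log
# endpoint on the active and passive training sets, and IIC_C / CII_C are
# computed on the calibration set from the predictions of the line fitted
# on the active training set. Steering part of the objective toward the
# calibration set ("statistical forcing") trades training-set fit for
# generalization.

#' Optimizer configuration
#'
#' @param threshold_T activity threshold for attributes (default 5: an
#'   attribute must occur in at least five active-training compounds to be
#'   optimizable).
#' @param epochs_N number of Monte Carlo epochs (full sweeps over the
#'   active attributes); default 15.
#' @param seed integer seed controlling initialization and move order.
#' @param step_size maximum move magnitude per attribute visit; the actual
#'   step is `step_size * U(0, 1]`. Default 0.05.
#' @param init_range range for the uniform weight initialization; a nonzero
#'   start keeps the initial DCW from being degenerate. Default `c(1, 3)`.
#' @param n_probes number of independent Monte Carlo probes (restarts with
#'   fresh initialization); the probe with the best target function wins.
#'   Default 1.
#' @param extend_steps logical; after an accepted move, keep doubling the
#'   step along the improving direction (at most 5 doublings). `TRUE`
#'   (default) converges much faster; `FALSE` reproduces the classic slow
#'   one-step-per-visit ascent.
#' @param fractions subset fractions handed to [assign_split()].
#' @param fit_set which subset defines the final (C0, C1) regression:
#'   `"active_training"` (default) or `"training_union"` (active + passive).
#' @param two_char_elements passed to the tokenizer.
#' @param protest_threshold passed to [cii()].
#' @return a list of class `optimizer_config`.
#' @export
optimizer_config <- function(threshold_T = 5L, epochs_N = 15L, seed = 1L,
                             step_size = 0.05, init_range = c(1, 3),
                             n_probes = 1L, extend_steps = TRUE,
                             fractions = rep(0.25, 4),
                             fit_set = c("active_training", "training_union"),
                             two_char_elements = c("Cl", "Br"),
                             protest_threshold = 0) {
  if (epochs_N < 1L) {
    coral_stop("epochs_N must be at least 1", "coral_invalid_parameter")
  }
  if (step_size <= 0) {
    coral_stop("step_size must be positive", "coral_invalid_parameter")
  }
  structure(
    list(threshold_T = as.integer(threshold_T), epochs_N = as.integer(epochs_N),
         seed = as.integer(seed), step_size = step_size,
         init_range = init_range, n_probes = as.integer(n_probes),
         extend_steps = isTRUE(extend_steps), fractions = fractions,
         fit_set = match.arg(fit_set), two_char_elements = two_char_elements,
         protest_threshold = protest_threshold),
    class = "optimizer_config"
  )
}

#' The Monte Carlo target function
#'
#' `TF = r_at + r_pt - |r_at - r_pt| * 0.1 + (iic_c + cii_c) * 0.3`.
#'
#' @param r_at,r_pt Pearson correlations of DCW vs log endpoint on the
#'   active and passive training sets.
#' @param iic_c,cii_c IIC and CII on the calibration set.
#' @return the TF value.
#' @export
target_function <- function(r_at, r_pt, iic_c, cii_c) {
  r_at + r_pt - abs(r_at - r_pt) * 0.1 + (iic_c + cii_c) * 0.3
}

# Compound-by-attribute count matrix over the given keys; attributes of a
# compound outside `keys` simply do not appear (weight 0 regardless).
attribute_count_matrix <- function(multisets, keys) {
  m <- matrix(0, nrow = length(multisets), ncol = length(keys),
              dimnames = list(NULL, keys))
  for (i in seq_along(multisets)) {
    ms <- multisets[[i]]
    hit <- names(ms) %in% keys
    if (any(hit)) m[i, names(ms)[hit]] <- ms[hit]
  }
  m
}

safe_cor <- function(x, y) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Optimize the correlation weights for one labeled dataset
#'
#' Runs coordinate-wise Monte Carlo ascent: per epoch the active attributes
#' are visited in seeded random order; for each, the weight is tentatively
#' moved by +delta and -delta (delta fresh-drawn per visit) and the variant
#' with the highest target function is kept if it strictly improves, with a
#' capped greedy step extension along the improving direction. Within a
#' probe the accepted-move TF sequence is non-decreasing, so the final
#' state is the probe's best; with `n_probes > 1` independent restarts the
#' probe with the best final TF is returned. DCW values are updated
#' incrementally per perturbed attribute.
#'
#' @param records data.frame with columns `smiles`, `endpoint_log`, and a
#'   filled-in `subset` column (all four subsets populated).
#' @param registry an [build_registry()] result built from the active
#'   training set.
#' @param config an [optimizer_config()].
#' @return list: `weight_table` (a `cw_table` of the best state), `trace`
#'   (data.frame with one row per accepted move and per epoch end: probe,
#'   epoch, attribute, r_at, r_pt, iic_c, cii_c, tf, event), `tf_best`, and
#'   `final_weights` (active-attribute weights of the winning probe).
#' @export
optimize_weights <- function(records, registry, config = optimizer_config()) {
  for (s in SUBSET_LEVELS) {
    if (!any(records$subset == s)) {
      coral_stop(sprintf("subset '%s' is empty", s), "coral_split_error")
    }
  }
  active_keys <- registry$table$key[registry$table$active]
  if (length(active_keys) == 0L) {
    coral_stop("no active attributes at this threshold", "coral_optimization_error")
  }
  multisets <- lapply(records$smiles, function(s) {
    extract_attributes(tokenize_smiles(s, registry$two_char_elements))
  })
  M <- attribute_count_matrix(multisets, active_keys)
  y <- records$endpoint_log
  at <- which(records$subset == "active_training")
  pt <- which(records$subset == "passive_training")
  cal <- which(records$subset == "calibration")

  tf_parts <- function(dcw) {
    r_at <- safe_cor(dcw[at], y[at])
    r_pt <- safe_cor(dcw[pt], y[pt])
    # IIC/CII are judged on the calibration set's own fitted line: tying
    # them to the training line's slope couples them to its sign, which
    # creates a discontinuity that can pin the ascent at r_at = 0
    line <- ols_line(dcw[cal], y[cal])
    pred_cal <- line[1] + line[2] * dcw[cal]
    iic_c <- tryCatch(suppressWarnings(iic(y[cal], pred_cal)),
                      error = function(e) 0)
    cii_c <- tryCatch(
      cii(y[cal], pred_cal, protest_threshold = config$protest_threshold),
      error = function(e) 0
    )
    c(r_at = r_at, r_pt = r_pt, iic_c = unname(iic_c), cii_c = unname(cii_c),
      tf = target_function(r_at, r_pt, iic_c, cii_c))
  }

  k <- length(active_keys)
  trace <- vector("list", 0)
  res <- with_seed(config$seed, {
    best <- NULL
    for (probe in seq_len(config$n_probes)) {
    w <- stats::runif(k, config$init_range[1], config$init_range[2])
    names(w) <- active_keys
    dcw <- as.vector(M %*% w)
    cur <- tf_parts(dcw)
    if (!is.finite(cur["tf"])) {
      coral_stop("target function non-finite at initialization",
                 "coral_numerical_error")
    }
    trace[[length(trace) + 1L]] <- c(list(probe = probe, epoch = 0L,
                                          attribute = NA_character_,
                                          event = "init"), as.list(cur))
    for (epoch in seq_len(config$epochs_N)) {
      for (j in sample.int(k)) {
        delta <- config$step_size * stats::runif(1)
        col <- M[, j]
        up <- tf_parts(dcw + delta * col)
        dn <- tf_parts(dcw - delta * col)
        cand <- if (up["tf"] >= dn["tf"]) list(sgn = 1, parts = up) else list(sgn = -1, parts = dn)
        if (!is.finite(cand$parts["tf"])) {
          coral_stop(
            sprintf("target function non-finite while perturbing '%s'",
                    active_keys[j]),
            "coral_numerical_error"
          )
        }
        if (cand$parts["tf"] > cur["tf"]) {  # ties reject the move
          # greedy extension: keep doubling the step along the improving
          # direction while TF keeps strictly increasing
          move <- cand$sgn * delta
          parts <- cand$parts
          if (config$extend_steps) {
            ext <- delta
            for (dbl in seq_len(5L)) {  # capped so one coordinate cannot run away
              ext2 <- ext * 2
              trial <- tf_parts(dcw + (cand$sgn * ext2) * col)
              if (!is.finite(trial["tf"]) || trial["tf"] <= parts["tf"]) break
              ext <- ext2
              move <- cand$sgn * ext
              parts <- trial
            }
          }
          w[j] <- w[j] + move
          dcw <- dcw + move * col
          cur <- parts
          trace[[length(trace) + 1L]] <- c(
            list(probe = probe, epoch = epoch, attribute = active_keys[j],
                 event = "accept"),
            as.list(parts)
          )
        }
      }
      trace[[length(trace) + 1L]] <- c(
        list(probe = probe, epoch = epoch, attribute = NA_character_,
             event = "epoch_end"),
        as.list(cur)
      )
    }
    if (is.null(best) || cur["tf"] > best$cur["tf"]) {
      best <- list(w = w, cur = cur)
    }
    }
    best
  })

  inactive_keys <- registry$table$key[!registry$table$active]
  weights <- c(res$w, stats::setNames(rep(0, length(inactive_keys)), inactive_keys))
  trace_df <- do.call(rbind, lapply(trace, function(row) {
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
  list(
    weight_table = cw_table(weights, registry, epochs_N = config$epochs_N),
    trace = trace_df,
    tf_best = unname(res$cur["tf"]),
    tf_breakdown = as.list(res$cur),
    final_weights = res$w
  )
}

#' Run the full pipeline for one data split
#'
#' Assigns subsets, builds the attribute registry from the active training
#' set, optimizes the correlation weights, fits the endpoint regression,
#' and evaluates the statistics panel on all four subsets.
#'
#' @param records compound records (see [read_endpoint_table()]); any
#'   existing `subset` column is overwritten.
#' @param split_id integer id of this split.
#' @param seed seed for both the subset assignment and the optimizer.
#' @param config an [optimizer_config()] (its own `seed` field is ignored
#'   in favor of `seed`).
#' @param endpoint_name label stored in the model.
#' @return list: `model` (a `coral_model`), `stats` (data.frame with one
#'   row per subset: subset, n, r2, iic, cii, q2, rmse, mae, f), `trace`,
#'   `records` (with subset, dcw, and predicted columns).
#' @export
run_split <- function(records, split_id = 1L, seed = 1L,
                      config = optimizer_config(),
                      endpoint_name = "endpoint") {
  records <- assign_split(records, seed = seed, fractions = config$fractions)
  at_smiles <- records$smiles[records$subset == "active_training"]
  registry <- build_registry(at_smiles, threshold_T = config$threshold_T,
                             two_char_elements = config$two_char_elements)
  config$seed <- as.integer(seed)
  opt <- optimize_weights(records, registry, config)

  pred_tab <- predict(
    coral_model(0, 1, opt$weight_table, registry, split_id = split_id,
                endpoint_name = endpoint_name, seed = seed),
    records$smiles
  )
  records$dcw <- pred_tab$dcw
  records$unknown_attribute_count <- pred_tab$unknown_attribute_count

  fit_rows <- if (config$fit_set == "training_union") {
    records$subset %in% c("active_training", "passive_training")
  } else {
    records$subset == "active_training"
  }
  reg_fit <- fit_endpoint_regression(records$dcw[fit_rows],
                                     records$endpoint_log[fit_rows])
  records$endpoint_log_pred <- reg_fit$c0 + reg_fit$c1 * records$dcw

  model <- coral_model(
    c0 = reg_fit$c0, c1 = reg_fit$c1, weight_table = opt$weight_table,
    registry = registry, split_id = split_id, endpoint_name = endpoint_name,
    seed = seed, dcw_range = range(records$dcw[fit_rows]),
    se_c0 = reg_fit$se_c0, se_c1 = reg_fit$se_c1
  )

  stats_rows <- lapply(SUBSET_LEVELS, function(s) {
    rows <- records$subset == s
    cbind(subset = s,
          fit_statistics(records$endpoint_log[rows],
                         records$endpoint_log_pred[rows],
                         x = records$dcw[rows]))
  })
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL

  list(model = model, stats = stats, trace = opt$trace, records = records,
       tf_best = opt$tf_best, tf_breakdown = opt$tf_breakdown)
}
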