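# Experiment orchestration: the repeated-split protocol for one endpoint,
# with self-describing on-disk outputs. This is the function the
# command-line wrapper (inst/cli/coral.R) drives.

#' Run the full repeated-split modeling experiment
#'
#' For each of `n_splits` splits (seed = `master_seed + split_id`): assign
#' the four subsets, build the registry on the active training set,
#' optimize the correlation weights, fit the endpoint line, and write a
#' model artifact, a per-subset statistics table, an applicability-domain
#' report, and the target-function trace. A cross-split summary and the
#' fully serialized run configuration (with a content hash) round out the
#' output directory.
#'
#' @param records compound records, or a file path readable by
#'   [read_endpoint_table()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and just returns the results.
#' @param n_splits number of repeated splits (default 3).
#' @param master_seed master seed; split `i` uses `master_seed + i`.
#' @param config an [optimizer_config()].
#' @param endpoint_name label for reports.
#' @param ad_multiplier applicability-domain threshold multiplier.
#' @param column_map passed to [read_endpoint_table()] when `records` is a
#'   path.
#' @return (invisibly) list of per-split results (see [run_split()], plus
#'   `domain`), with the summary data.frame in `$summary`.
#' @export
run_experiment <- function(records, out_dir = NULL, n_splits = 3L,
                           master_seed = 1L, config = optimizer_config(),
                           endpoint_name = "endpoint", ad_multiplier = 2,
                           column_map = list(id = "id", smiles = "smiles",
                                             endpoint = "endpoint")) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_endpoint_table(records, column_map = column_map)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  cfg_json <- jsonlite::toJSON(
    list(
      endpoint_name = endpoint_name, n_splits = n_splits,
      master_seed = master_seed, ad_multiplier = ad_multiplier,
      threshold_T = config$threshold_T, epochs_N = config$epochs_N,
      step_size = config$step_size, init_range = config$init_range,
      fractions = config$fractions, fit_set = config$fit_set,
      two_char_elements = config$two_char_elements,
      protest_threshold = config$protest_threshold,
      n_records = nrow(records)
    ),
    auto_unbox = TRUE, digits = NA
  )
  cfg_hash <- fnv1a32(as.character(cfg_json))
  version <- as.character(utils::packageVersion("coralcw"))

  results <- vector("list", n_splits)
  for (i in seq_len(n_splits)) {
    seed_i <- master_seed + i
    run <- run_split(records, split_id = i, seed = seed_i, config = config,
                     endpoint_name = endpoint_name)
    run$domain <- domain_report(run$model, run$records,
                                multiplier = ad_multiplier)
    if (!is.null(out_dir)) {
      stamp <- c(
        sprintf("# coralcw %s | config %s | split %d | seed %d",
                version, cfg_hash, i, seed_i)
      )
      write_coral_model(run$model, file.path(out_dir, sprintf("model_split%d.txt", i)))
      stats_path <- file.path(out_dir, sprintf("stats_split%d.csv", i))
      writeLines(stamp, stats_path)
      suppressWarnings(utils::write.table(
        run$stats, stats_path, sep = ",", row.names = FALSE, append = TRUE,
        quote = FALSE
      ))
      ad_path <- file.path(out_dir, sprintf("ad_split%d.csv", i))
      writeLines(stamp, ad_path)
      suppressWarnings(utils::write.table(
        run$domain, ad_path, sep = ",", row.names = FALSE, append = TRUE,
        quote = FALSE
      ))
      trace_path <- file.path(out_dir, sprintf("tf_trace_split%d.csv", i))
      writeLines(stamp, trace_path)
      suppressWarnings(utils::write.table(
        run$trace, trace_path, sep = ",", row.names = FALSE, append = TRUE,
        quote = FALSE
      ))
    }
    results[[i]] <- run
  }

  summary_rows <- lapply(seq_len(n_splits), function(i) {
    st <- results[[i]]$stats
    cbind(split = i, seed = master_seed + i, st)
  })
  summary_df <- do.call(rbind, summary_rows)
  results$summary <- summary_df

  if (!is.null(out_dir)) {
    writeLines(as.character(cfg_json), file.path(out_dir, "config.json"))
    sum_path <- file.path(out_dir, "summary.csv")
    writeLines(sprintf("# coralcw %s | config %s", version, cfg_hash), sum_path)
    suppressWarnings(utils::write.table(
      summary_df, sum_path, sep = ",", row.names = FALSE, append = TRUE,
      quote = FALSE
    ))
  }
  invisible(results)
}

#' Pretty-print a statistics table in the standard report layout
#'
#' @param stats a statistics data.frame from [run_split()] or the summary
#'   from [run_experiment()].
#' @return the formatted character lines, invisibly (also printed).
#' @export
format_stats_table <- function(stats) {
  df <- stats
  num_cols <- intersect(c("r2", "iic", "cii", "q2", "rmse", "mae"), names(df))
  for (cl in num_cols) df[[cl]] <- sprintf("%.4f", df[[cl]])
  if ("f" %in% names(df)) df$f <- ifelse(is.na(stats$f), "-", sprintf("%.0f", stats$f))
  for (cl in names(df)) df[[cl]][df[[cl]] == "NA"] <- "-"
  lines <- utils::capture.output(print(df, row.names = FALSE))
  cat(lines, sep = "\n")
  invisible(lines)
}
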