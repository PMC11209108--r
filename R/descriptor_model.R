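# The optimal descriptor DCW(T, N) and the one-descriptor endpoint model
#   endpoint_log = C0 + C1 * DCW(T, N),
# where DCW is the sum of correlation weights over a molecule's SMILES
# attributes (single atoms and adjacent pairs).

#' Create a correlation-weight table
#'
#' Wraps a named weight vector together with the optimization parameters.
#' Inactive attributes always carry weight exactly 0 and are never perturbed
#' by the optimizer; attributes never seen by the registry contribute 0 to
#' DCW and are counted as unknown for the applicability report.
#'
#' @param weights named numeric vector, attribute key -> weight.
#' @param registry the [build_registry()] result the weights refer to.
#' @param epochs_N number of Monte Carlo epochs the table was trained for.
#' @return object of class `cw_table`.
#' @export
cw_table <- function(weights, registry, epochs_N = NA_integer_) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(!is.finite(weights))) {
    coral_stop("weights must be finite", "coral_invalid_parameter")
  }
  inactive <- registry$table$key[!registry$table$active]
  bad <- intersect(names(weights)[weights != 0], inactive)
  if (length(bad) > 0L) {
    coral_stop(
      sprintf("inactive attribute(s) carry nonzero weight: %s",
              paste(utils::head(bad, 3), collapse = ", ")),
      "coral_invalid_parameter"
    )
  }
  structure(
    list(weights = weights, threshold_T = registry$threshold_T,
         epochs_N = as.integer(epochs_N)),
    class = "cw_table"
  )
}

#' Compute DCW for one attribute multiset
#'
#' @param attribute_multiset named integer vector (key -> multiplicity), as
#'   returned by [extract_attributes()].
#' @param table a `cw_table` (or plain named numeric vector of weights).
#' @return list with `dcw` (the weighted sum) and `unknown` (number of
#'   attribute occurrences absent from the weight table; they contribute 0).
#' @export
compute_dcw <- function(attribute_multiset, table) {
  w <- if (inherits(table, "cw_table")) table$weights else table
  keys <- names(attribute_multiset)
  hit <- keys %in% names(w)
  dcw <- if (any(hit)) {
    sum(w[keys[hit]] * attribute_multiset[hit])
  } else 0
  list(dcw = unname(dcw), unknown = sum(attribute_multiset[!hit]))
}

#' Ordinary-least-squares fit of the endpoint regression
#'
#' Fits `endpoint_log = C0 + C1 * DCW` and reports coefficient standard
#' errors (printed as the +/- values in model equations).
#'
#' @param x DCW values (n >= 3, non-constant).
#' @param y log endpoint values.
#' @return list: `c0`, `c1`, `se_c0`, `se_c1`.
#' @export
fit_endpoint_regression <- function(x, y) {
  check_paired(x, y, min_n = 3L)
  if (stats::sd(x) == 0) {
    coral_stop("descriptor has zero variance; cannot fit the regression",
               "coral_degenerate_descriptor")
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(
    c0 = unname(cf[1, 1]), c1 = unname(cf[2, 1]),
    se_c0 = unname(cf[1, 2]), se_c1 = unname(cf[2, 2])
  )
}

# Fast closed-form OLS used inside the optimizer's inner loop; a unit test
# pins it against fit_endpoint_regression().
ols_line <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) return(c(c0 = yb, c1 = 0))
  c1 <- sum((x - xb) * (y - yb)) / sxx
  c(c0 = yb - c1 * xb, c1 = c1)
}

#' Assemble a fitted model object
#'
#' @param c0,c1 regression coefficients (with standard errors `se_c0`,
#'   `se_c1` if known).
#' @param weight_table a `cw_table`.
#' @param registry the attribute registry the model was trained with.
#' @param split_id integer id of the data split.
#' @param endpoint_name label such as `"logNOEC"`.
#' @param seed seed the training run used.
#' @param dcw_range numeric length-2, range of training-set DCW values.
#' @param se_c0,se_c1 coefficient standard errors.
#' @return object of class `coral_model`.
#' @export
coral_model <- function(c0, c1, weight_table, registry, split_id = 1L,
                        endpoint_name = "endpoint", seed = NA_integer_,
                        dcw_range = c(NA_real_, NA_real_),
                        se_c0 = NA_real_, se_c1 = NA_real_) {
  stopifnot(is.finite(c0), is.finite(c1), inherits(weight_table, "cw_table"))
  structure(
    list(
      c0 = c0, c1 = c1, se_c0 = se_c0, se_c1 = se_c1,
      weight_table = weight_table, registry = registry,
      split_id = as.integer(split_id), endpoint_name = endpoint_name,
      seed = as.integer(seed), dcw_range = dcw_range
    ),
    class = "coral_model"
  )
}

#' @export
print.coral_model <- function(x, ...) {
  cat(sprintf(
    "<coral_model> %s = %.4f (+/-%.4f) + %.4f (+/-%.4f) * DCW(%d; %d)  [split %d]\n",
    x$endpoint_name, x$c0, x$se_c0, x$c1, x$se_c1,
    x$weight_table$threshold_T, x$weight_table$epochs_N, x$split_id
  ))
  invisible(x)
}

#' Predict the log endpoint for SMILES strings
#'
#' @param object a `coral_model`.
#' @param smiles character vector of SMILES strings.
#' @param ... unused.
#' @return data.frame: `smiles`, `dcw`, `endpoint_log_pred`,
#'   `unknown_attribute_count` (occurrences of attributes the model has
#'   never seen; they contribute 0 to DCW and feed the applicability
#'   report).
#' @export
predict.coral_model <- function(object, smiles, ...) {
  rows <- lapply(smiles, function(s) {
    ms <- extract_attributes(
      tokenize_smiles(s, object$registry$two_char_elements)
    )
    d <- compute_dcw(ms, object$weight_table)
    data.frame(smiles = s, dcw = d$dcw,
               endpoint_log_pred = object$c0 + object$c1 * d$dcw,
               unknown_attribute_count = d$unknown,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a model artifact as structured text
#'
#' Key-value header plus an embedded tab-separated weight table. Numbers are
#' written with 17 significant digits so that [read_coral_model()] is a
#' bit-exact round trip.
#'
#' @param model a `coral_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coral_model <- function(model, path) {
  reg <- model$registry$table
  w <- model$weight_table$weights
  weight_col <- ifelse(reg$key %in% names(w), w[reg$key], 0)
  header <- c(
    "# coralcw model artifact v1",
    paste0("endpoint_name: ", model$endpoint_name),
    paste0("split_id: ", model$split_id),
    paste0("seed: ", model$seed),
    paste0("threshold_T: ", model$weight_table$threshold_T),
    paste0("epochs_N: ", model$weight_table$epochs_N),
    paste0("two_char_elements: ",
           paste(model$registry$two_char_elements, collapse = ",")),
    paste0("c0: ", fmt_num(model$c0)),
    paste0("c1: ", fmt_num(model$c1)),
    paste0("se_c0: ", fmt_num(model$se_c0)),
    paste0("se_c1: ", fmt_num(model$se_c1)),
    paste0("dcw_min: ", fmt_num(model$dcw_range[1])),
    paste0("dcw_max: ", fmt_num(model$dcw_range[2])),
    "[weights]",
    "key\tarity\tcount_train\tactive\tweight"
  )
  body <- sprintf("%s\t%s\t%d\t%d\t%s", reg$key, reg$arity, reg$count_train,
                  as.integer(reg$active), fmt_num(weight_col))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a model artifact written by [write_coral_model()]
#'
#' @param path artifact file path.
#' @return a `coral_model`.
#' @export
read_coral_model <- function(path) {
  lines <- readLines(path)
  sep <- match("[weights]", lines)
  if (is.na(sep)) {
    coral_stop("not a coralcw model artifact (no [weights] section)",
               "coral_io_error")
  }
  hdr <- lines[seq_len(sep - 1L)]
  hdr <- hdr[!startsWith(hdr, "#")]
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(p) paste(p[-1], collapse = ": "), character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  tab <- utils::read.table(
    text = lines[(sep + 1L):length(lines)], header = TRUE, sep = "\t",
    quote = "", comment.char = "", stringsAsFactors = FALSE
  )
  registry <- structure(
    list(
      table = data.frame(key = tab$key, arity = tab$arity,
                         count_train = as.integer(tab$count_train),
                         active = as.logical(tab$active),
                         stringsAsFactors = FALSE),
      threshold_T = as.integer(vals["threshold_T"]),
      two_char_elements = strsplit(vals[["two_char_elements"]], ",")[[1]]
    ),
    class = "attribute_registry"
  )
  weights <- stats::setNames(as.numeric(tab$weight), tab$key)
  wt <- cw_table(weights, registry, epochs_N = as.integer(vals["epochs_N"]))
  coral_model(
    c0 = as.numeric(vals["c0"]), c1 = as.numeric(vals["c1"]),
    weight_table = wt, registry = registry,
    split_id = as.integer(vals["split_id"]),
    endpoint_name = vals[["endpoint_name"]],
    seed = as.integer(vals["seed"]),
    dcw_range = c(as.numeric(vals["dcw_min"]), as.numeric(vals["dcw_max"])),
    se_c0 = as.numeric(vals["se_c0"]), se_c1 = as.numeric(vals["se_c1"])
  )
}
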