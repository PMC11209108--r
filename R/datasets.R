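# Endpoint tables and the four-subset protocol.
#
# A compound record table is a plain data.frame with one row per substance:
# id, smiles, endpoint_raw, endpoint_log (= log10 endpoint_raw), subset.
# Substances are assigned at random to active training / passive training /
# calibration / validation subsets; repeating the split with different seeds
# yields the repeated-split protocol under which one model is built per split.

SUBSET_LEVELS <- c("active_training", "passive_training", "calibration", "validation")

#' Read a compound/endpoint table from CSV or TSV
#'
#' Reads a delimited table with one row per substance, applies the log10
#' transform to the endpoint, and rejects rows with missing SMILES or
#' missing/non-positive endpoint values (concentrations must be positive for
#' the log scale). Rejections are reported via `message()` and kept in the
#' `rejected` attribute.
#'
#' @param path file path; comma- or tab-delimited with a header.
#' @param column_map named list mapping the roles `id`, `smiles`, `endpoint`
#'   to column names in the file.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` -> tab, otherwise comma).
#' @return data.frame with columns `id`, `smiles`, `endpoint_raw`,
#'   `endpoint_log`, `subset` (initially `"unassigned"`); attribute
#'   `rejected` holds the dropped rows with a `reason` column.
#' @export
read_endpoint_table <- function(path,
                                column_map = list(id = "id", smiles = "smiles",
                                                  endpoint = "endpoint"),
                                sep = NULL) {
  if (!file.exists(path)) {
    coral_stop(sprintf("data file not found: %s", path), "coral_io_error")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- unlist(column_map[c("id", "smiles", "endpoint")])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    coral_stop(
      sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
      "coral_schema_error"
    )
  }
  df <- data.frame(
    id = as.character(raw[[column_map$id]]),
    smiles = as.character(raw[[column_map$smiles]]),
    endpoint_raw = suppressWarnings(as.numeric(raw[[column_map$endpoint]])),
    stringsAsFactors = FALSE
  )
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$smiles) | !nzchar(trimws(df$smiles))] <- "empty SMILES"
  reason[is.na(df$endpoint_raw)] <- "missing or non-numeric endpoint"
  reason[!is.na(df$endpoint_raw) & df$endpoint_raw <= 0] <- "non-positive endpoint"
  rejected <- cbind(df[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  records <- df[is.na(reason), , drop = FALSE]
  if (nrow(records) == 0L) {
    coral_stop("no usable rows in the table", "coral_empty_dataset")
  }
  if (nrow(rejected) > 0L) {
    message(sprintf("read_endpoint_table: accepted %d rows, rejected %d (%s)",
                    nrow(records), nrow(rejected),
                    paste(unique(rejected$reason), collapse = "; ")))
  }
  dup <- duplicated(records$smiles)
  if (any(dup)) {
    message(sprintf("read_endpoint_table: %d duplicate SMILES kept as distinct records",
                    sum(dup)))
  }
  records$endpoint_log <- log_transform(records$endpoint_raw)
  records$subset <- "unassigned"
  rownames(records) <- NULL
  attr(records, "rejected") <- rejected
  records
}

#' Log10 transform for endpoint concentrations
#'
#' @param value positive numeric vector.
#' @return `log10(value)`.
#' @export
log_transform <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    coral_stop("endpoint values must be positive and finite for the log scale",
               "coral_domain_error")
  }
  log10(value)
}

#' Assign compounds to the four validation subsets
#'
#' Randomly permutes the records under `seed` and partitions them into
#' active training, passive training, calibration, and validation subsets
#' according to `fractions` (largest-remainder apportionment, so subset
#' sizes differ from the exact fractional counts by less than one compound).
#' Deterministic given (records, seed, fractions).
#'
#' @param records data.frame of compound records (any data.frame with one
#'   row per compound).
#' @param seed integer seed for the permutation.
#' @param fractions four non-negative numbers summing to 1, in subset order
#'   active training, passive training, calibration, validation.
#' @return `records` with a `subset` column filled in.
#' @export
assign_split <- function(records, seed, fractions = rep(0.25, 4)) {
  n <- nrow(records)
  if (n < 8L) {
    coral_stop("need at least 8 records to populate four subsets", "coral_split_error")
  }
  if (length(fractions) != 4L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    coral_stop("fractions must be four non-negative values summing to 1",
               "coral_split_error")
  }
  sizes <- apportion_sizes(n, fractions)
  if (any(sizes == 0L)) {
    coral_stop("a subset would be empty under these fractions", "coral_split_error")
  }
  perm <- with_seed(seed, sample.int(n))
  labels <- rep(SUBSET_LEVELS, times = sizes)
  records$subset <- labels[order(perm)]
  records
}

# Largest-remainder apportionment of n among the four subsets.
apportion_sizes <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  left <- n - sum(sizes)
  if (left > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1L
  }
  as.integer(sizes)
}

subset_rows <- function(records, which) {
  records[records$subset == which, , drop = FALSE]
}
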