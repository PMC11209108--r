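# Applicability domain from the distributional defect of SMILES attributes.
#
# An attribute that appears with very different frequency in the training
# and calibration sets is a structural feature the model has learned from an
# unbalanced sample; a compound built from many such attributes (or from
# attributes never seen at all) sits outside the region where predictions
# are trustworthy. The defect of attribute A is
#
#   defect(A) = |P_T(A) - P_C(A)| / (N_T(A) + N_C(A))
#
# with P_X the fraction of compounds in set X containing A and N_X the
# number of such compounds; 0 when A occurs in neither set. A compound's
# defect is the sum over its attribute multiset, and it is in-domain when
# its defect does not exceed `multiplier` times the mean defect of the
# training compounds.

#' Per-attribute distributional defects
#'
#' @param train_smiles SMILES of the (active) training set.
#' @param calib_smiles SMILES of the calibration set.
#' @param two_char_elements passed to the tokenizer.
#' @return data.frame: `key`, `n_train`, `n_calib`, `defect`.
#' @export
attribute_defect <- function(train_smiles, calib_smiles,
                             two_char_elements = c("Cl", "Br")) {
  presence <- function(smiles) {
    keys <- lapply(smiles, function(s) {
      names(extract_attributes(tokenize_smiles(s, two_char_elements)))
    })
    table(unlist(keys, use.names = FALSE))
  }
  nt <- presence(train_smiles)
  nc <- presence(calib_smiles)
  keys <- union(names(nt), names(nc))
  n_train <- ifelse(keys %in% names(nt), as.integer(nt[keys]), 0L)
  n_calib <- ifelse(keys %in% names(nc), as.integer(nc[keys]), 0L)
  p_train <- n_train / length(train_smiles)
  p_calib <- n_calib / length(calib_smiles)
  tot <- n_train + n_calib
  defect <- ifelse(tot == 0, 0, abs(p_train - p_calib) / tot)
  out <- data.frame(key = keys, n_train = n_train, n_calib = n_calib,
                    defect = defect, stringsAsFactors = FALSE)
  out[order(out$key), , drop = FALSE]
}

#' Applicability-domain report for a fitted model
#'
#' Sums the attribute defects over each compound's attribute multiset (with
#' multiplicity; attributes absent from both reference sets contribute 0
#' but are counted as unknown) and flags compounds whose total defect
#' exceeds `multiplier` times the mean defect of the training compounds.
#'
#' @param model a `coral_model`.
#' @param records data.frame with `id`, `smiles`, and `subset` columns; the
#'   `active_training` and `calibration` subsets define the defect table
#'   and the in-domain threshold.
#' @param new_smiles optional SMILES to assess instead of `records` itself
#'   (named, or ids are generated).
#' @param multiplier in-domain threshold as a multiple of the mean
#'   training-compound defect; default 2.
#' @return data.frame: `id`, `defect`, `unknown_attribute_count`,
#'   `in_domain`; the threshold is stored in attribute
#'   `defect_threshold`. A compound is in-domain when its defect is within
#'   the threshold *and* it contains no attribute unseen in both reference
#'   sets (`unknown_attribute_count == 0`).
#' @export
domain_report <- function(model, records, new_smiles = NULL, multiplier = 2) {
  two_char <- model$registry$two_char_elements
  defects <- attribute_defect(
    records$smiles[records$subset == "active_training"],
    records$smiles[records$subset == "calibration"],
    two_char_elements = two_char
  )
  dmap <- stats::setNames(defects$defect, defects$key)
  compound_defect <- function(smiles) {
    ms <- extract_attributes(tokenize_smiles(smiles, two_char))
    hit <- names(ms) %in% names(dmap)
    d <- if (any(hit)) sum(dmap[names(ms)[hit]] * ms[hit]) else 0
    c(defect = unname(d), unknown = sum(ms[!hit]))
  }
  train_defects <- vapply(
    records$smiles[records$subset == "active_training"],
    function(s) compound_defect(s)["defect"], numeric(1)
  )
  threshold <- multiplier * mean(train_defects)

  if (is.null(new_smiles)) {
    ids <- if ("id" %in% names(records)) records$id else as.character(seq_len(nrow(records)))
    targets <- records$smiles
  } else {
    ids <- if (!is.null(names(new_smiles))) names(new_smiles) else as.character(seq_along(new_smiles))
    targets <- unname(new_smiles)
  }
  vals <- t(vapply(targets, compound_defect, numeric(2)))
  out <- data.frame(
    id = ids, defect = vals[, "defect"],
    unknown_attribute_count = as.integer(vals[, "unknown"]),
    in_domain = vals[, "defect"] <= threshold & vals[, "unknown"] == 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "defect_threshold") <- threshold
  out
}
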