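# SMILES attributes: tokenization into "SMILES atoms" and adjacent-pair
# features, and the attribute registry with the activity threshold T.
#
# The descriptor machinery deliberately operates on the SMILES *text*, not on
# a perceived molecular graph: every undivided fragment of the string (an
# organic-subset atom, a two-character element such as Cl/Br, a full
# bracket-atom span, a bond symbol, a ring-closure digit, a branch
# parenthesis) is a token, and both tokens and adjacent token pairs become
# attributes that carry correlation weights.

PAIR_SEP <- "|"

#' Tokenize a SMILES string into SMILES atoms
#'
#' Splits a SMILES string into its undivided fragments: single symbols,
#' two-character elements (`Cl`, `Br` by default), and bracket-atom spans
#' (`[N+]`, `[nH]`, ...) kept whole. Stereo markers (`/`, `\`, `@`) are
#' stripped before tokenization because the models do not use chiral or
#' cis/trans information.
#'
#' @param smiles a single non-empty SMILES string.
#' @param two_char_elements character vector of two-character element symbols
#'   recognized outside brackets. Default `c("Cl", "Br")`; extend with e.g.
#'   `"Si"` if your chemistry needs it.
#' @return a data.frame with columns `text` (token) and `kind` (one of
#'   `atom_organic`, `atom_bracket`, `bond`, `ring_closure`, `branch`,
#'   `other`), one row per token in string order.
#' @examples
#' tokenize_smiles("ClCBr")$text      # "Cl" "C" "Br"
#' tokenize_smiles("C[N+](C)C")$text  # "C" "[N+]" "(" "C" ")" "C"
#' @export
tokenize_smiles <- function(smiles, two_char_elements = c("Cl", "Br")) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    coral_stop("`smiles` must be a single string", "coral_empty_input")
  }
  stripped <- strip_stereo(smiles)
  if (!nzchar(stripped)) {
    coral_stop("empty SMILES string", "coral_empty_input")
  }
  chars <- strsplit(stripped, "", fixed = TRUE)[[1]]
  n <- length(chars)
  texts <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "]") {
      coral_stop(
        sprintf("unbalanced ']' at position %d in '%s'", i, smiles),
        "coral_malformed_smiles"
      )
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") {
        if (chars[j] == "[") {
          coral_stop(
            sprintf("nested '[' at position %d in '%s'", j, smiles),
            "coral_malformed_smiles"
          )
        }
        j <- j + 1L
      }
      if (j > n) {
        coral_stop(
          sprintf("unbalanced '[' at position %d in '%s'", i, smiles),
          "coral_malformed_smiles"
        )
      }
      texts <- c(texts, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      # two-digit ring closure, e.g. %12
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)]))) {
        coral_stop(
          sprintf("'%%' not followed by two digits at position %d in '%s'", i, smiles),
          "coral_malformed_smiles"
        )
      }
      texts <- c(texts, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_char_elements) {
      texts <- c(texts, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      texts <- c(texts, ch)
      i <- i + 1L
    }
  }
  data.frame(
    text = texts,
    kind = vapply(texts, classify_token, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

# Remove stereo markers: bond direction slashes anywhere, tetrahedral '@'
# (which only occurs inside bracket atoms).
strip_stereo <- function(smiles) {
  gsub("[/\\\\@]", "", smiles)
}

classify_token <- function(text) {
  if (startsWith(text, "[")) return("atom_bracket")
  if (text %in% c("(", ")")) return("branch")
  if (grepl("^[0-9]$", text) || startsWith(text, "%")) return("ring_closure")
  if (text %in% c("-", "=", "#", "$", ":", "~", ".")) return("bond")
  if (grepl("^[A-Za-z][a-z]?$", text)) return("atom_organic")
  "other"
}

#' Extract single and pair attributes from a token sequence
#'
#' Emits one single-arity attribute per token and one pair-arity attribute
#' per adjacent token pair, in string order. Pair keys are order-normalized
#' (lexicographic), so a fragment and its reverse contribute the same key:
#' `key(a, b) == key(b, a)`.
#'
#' @param tokens data.frame from [tokenize_smiles()], or a character vector
#'   of token texts.
#' @return a named integer vector: attribute key -> multiplicity. Pair keys
#'   are the two token texts joined by `"|"`.
#' @export
extract_attributes <- function(tokens) {
  texts <- if (is.data.frame(tokens)) tokens$text else as.character(tokens)
  if (length(texts) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  keys <- texts
  if (length(texts) >= 2L) {
    a <- texts[-length(texts)]
    b <- texts[-1L]
    keys <- c(keys, paste(pmin(a, b), pmax(a, b), sep = PAIR_SEP))
  }
  tab <- table(keys)
  structure(as.integer(tab), names = names(tab))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = PAIR_SEP)

is_pair_key <- function(key) grepl(PAIR_SEP, key, fixed = TRUE)

#' Build the attribute registry from a reference compound set
#'
#' Extracts all attributes occurring in the reference set (normally the
#' active training set), counts for each attribute the number of reference
#' compounds containing it at least once, and marks attributes active when
#' that count reaches the threshold `T`. Inactive (rare) attributes stay in
#' the registry but their correlation weight is pinned at 0 and never
#' perturbed by the optimizer.
#'
#' @param smiles character vector of reference SMILES strings.
#' @param threshold_T positive integer activity threshold. `T = 5` means an
#'   attribute must occur in at least five reference compounds to be active.
#' @param two_char_elements passed to [tokenize_smiles()].
#' @return an object of class `attribute_registry`: a list with `table`
#'   (data.frame: key, arity, count_train, active), `threshold_T`, and the
#'   token configuration.
#' @export
build_registry <- function(smiles, threshold_T = 5L,
                           two_char_elements = c("Cl", "Br")) {
  if (length(smiles) == 0L) {
    coral_stop("reference set is empty", "coral_invalid_parameter")
  }
  threshold_T <- as.integer(threshold_T)
  if (is.na(threshold_T) || threshold_T < 1L) {
    coral_stop("threshold T must be a positive integer", "coral_invalid_parameter")
  }
  per_compound <- lapply(smiles, function(s) {
    names(extract_attributes(tokenize_smiles(s, two_char_elements)))
  })
  # presence count: number of compounds containing the key at least once
  all_keys <- unlist(per_compound, use.names = FALSE)
  counts <- table(all_keys)
  tab <- data.frame(
    key = names(counts),
    arity = ifelse(is_pair_key(names(counts)), "pair", "single"),
    count_train = as.integer(counts),
    stringsAsFactors = FALSE
  )
  tab$active <- tab$count_train >= threshold_T
  tab <- tab[order(tab$arity, tab$key), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(
      table = tab,
      threshold_T = threshold_T,
      two_char_elements = two_char_elements
    ),
    class = "attribute_registry"
  )
}

#' @export
print.attribute_registry <- function(x, ...) {
  cat(sprintf(
    "<attribute_registry> %d attributes (%d active at T = %d)\n",
    nrow(x$table), sum(x$table$active), x$threshold_T
  ))
  invisible(x)
}
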