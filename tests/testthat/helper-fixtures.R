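# Shared fixtures, all built in code.

# A tiny deterministic record table with known structure.
toy_records <- function(n = 12, seed = 42) {
  ds <- generate_dataset(synthetic_spec(n_compounds = n, seed = seed))
  ds$records
}

# Independent re-tokenization used by oracles: single pass over characters,
# intentionally written differently from tokenize_smiles().
oracle_tokens <- function(smiles) {
  s <- gsub("[/\\\\@]", "", smiles)
  out <- character(0)
  while (nchar(s) > 0) {
    if (substr(s, 1, 1) == "[") {
      len <- regexpr("]", s, fixed = TRUE)
      out <- c(out, substr(s, 1, len))
      s <- substr(s, len + 1, nchar(s))
    } else if (substr(s, 1, 2) %in% c("Cl", "Br")) {
      out <- c(out, substr(s, 1, 2))
      s <- substr(s, 3, nchar(s))
    } else {
      out <- c(out, substr(s, 1, 1))
      s <- substr(s, 2, nchar(s))
    }
  }
  out
}

# Brute-force DCW: explicit walk over tokens and adjacent pairs.
oracle_dcw <- function(smiles, weights) {
  toks <- oracle_tokens(smiles)
  total <- 0
  for (t in toks) {
    if (t %in% names(weights)) total <- total + weights[[t]]
  }
  if (length(toks) >= 2) {
    for (i in seq_len(length(toks) - 1)) {
      pk <- paste(sort(c(toks[i], toks[i + 1])), collapse = "|")
      if (pk %in% names(weights)) total <- total + weights[[pk]]
    }
  }
  total
}

# A small pool of random synthetic SMILES for property tests.
random_smiles_pool <- function(n = 50, seed = 99) {
  ds <- generate_dataset(synthetic_spec(
    n_compounds = n, seed = seed, branch_prob = 0.3, ring_prob = 0.4,
    bond_prob = 0.2
  ))
  ds$records$smiles
}
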