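test_that("tokenizer splits organic atoms, two-char elements, and bracket atoms", {
  expect_equal(tokenize_smiles("OCC")$text, c("O", "C", "C"))
  expect_equal(tokenize_smiles("ClCBr")$text, c("Cl", "C", "Br"))
  expect_equal(tokenize_smiles("C[N+](C)C")$text,
               c("C", "[N+]", "(", "C", ")", "C"))
  tk <- tokenize_smiles("C[N+](C)1%12=O")
  expect_equal(tk$kind,
               c("atom_organic", "atom_bracket", "branch", "atom_organic",
                 "branch", "ring_closure", "ring_closure", "bond",
                 "atom_organic"))
})

test_that("two-character element set is configurable", {
  expect_equal(tokenize_smiles("SiC", two_char_elements = c("Cl", "Br", "Si"))$text,
               c("Si", "C"))
  expect_equal(tokenize_smiles("SiC")$text, c("S", "i", "C"))
})

test_that("stereo markers are stripped before tokenization", {
  expect_equal(tokenize_smiles("F/C=C\\F")$text,
               c("F", "C", "=", "C", "F"))
  expect_equal(tokenize_smiles("N[C@@H](C)O")$text,
               c("N", "[CH]", "(", "C", ")", "O"))
})

test_that("malformed and empty SMILES are rejected with classed errors", {
  expect_error(tokenize_smiles(""), class = "coral_empty_input")
  expect_error(tokenize_smiles("C[NH2"), class = "coral_malformed_smiles")
  expect_error(tokenize_smiles("CN]C"), class = "coral_malformed_smiles")
  expect_error(tokenize_smiles("C[[N]]"), class = "coral_malformed_smiles")
})

test_that("token texts concatenate back to the stereo-stripped input", {
  for (s in random_smiles_pool(50)) {
    expect_identical(paste(tokenize_smiles(s)$text, collapse = ""), s)
  }
  expect_identical(
    paste(tokenize_smiles("F/C=C\\[C@H](Cl)Br")$text, collapse = ""),
    "FC=C[CH](Cl)Br"
  )
})

test_that("attribute extraction enumerates singles and normalized adjacent pairs", {
  ms <- extract_attributes(tokenize_smiles("OCC"))
  expect_equal(ms[["O"]], 1L)
  expect_equal(ms[["C"]], 2L)
  expect_equal(ms[["C|C"]], 1L)
  expect_equal(ms[["C|O"]], 1L)
  expect_equal(sum(ms), 5L)  # 3 singles + 2 pairs

  expect_equal(extract_attributes("C"), c(C = 1L))
  expect_length(extract_attributes(character(0)), 0L)

  # direction invariance of pair keys
  expect_identical(extract_attributes(c("C", "O")), extract_attributes(c("O", "C")))
})

test_that("pair-key multiset is invariant under token-order reversal", {
  for (s in random_smiles_pool(25)) {
    toks <- tokenize_smiles(s)$text
    fwd <- extract_attributes(toks)
    rev_ <- extract_attributes(rev(toks))
    pairs_only <- function(x) sort(x[grepl("|", names(x), fixed = TRUE)])
    expect_identical(pairs_only(fwd), pairs_only(rev_))
  }
})

test_that("registry counts compounds containing each attribute and applies T", {
  smiles <- c("CCCCC", "CO", "CN", "CCl", "CBr")  # 'C' in all 5
  reg <- build_registry(smiles, threshold_T = 5)
  tab <- reg$table
  expect_true(tab$active[tab$key == "C"])
  expect_equal(tab$count_train[tab$key == "C"], 5L)
  # 'O' appears in 1 compound only
  expect_false(tab$active[tab$key == "O"])

  # attribute in 4 of 5 compounds sits just under T = 5
  smiles2 <- c("CO", "CO", "CO", "CO", "CC")
  reg2 <- build_registry(smiles2, threshold_T = 5)
  expect_equal(reg2$table$count_train[reg2$table$key == "O"], 4L)
  expect_false(reg2$table$active[reg2$table$key == "O"])

  # degenerate threshold: everything observed is active
  reg3 <- build_registry(smiles2, threshold_T = 1)
  expect_true(all(reg3$table$active))

  expect_error(build_registry(smiles, threshold_T = 0),
               class = "coral_invalid_parameter")
  expect_error(build_registry(character(0)), class = "coral_invalid_parameter")
})

test_that("registry counts match a naive per-compound membership recount", {
  pool <- random_smiles_pool(20, seed = 7)
  reg <- build_registry(pool, threshold_T = 3)
  for (key in sample(reg$table$key, 15)) {
    naive <- sum(vapply(pool, function(s) {
      toks <- oracle_tokens(s)
      singles <- unique(toks)
      pairs <- if (length(toks) >= 2) {
        unique(vapply(seq_len(length(toks) - 1), function(i) {
          paste(sort(c(toks[i], toks[i + 1])), collapse = "|")
        }, character(1)))
      } else character(0)
      key %in% c(singles, pairs)
    }, logical(1)))
    expect_equal(reg$table$count_train[reg$table$key == key], naive)
  }
})
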