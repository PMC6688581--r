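test_that("toy complexes parse into typed chains", {
  toy <- make_toy_complex(toy_complex_spec(n_protein_residues = 3, n_rna_nt = 2,
                                           n_basepairs = 1, seed = 4), "mini")
  cs <- parse_complex(toy$pdb_text, "mini")
  expect_s3_class(cs, "complex_structure")
  expect_length(cs$chains, 2)
  expect_setequal(vapply(cs$chains, `[[`, "", "kind"), c("protein", "rna"))

  wat <- make_toy_complex(toy_complex_spec(include_waters = TRUE, seed = 2), "w1")
  csw <- parse_complex(wat$pdb_text, "w1")
  expect_equal(csw$chains[["W"]]$kind, "other")
})

test_that("parse errors name the problem", {
  expect_error(parse_complex("", "x"), "no ATOM records")
  expect_error(parse_complex("HEADER only\nEND", "x"), "no ATOM records")
  good <- make_toy_complex(toy_complex_spec(seed = 1), "g")$pdb_text
  lines <- strsplit(good, "\n")[[1]]
  lines[2] <- paste0(substr(lines[2], 1, 30), "   bad.coord", substr(lines[2], 43, nchar(lines[2])))
  expect_error(parse_complex(lines, "g"), "line 2")
})

test_that("chain typing follows the residue alphabet", {
  mk <- function(names) list(residues = data.frame(name = names, stringsAsFactors = FALSE))
  expect_equal(classify_chain(mk(c("ALA", "GLY", "LYS"))), "protein")
  expect_equal(classify_chain(mk(c("A", "U", "G"))), "rna")
  expect_equal(classify_chain(mk(c("HOH", "HOH"))), "other")
  # 80% threshold: 1 modified residue in 10 stays protein, 1 in 3 does not
  expect_equal(classify_chain(mk(c(rep("ALA", 9), "MSE"))), "protein")
  expect_equal(classify_chain(mk(c("ALA", "GLY", "MSE"))), "other")
  expect_error(classify_chain(mk(character())), "empty")
})

test_that("sequences extract with standard code mapping and X fallback", {
  toy <- make_toy_complex(toy_complex_spec(n_protein_residues = 31, n_rna_nt = 6,
                                           n_basepairs = 2, seed = 9), "s1")
  cs <- parse_complex(toy$pdb_text, "s1")
  seqs <- extract_sequences(cs)
  expect_equal(unname(seqs$protein), toy$protein_seq)
  expect_equal(unname(seqs$rna), toy$rna_seq)

  # splice a nonstandard residue name into the PDB text (resname cols 18-20)
  lines <- strsplit(toy$pdb_text, "\n")[[1]]
  lines[1] <- paste0(substr(lines[1], 1, 17), "MSE", substr(lines[1], 21, nchar(lines[1])))
  cs2 <- parse_complex(lines, "s2")
  expect_warning(seqs2 <- extract_sequences(cs2), "MSE")
  expect_equal(substr(unname(seqs2$protein), 1, 1), "X")
})

test_that("admission filters enforce the 30-residue / 2-nt thresholds", {
  ok <- make_toy_complex(toy_complex_spec(n_protein_residues = 35, n_rna_nt = 8,
                                          n_basepairs = 2, seed = 3), "ok")
  cs <- parse_complex(ok$pdb_text, "ok")
  expect_s3_class(validate_complex(cs), "complex_structure")

  # exactly 30 residues passes; 29 fails with reason no_protein
  b30 <- make_toy_complex(toy_complex_spec(n_protein_residues = 30, n_rna_nt = 4,
                                           n_basepairs = 1, seed = 5), "b30")
  expect_s3_class(validate_complex(parse_complex(b30$pdb_text, "b30")),
                  "complex_structure")
  b29 <- make_toy_complex(toy_complex_spec(n_protein_residues = 29, n_rna_nt = 4,
                                           n_basepairs = 1, seed = 5), "b29")
  err <- tryCatch(suppressWarnings(validate_complex(parse_complex(b29$pdb_text, "b29"))),
                  condition = function(c) c)
  expect_s3_class(err, "prbind_validation_error")
  expect_equal(err$reason, "no_protein")

  b1nt <- make_toy_complex(toy_complex_spec(n_protein_residues = 32, n_rna_nt = 1,
                                            n_basepairs = 0, seed = 6), "b1")
  err2 <- tryCatch(suppressWarnings(validate_complex(parse_complex(b1nt$pdb_text, "b1"))),
                   condition = function(c) c)
  expect_s3_class(err2, "prbind_validation_error")
  expect_equal(err2$reason, "no_rna")
})

test_that("round trip through PDB text preserves chains, counts and sequences", {
  for (seed in c(1, 17)) {
    spec <- toy_complex_spec(n_protein_residues = 33, n_rna_nt = 10,
                             n_basepairs = 3, seed = seed)
    toy <- make_toy_complex(spec, "rt")
    cs <- parse_complex(toy$pdb_text, "rt")
    expect_equal(nrow(cs$chains[["A"]]$residues), 33)
    expect_equal(nrow(cs$chains[["B"]]$residues), 10)
    seqs <- extract_sequences(cs)
    expect_equal(unname(seqs$protein), toy$protein_seq)
    expect_equal(unname(seqs$rna), toy$rna_seq)
  }
})
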