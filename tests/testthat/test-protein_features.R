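tab <- residue_property_table()

test_that("molecular mass is additive and skips unknowns", {
  g <- tab["G", "molecular_weight"]
  expect_equal(protein_molecular_mass("G", tab), g)
  expect_equal(protein_molecular_mass("GG", tab), 2 * g)
  expect_warning(m <- protein_molecular_mass("GXG", tab), "skipping")
  expect_equal(m, 2 * g)
  expect_error(protein_molecular_mass("", tab), "nonempty")
})

test_that("hydrogen-bond totals match a per-character oracle", {
  expect_error(hydrogen_bond_total("", tab), "nonempty")
  expect_equal(hydrogen_bond_total("GG", tab), 2 * tab["G", "hbond_capacity"])
  set.seed(31)
  for (i in 1:20) {
    seq <- paste(sample(tab$aa, sample(5:60, 1), replace = TRUE), collapse = "")
    oracle <- sum(vapply(strsplit(seq, "")[[1]],
                         function(ch) tab[ch, "hbond_capacity"], numeric(1)))
    expect_equal(hydrogen_bond_total(seq, tab), oracle)
  }
})

test_that("residue-class counts respect the configured partition", {
  cc <- residue_class_counts("KRDE", tab)
  expect_equal(unname(cc["n_charged"]), 4)
  expect_equal(unname(cc["pct_charged"]), 100)
  # all-hydrophobic sequence saturates its class
  hydro <- paste(tab$aa[tab$hydrophobic], collapse = "")
  cc2 <- residue_class_counts(hydro, tab)
  expect_equal(unname(cc2["pct_hydrophobic"]), 100)
  expect_equal(unname(cc2["n_hydrophilic"]), 0)
  # His is aromatic and positively charged but counted once in the union
  cc3 <- residue_class_counts("H", tab)
  expect_equal(unname(cc3["n_aromatic_positive"]), 1)
})

test_that("class counts are permutation-invariant, additive and scale-invariant", {
  set.seed(7)
  for (i in 1:10) {
    seq <- paste(sample(tab$aa, 40, replace = TRUE), collapse = "")
    perm <- paste(sample(strsplit(seq, "")[[1]]), collapse = "")
    expect_equal(residue_class_counts(seq, tab), residue_class_counts(perm, tab))
    cc <- residue_class_counts(seq, tab)
    expect_true(cc["n_hydrophilic"] + cc["n_hydrophobic"] <= nchar(seq))
    expect_true(all(cc[grep("^pct_", names(cc))] >= 0 & cc[grep("^pct_", names(cc))] <= 100))
    # duplication leaves percentages unchanged, doubles counts
    dup <- residue_class_counts(paste0(seq, seq), tab)
    expect_equal(dup[grep("^pct_", names(dup))], cc[grep("^pct_", names(cc))])
    expect_equal(dup[grep("^n_", names(dup))], 2 * cc[grep("^n_", names(cc))])
  }
})

test_that("classic DSSP output parses, skipping chain breaks", {
  toy <- make_toy_complex(toy_complex_spec(n_protein_residues = 10, n_rna_nt = 4,
                                           n_basepairs = 1, seed = 8), "d1")
  ssr <- parse_dssp(toy$dssp_text)
  expect_equal(nrow(ssr), 10)
  expect_true(all(ssr$accessibility >= 0))
  # insert a '!' chain-break line
  lines <- strsplit(toy$dssp_text, "\n")[[1]]
  brk <- paste0(sprintf("%5d", 99), sprintf("%5d", 99), " ", "A", " ", "!")
  lines <- append(lines, brk, after = 7)
  ssr2 <- parse_dssp(lines)
  expect_equal(nrow(ssr2), 10)
  expect_error(parse_dssp(""), "missing")
  expect_error(parse_dssp("just some text\nwith lines"), "missing")
})

test_that("helix/sheet features follow the DSSP state sets", {
  spec <- toy_complex_spec(n_protein_residues = 10, n_rna_nt = 4, n_basepairs = 1,
                           protein_composition = c(A = 1),
                           ss_string = "HHHHEEECCC", seed = 10)
  toy <- make_toy_complex(spec, "ss1")
  ssr <- parse_dssp(toy$dssp_text)
  f <- secondary_structure_features(ssr, toy$protein_seq, tab)
  expect_equal(unname(f["helix_count"]), 4)
  expect_equal(unname(f["sheet_count"]), 3)
  expect_equal(unname(f["helix_pct"]), 40)
  expect_equal(unname(f["sheet_pct"]), 30)
  expect_equal(unname(f["helix_mass"]), 4 * tab["A", "molecular_weight"])
  expect_equal(unname(f["helix_segments"]), 1)
  expect_equal(unname(f["sheet_segments"]), 1)

  # all-coil record: everything zero
  spec0 <- toy_complex_spec(n_protein_residues = 10, n_rna_nt = 4, n_basepairs = 1,
                            ss_string = paste(rep("C", 10), collapse = ""), seed = 11)
  toy0 <- make_toy_complex(spec0, "ss0")
  f0 <- secondary_structure_features(parse_dssp(toy0$dssp_text), toy0$protein_seq, tab)
  expect_equal(unname(f0[c("helix_count", "sheet_count", "helix_mass",
                           "sheet_mass", "helix_pct", "sheet_pct")]),
               rep(0, 6))
})

test_that("total accessibility is a straight sum over the ACC column", {
  ssr <- data.frame(chain_id = "A", seq_number = 1:3, insertion_code = "",
                    aa = c("A", "G", "K"), ss_code = "C",
                    accessibility = c(10, 20, 30), stringsAsFactors = FALSE)
  expect_equal(total_rasa(ssr), 60)
  ssr0 <- ssr
  ssr0$accessibility <- 0
  expect_equal(total_rasa(ssr0), 0)
  set.seed(12)
  ssr$accessibility <- sample(0:250, 3)
  acc <- 0
  for (i in 1:3) acc <- acc + ssr$accessibility[i]
  expect_equal(total_rasa(ssr), acc)
  ssr$accessibility[1] <- -1
  expect_error(total_rasa(ssr), "negative")
})
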