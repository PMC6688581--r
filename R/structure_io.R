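#' Parse a protein-RNA complex from PDB-format text
#'
#' Reads ATOM/HETATM records (via [bio3d::read.pdb()]), groups atoms into
#' chains and residues, and types each chain as `protein`, `rna` or `other`.
#' Only the first model of a multi-model (NMR) file is used, and where
#' alternate locations are present the highest-occupancy alternative is kept
#' (ties resolved in file order).
#'
#' @param pdb_text Character scalar (or vector of lines) with PDB-format
#'   content containing at least one ATOM record.
#' @param complex_id Identifier attached to the parsed complex.
#' @return A `complex_structure` object: a list with `complex_id` and
#'   `chains`, where each chain holds `chain_id`, `kind` and a residue table
#'   (`name`, `seq_number`, `insertion_code`, `n_atoms`) plus its atoms.
#' @seealso [validate_complex()], [extract_sequences()]
#' @export
parse_complex <- function(pdb_text, complex_id) {
  lines <- if (length(pdb_text) == 1L) strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(rec == "ATOM  ")) {
    stop("no ATOM records found in PDB text for complex '", complex_id, "'")
  }
  # sanity-check fixed columns before handing over to the reader
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed ATOM/HETATM record at line ", i, ": record shorter than 54 columns")
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      stop("malformed ATOM/HETATM record at line ", i, ": non-numeric coordinates")
    }
  }
  # first model only
  endmdl <- which(rec == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1])]

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z))) {
    stop("non-finite coordinates in complex '", complex_id, "'")
  }

  # alternate locations: keep the highest-occupancy altloc per atom site
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      if (length(ix) == 1L) return(ix)
      ix[which.max(at$o[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  chains <- lapply(unique(at$chain), function(ch) {
    ca <- at[at$chain == ch, , drop = FALSE]
    rkey <- paste(ca$resno, ca$insert, sep = "_")
    first <- !duplicated(rkey)
    res <- data.frame(
      name = trimws(ca$resid[first]),
      seq_number = ca$resno[first],
      insertion_code = ca$insert[first],
      n_atoms = as.vector(table(factor(rkey, levels = unique(rkey)))),
      stringsAsFactors = FALSE
    )
    res <- res[order(res$seq_number, res$insertion_code), , drop = FALSE]
    rownames(res) <- NULL
    chain <- list(chain_id = ch, kind = NA_character_, residues = res,
                  atoms = ca[, c("elety", "resid", "resno", "insert", "x", "y", "z", "o")])
    chain$kind <- classify_chain(chain)
    chain
  })
  names(chains) <- vapply(chains, `[[`, "", "chain_id")
  if (anyDuplicated(names(chains))) {
    stop("duplicate chain identifiers in complex '", complex_id, "'")
  }
  structure(list(complex_id = complex_id, chains = chains),
            class = "complex_structure")
}

#' Type a chain as protein, RNA or other
#'
#' A chain is called `protein` when more than `threshold` of its residue names
#' are standard amino acids, `rna` when more than `threshold` are
#' ribonucleotides (A, U, G, C); anything else (waters, ligands, heavily
#' modified chains) is `other`.  The default threshold of 0.8 tolerates
#' occasional modified residues without misclassifying the chain.
#'
#' @param chain A chain element of a `complex_structure`, or anything with a
#'   `residues` data.frame carrying a `name` column.
#' @param threshold Fraction of residues that must match an alphabet.
#' @return One of `"protein"`, `"rna"`, `"other"`.
#' @export
classify_chain <- function(chain, threshold = 0.8) {
  res <- chain$residues$name
  if (!length(res)) stop("cannot classify an empty chain")
  frac_aa <- mean(res %in% names(aa_three_to_one))
  frac_rna <- mean(res %in% rna_alphabet)
  if (frac_aa > threshold) "protein" else if (frac_rna > threshold) "rna" else "other"
}

#' Extract one-letter sequences from a parsed complex
#'
#' Protein chains are mapped from 3-letter to 1-letter codes; RNA chains are
#' taken as-is.  Nonstandard residues (e.g. MSE) become `'X'` with a warning;
#' they count toward chain length but are excluded from the per-residue
#' property sums downstream.
#'
#' @param cs A `complex_structure`.
#' @return A list with `protein` and `rna`: named character vectors of
#'   sequences, one per chain, in chain order.
#' @export
extract_sequences <- function(cs) {
  stopifnot(inherits(cs, "complex_structure"))
  prot <- list()
  rna <- list()
  for (chain in cs$chains) {
    if (chain$kind == "protein") {
      codes <- aa_three_to_one[chain$residues$name]
      if (anyNA(codes)) {
        bad <- unique(chain$residues$name[is.na(codes)])
        warning("chain ", chain$chain_id, ": nonstandard residues mapped to 'X': ",
                paste(bad, collapse = ", "))
        codes[is.na(codes)] <- "X"
      }
      prot[[chain$chain_id]] <- paste(codes, collapse = "")
    } else if (chain$kind == "rna") {
      nt <- chain$residues$name
      if (!all(nt %in% rna_alphabet)) {
        bad <- unique(nt[!nt %in% rna_alphabet])
        warning("chain ", chain$chain_id, ": non-AUGC nucleotides mapped to 'X': ",
                paste(bad, collapse = ", "))
        nt[!nt %in% rna_alphabet] <- "X"
      }
      rna[[chain$chain_id]] <- paste(nt, collapse = "")
    }
  }
  list(protein = unlist(prot), rna = unlist(rna))
}

#' Apply the dataset admission filters to a complex
#'
#' Retains protein chains with 30 or more residues and RNA chains with 2 or
#' more nucleotides; shorter chains are dropped with a warning.  The complex
#' is rejected (with a reason code) when no protein or no RNA chain survives.
#'
#' @param cs A `complex_structure`.
#' @param min_protein_residues,min_rna_nt Admission thresholds.
#' @return The validated `complex_structure` (possibly with chains dropped).
#'   On rejection an error of class `prbind_validation_error` is signalled
#'   whose condition carries `reason` in `no_protein`, `no_rna`.
#' @export
validate_complex <- function(cs, min_protein_residues = 30, min_rna_nt = 2) {
  stopifnot(inherits(cs, "complex_structure"))
  keep <- vapply(cs$chains, function(chain) {
    n <- nrow(chain$residues)
    ok <- switch(chain$kind,
                 protein = n >= min_protein_residues,
                 rna = n >= min_rna_nt,
                 FALSE)
    if (!ok && chain$kind %in% c("protein", "rna")) {
      warning("complex ", cs$complex_id, ": dropping ", chain$kind, " chain ",
              chain$chain_id, " (", n, " residues, too_short)")
    }
    ok
  }, logical(1))
  out <- cs
  out$chains <- cs$chains[keep]
  kinds <- vapply(out$chains, `[[`, "", "kind")
  reject <- function(reason) {
    stop(errorCondition(
      paste0("complex ", cs$complex_id, " rejected: ", reason),
      reason = reason, class = c("prbind_validation_error", "error", "condition")
    ))
  }
  if (!any(kinds == "protein")) reject("no_protein")
  if (!any(kinds == "rna")) reject("no_rna")
  out
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex_structure:", x$complex_id, "\n")
  for (chain in x$chains) {
    cat(sprintf("  chain %s  %-7s %d residues\n",
                chain$chain_id, chain$kind, nrow(chain$residues)))
  }
  invisible(x)
}
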