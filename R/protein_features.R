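#' Protein molecular mass from sequence
#'
#' Sums per-residue molecular weights from the property table over a
#' one-letter protein sequence.  `'X'` placeholders (nonstandard residues)
#' are skipped with a warning so that property sums stay well defined.
#'
#' @param seq One-letter protein sequence (character scalar, nonempty).
#' @param table Property table from [residue_property_table()].
#' @return Total mass in Da.
#' @export
protein_molecular_mass <- function(seq, table = residue_property_table()) {
  chars <- seq_chars(seq)
  w <- table[chars, "molecular_weight"]
  if (anyNA(w)) {
    warning("skipping ", sum(is.na(w)), " residue(s) without a mass entry ('X' or unknown)")
  }
  sum(w, na.rm = TRUE)
}

#' Total hydrogen-bonding capacity of a protein sequence
#'
#' Sums the per-residue hydrogen-bond capacity (side-chain donor+acceptor
#' sites plus backbone sites; see [residue_property_table()]).
#'
#' @inheritParams protein_molecular_mass
#' @return Total count of hydrogen-bonding sites.
#' @export
hydrogen_bond_total <- function(seq, table = residue_property_table()) {
  chars <- seq_chars(seq)
  h <- table[chars, "hbond_capacity"]
  sum(h, na.rm = TRUE)
}

#' Residue-class counts and percentages
#'
#' Counts residues in the five class groupings of the feature catalogue:
#' hydrophilic, hydrophobic, aromatic-or-positively-charged (a union count,
#' so His is counted once), charged, and polar.  Percentages are relative to
#' the full sequence length (including any `'X'` placeholders).
#'
#' @inheritParams protein_molecular_mass
#' @return Named numeric vector with `n_*` counts and `pct_*` percentages for
#'   the five classes.
#' @export
residue_class_counts <- function(seq, table = residue_property_table()) {
  chars <- seq_chars(seq)
  n <- length(chars)
  known <- chars[chars %in% rownames(table)]
  cnt <- function(flag) sum(table[known, flag])
  counts <- c(
    n_hydrophilic = cnt("hydrophilic"),
    n_hydrophobic = cnt("hydrophobic"),
    n_aromatic_positive = sum(table[known, "aromatic"] | table[known, "positively_charged"]),
    n_charged = cnt("charged"),
    n_polar = cnt("polar")
  )
  pct <- 100 * counts / n
  names(pct) <- sub("^n_", "pct_", names(counts))
  c(counts, pct)
}

seq_chars <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("sequence must be a nonempty character scalar")
  }
  strsplit(seq, "")[[1]]
}

#' Parse classic DSSP output
#'
#' Reads the fixed-column residue lines of a classic `.dssp` file: PDB
#' residue number, insertion code, chain, amino acid, 8-state secondary
#' structure code, and the ACC solvent-accessibility column (A^2).
#' Chain-break lines (`'!'` in the AA column) are skipped.
#'
#' @param dssp_text DSSP file content (scalar or vector of lines).
#' @return A data.frame with `chain_id`, `seq_number`, `insertion_code`,
#'   `aa`, `ss_code`, `accessibility`.
#' @export
parse_dssp <- function(dssp_text) {
  lines <- if (length(dssp_text) == 1L) strsplit(dssp_text, "\n", fixed = TRUE)[[1]] else dssp_text
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not DSSP output: missing '  #  RESIDUE' header line")
  body <- lines[seq.int(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]  # chain breaks
  if (!length(body)) {
    return(data.frame(chain_id = character(), seq_number = integer(),
                      insertion_code = character(), aa = character(),
                      ss_code = character(), accessibility = numeric(),
                      stringsAsFactors = FALSE))
  }
  seqno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  acc <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  bad <- which(is.na(seqno) | is.na(acc))
  if (length(bad)) {
    stop("unparseable DSSP residue line ", hdr[1] + bad[1],
         ": ", trimws(body[bad[1]]))
  }
  if (any(acc < 0)) stop("negative accessibility in DSSP output")
  data.frame(
    chain_id = substr(body, 12, 12),
    seq_number = seqno,
    insertion_code = trimws(substr(body, 11, 11)),
    aa = substr(body, 14, 14),
    ss_code = substr(body, 17, 17),
    accessibility = acc,
    stringsAsFactors = FALSE
  )
}

#' Helix and sheet features from a DSSP record
#'
#' Residue counts, summed residue masses and percentages for alpha-helix and
#' beta-sheet states.  Helix states are DSSP `H`, `G`, `I`; sheet states are
#' `E`, `B` (configurable).  Counts are residue counts; contiguous-segment
#' counts are emitted alongside as auxiliary features.
#'
#' @param ssr Parsed DSSP record from [parse_dssp()].
#' @param seq One-letter protein sequence matching `ssr` row-for-row
#'   (concatenated protein chains).
#' @param table Property table for residue masses.
#' @param helix_set,sheet_set DSSP 8-state codes counted as helix / sheet.
#' @return Named numeric vector: `helix_count`, `sheet_count`, `helix_mass`,
#'   `sheet_mass`, `helix_pct`, `sheet_pct`, `helix_segments`,
#'   `sheet_segments`.
#' @export
secondary_structure_features <- function(ssr, seq, table = residue_property_table(),
                                         helix_set = c("H", "G", "I"),
                                         sheet_set = c("E", "B")) {
  chars <- seq_chars(seq)
  n <- length(chars)
  if (nrow(ssr) != n) {
    mismatch <- abs(nrow(ssr) - n) / max(n, 1)
    if (mismatch > 0.1) {
      stop("DSSP record (", nrow(ssr), " residues) does not join sequence (",
           n, " residues)")
    }
    warning("DSSP record and sequence lengths differ slightly; truncating to the shorter")
    m <- min(nrow(ssr), n)
    ssr <- ssr[seq_len(m), , drop = FALSE]
    chars <- chars[seq_len(m)]
    n <- m
  }
  mass_of <- function(sel) {
    w <- table[chars[sel], "molecular_weight"]
    sum(w, na.rm = TRUE)
  }
  in_helix <- ssr$ss_code %in% helix_set
  in_sheet <- ssr$ss_code %in% sheet_set
  segments <- function(x) sum(x & !c(FALSE, x[-length(x)]))
  c(
    helix_count = sum(in_helix),
    sheet_count = sum(in_sheet),
    helix_mass = mass_of(in_helix),
    sheet_mass = mass_of(in_sheet),
    helix_pct = 100 * sum(in_helix) / n,
    sheet_pct = 100 * sum(in_sheet) / n,
    helix_segments = segments(in_helix),
    sheet_segments = segments(in_sheet)
  )
}

#' Total solvent-accessible surface area
#'
#' Sums the DSSP ACC column (absolute accessibility, A^2) over all residues.
#' With `relative = TRUE` each residue's accessibility is first divided by
#' its maximum accessible surface area, giving a sum of relative
#' accessibilities instead.
#'
#' @param ssr Parsed DSSP record from [parse_dssp()].
#' @param relative Normalise per residue by maximum accessibility.
#' @return Summed accessibility (A^2, or dimensionless when `relative`).
#' @export
total_rasa <- function(ssr, relative = FALSE) {
  if (!nrow(ssr)) stop("empty DSSP record")
  if (any(ssr$accessibility < 0)) stop("negative accessibility")
  if (!relative) return(sum(ssr$accessibility))
  max_acc <- c(A = 106, R = 248, N = 157, D = 163, C = 135, E = 194, Q = 198,
               G = 84, H = 184, I = 169, L = 164, K = 205, M = 188, F = 197,
               P = 136, S = 130, T = 142, W = 227, Y = 222, V = 142)
  denom <- max_acc[ssr$aa]
  denom[is.na(denom)] <- mean(max_acc)
  sum(ssr$accessibility / denom)
}

#' Compute the full protein feature block
#'
#' Convenience wrapper combining the sequence-based features (mass, hydrogen
#' bonds, residue-class counts) and, when a DSSP record is supplied, the
#' structure-based features (helix/sheet counts, masses, percentages and
#' total accessibility).  Multi-chain proteins are handled by passing the
#' concatenation of all protein chains.
#'
#' @param seq Concatenated one-letter protein sequence.
#' @param ssr Optional parsed DSSP record aligned to `seq`.
#' @param table Property table.
#' @return Named numeric vector of protein features; structure features are
#'   `NA` when `ssr` is absent.
#' @export
protein_feature_block <- function(seq, ssr = NULL, table = residue_property_table()) {
  base <- c(
    protein_molecular_mass = suppressWarnings(protein_molecular_mass(seq, table)),
    hbond_total = hydrogen_bond_total(seq, table),
    residue_class_counts(seq, table)
  )
  if (is.null(ssr)) {
    struct <- c(helix_count = NA_real_, sheet_count = NA_real_,
                helix_mass = NA_real_, sheet_mass = NA_real_,
                helix_pct = NA_real_, sheet_pct = NA_real_,
                helix_segments = NA_real_, sheet_segments = NA_real_,
                total_rasa = NA_real_)
  } else {
    struct <- c(secondary_structure_features(ssr, seq, table),
                total_rasa = total_rasa(ssr))
  }
  c(base, struct)
}
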