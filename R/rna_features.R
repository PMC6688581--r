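#' RNA molecular mass from sequence
#'
#' Computes the RNA molecular weight from base composition as
#' `329.2*A + 306.2*U + 305.2*C + 345.2*G + 159`, where A, U, C, G are the
#' base counts and the constant 159 accounts for the terminal phosphate
#' group.  Non-AUGC characters are skipped with a warning.  For multi-chain
#' RNAs apply the formula per chain (the terminal term is per molecule) and
#' sum, or use [rna_feature_block()] which does so.
#'
#' @param seq One-letter RNA sequence over A, U, G, C.  The empty string is
#'   allowed and yields the constant term alone.
#' @return Mass in Da.
#' @export
rna_molecular_mass <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L) {
    stop("sequence must be a character scalar")
  }
  chars <- if (nzchar(seq)) strsplit(seq, "")[[1]] else character()
  unknown <- !chars %in% rna_alphabet
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " non-AUGC character(s) in RNA sequence")
    chars <- chars[!unknown]
  }
  329.2 * sum(chars == "A") + 306.2 * sum(chars == "U") +
    305.2 * sum(chars == "C") + 345.2 * sum(chars == "G") + 159
}

#' Parse RNAfold partition-function output
#'
#' Extracts the two Boltzmann-ensemble scalars printed by RNAfold in
#' partition-function mode: the frequency of the minimum-free-energy
#' structure in the ensemble, and the ensemble diversity (expected base-pair
#' distance).  Dot-bracket structure strings are ignored.
#'
#' @param text RNAfold output (scalar or vector of lines).
#' @return A list with `mfe_frequency` (in `[0, 1]`) and
#'   `ensemble_diversity` (`>= 0`).
#' @export
parse_rnafold_output <- function(text) {
  txt <- paste(if (length(text) > 1L) paste(text, collapse = "\n") else text)
  num <- "([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)"
  mf <- regmatches(txt, regexec(paste0("frequency of mfe structure in ensemble\\s+", num), txt))[[1]]
  dv <- regmatches(txt, regexec(paste0("ensemble diversity\\s+", num), txt))[[1]]
  if (length(mf) < 2L || length(dv) < 2L) {
    stop("not partition-function RNAfold output: missing 'frequency of mfe structure",
         " in ensemble' or 'ensemble diversity' line")
  }
  freq <- as.numeric(mf[2])
  div <- as.numeric(dv[2])
  if (freq < 0 || freq > 1) stop("MFE structure frequency ", freq, " outside [0, 1]")
  if (div < 0) stop("ensemble diversity must be nonnegative")
  list(mfe_frequency = freq, ensemble_diversity = div)
}

#' Parse RNAVIEW base-pair annotation output
#'
#' Reads the `BEGIN_base-pair ... END_base-pair` section of an RNAVIEW
#' `.out` listing.  Pair lines carry 1-based nucleotide indices and a
#' Leontis-Westhof edge/orientation annotation; canonical cis
#' Watson-Crick/Watson-Crick pairs (annotated `+/+ cis`, `-/- cis` or
#' `W/W cis`) are labelled `cWW`.  An optional
#' `BEGIN_base-phosphate ... END_base-phosphate` section lists
#' base-phosphate interactions with category labels such as `0BPh`.
#'
#' @param text RNAVIEW output (scalar or vector of lines).
#' @param rna_length Total RNA length in nucleotides; pair indices must not
#'   exceed it.
#' @return A `base_pair_record`: list with `pairs` (data.frame `i`, `j`,
#'   `family`), `base_phosphates` (data.frame `i`, `j`, `category`) and
#'   `rna_length`.
#' @export
parse_rnaview_output <- function(text, rna_length) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  section <- function(tag) {
    b <- grep(paste0("^BEGIN_", tag), lines)
    e <- grep(paste0("^END_", tag), lines)
    if (!length(b) || !length(e) || e[1] <= b[1]) return(character())
    if (e[1] == b[1] + 1L) return(character())
    lines[(b[1] + 1L):(e[1] - 1L)]
  }
  pair_lines <- section("base-pair")
  pairs <- data.frame(i = integer(), j = integer(), family = character(),
                      stringsAsFactors = FALSE)
  for (ln in pair_lines) {
    m <- regmatches(ln, regexec("^\\s*([0-9]+)_([0-9]+),", ln))[[1]]
    if (length(m) < 3L) next
    i <- as.integer(m[2]); j <- as.integer(m[3])
    fam <- if (grepl("(\\+/\\+|-/-|W/W)\\s+cis", ln)) "cWW" else {
      lw <- regmatches(ln, regexec("([WHSwhs./])/([WHSwhs./])\\s+(cis|tran)", ln))[[1]]
      if (length(lw) == 4L) {
        paste0(ifelse(lw[4] == "cis", "c", "t"), toupper(lw[2]), toupper(lw[3]))
      } else "unclassified"
    }
    pairs <- rbind(pairs, data.frame(i = i, j = j, family = fam,
                                     stringsAsFactors = FALSE))
  }
  bph_lines <- section("base-phosphate")
  bph <- data.frame(i = integer(), j = integer(), category = character(),
                    stringsAsFactors = FALSE)
  for (ln in bph_lines) {
    m <- regmatches(ln, regexec("^\\s*([0-9]+)_([0-9]+)\\s+([0-9]+BPh)", ln))[[1]]
    if (length(m) < 4L) next
    bph <- rbind(bph, data.frame(i = as.integer(m[2]), j = as.integer(m[3]),
                                 category = m[4], stringsAsFactors = FALSE))
  }
  idx <- c(pairs$i, pairs$j, bph$i, bph$j)
  if (length(idx) && (min(idx) < 1L || max(idx) > rna_length)) {
    stop("base-pair index outside [1, ", rna_length, "] in RNAVIEW output")
  }
  structure(list(pairs = pairs, base_phosphates = bph, rna_length = rna_length),
            class = "base_pair_record")
}

#' Base-pair family features
#'
#' Counts cis Watson-Crick (cWW) pairs and 0BPh base-phosphate interactions
#' and their relative frequencies: cWW relative to all annotated base pairs,
#' 0BPh relative to all annotated base-phosphate interactions, with 0/0
#' defined as 0.
#'
#' @param bpr A `base_pair_record` from [parse_rnaview_output()].
#' @return Named numeric vector `cww_count`, `cww_relative_frequency`,
#'   `bph0_count`, `bph0_relative_frequency`.
#' @export
basepair_features <- function(bpr) {
  stopifnot(inherits(bpr, "base_pair_record"))
  np <- nrow(bpr$pairs)
  nb <- nrow(bpr$base_phosphates)
  cww <- sum(bpr$pairs$family == "cWW")
  bph0 <- sum(bpr$base_phosphates$category == "0BPh")
  c(
    cww_count = cww,
    cww_relative_frequency = if (np > 0) cww / np else 0,
    bph0_count = bph0,
    bph0_relative_frequency = if (nb > 0) bph0 / nb else 0
  )
}

#' Compute the full RNA feature block
#'
#' Combines the sequence-based mass (applied per chain, terminal constant
#' added once per chain) with the ensemble features (computed on the first
#' chain by default, since folding output is single-sequence) and the
#' base-pair features.
#'
#' @param rna_seqs Character vector of RNA chain sequences.
#' @param ensemble Optional list from [parse_rnafold_output()].
#' @param bpr Optional `base_pair_record` from [parse_rnaview_output()].
#' @return Named numeric vector of RNA features; structure-derived entries
#'   are `NA` when their inputs are absent.
#' @export
rna_feature_block <- function(rna_seqs, ensemble = NULL, bpr = NULL) {
  mass <- sum(vapply(rna_seqs, rna_molecular_mass, numeric(1)))
  ens <- if (is.null(ensemble)) {
    c(mfe_frequency = NA_real_, ensemble_diversity = NA_real_)
  } else {
    c(mfe_frequency = ensemble$mfe_frequency,
      ensemble_diversity = ensemble$ensemble_diversity)
  }
  bp <- if (is.null(bpr)) {
    c(cww_count = NA_real_, cww_relative_frequency = NA_real_,
      bph0_count = NA_real_, bph0_relative_frequency = NA_real_)
  } else {
    basepair_features(bpr)
  }
  c(rna_molecular_mass = mass, ens, bp)
}
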