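rna_class_levels <- c("I_single_stranded", "II_duplex", "III_trna",
                      "IV_loop", "V_small_fragment", "VI_miscellaneous")

#' Assign a complex to one of six RNA-type classes
#'
#' Complexes are grouped by the kind of RNA bound: (I) single-stranded RNA,
#' (II) duplex RNA, (III) tRNA, (IV) RNA with loop structure, (V) small RNA
#' fragment, (VI) miscellaneous.  When an explicit curated label is given
#' (a roman numeral or an NDB-style category string) it is mapped directly
#' and structural inputs are ignored.  Otherwise a documented heuristic
#' cascade over sequence lengths and annotated base pairs is applied, with
#' fixed precedence V, II, III, IV, I, VI so the assignment is deterministic
#' and total (VI is the catch-all).
#'
#' The heuristic path is a tool extension: curated labels are the
#' authoritative route, and the cascade thresholds are exposed in
#' `class_rules()` so they can be audited or changed.
#'
#' @param rna_seqs Character vector of RNA chain sequences (at least one).
#' @param bpr Optional `base_pair_record` over the concatenated RNA.
#' @param explicit_label Optional curated class label; dominates when given.
#' @param rules Threshold list from [class_rules()].
#' @return A length-1 factor over the six class levels, with attribute
#'   `source` either `"explicit_label"` or `"rule"`.
#' @export
assign_class <- function(rna_seqs, bpr = NULL, explicit_label = NULL,
                         rules = class_rules()) {
  if (!length(rna_seqs)) stop("at least one RNA sequence is required")
  if (!is.null(explicit_label) && !is.na(explicit_label) && nzchar(explicit_label)) {
    lab <- map_explicit_label(explicit_label)
    return(structure(factor(lab, levels = rna_class_levels), source = "explicit_label"))
  }
  lens <- nchar(rna_seqs)
  total_nt <- sum(lens)
  cww <- if (!is.null(bpr)) bpr$pairs[bpr$pairs$family == "cWW", , drop = FALSE] else NULL
  n_pairs <- if (!is.null(bpr)) nrow(bpr$pairs) else 0L

  lab <- if (total_nt < rules$small_fragment_max_nt) {
    "V_small_fragment"
  } else if (length(rna_seqs) >= 2 && !is.null(cww) && nrow(cww) > 0 &&
             interchain_paired_fraction(cww, lens) > rules$duplex_min_paired_fraction) {
    "II_duplex"
  } else if (length(rna_seqs) == 1 && total_nt >= rules$trna_nt_range[1] &&
             total_nt <= rules$trna_nt_range[2] && !is.null(cww) &&
             count_hairpins(cww) >= rules$trna_min_hairpins) {
    "III_trna"
  } else if (length(rna_seqs) == 1 && !is.null(cww) && nrow(cww) > 0 &&
             count_hairpins(cww) >= 1 &&
             paired_fraction(cww, total_nt) >= rules$loop_min_paired_fraction) {
    "IV_loop"
  } else if (n_pairs == 0) {
    "I_single_stranded"
  } else {
    "VI_miscellaneous"
  }
  structure(factor(lab, levels = rna_class_levels), source = "rule")
}

#' Thresholds for the heuristic class cascade
#'
#' @param small_fragment_max_nt RNAs shorter than this are class V.
#' @param duplex_min_paired_fraction Fraction of nucleotides in inter-chain
#'   cWW pairs above which a multi-chain RNA is class II.
#' @param trna_nt_range Single-chain length window for tRNA.
#' @param trna_min_hairpins Minimum hairpin count for tRNA (cloverleaf).
#' @param loop_min_paired_fraction Minimum cWW-paired fraction for a
#'   single-chain RNA to count as loop-structured (class IV).
#' @return A named list of thresholds.
#' @export
class_rules <- function(small_fragment_max_nt = 8,
                        duplex_min_paired_fraction = 0.5,
                        trna_nt_range = c(60, 100),
                        trna_min_hairpins = 3,
                        loop_min_paired_fraction = 0.25) {
  list(small_fragment_max_nt = small_fragment_max_nt,
       duplex_min_paired_fraction = duplex_min_paired_fraction,
       trna_nt_range = trna_nt_range,
       trna_min_hairpins = trna_min_hairpins,
       loop_min_paired_fraction = loop_min_paired_fraction)
}

map_explicit_label <- function(label) {
  key <- tolower(trimws(label))
  lut <- c(
    "i" = 1, "single-stranded rna" = 1, "single stranded rna" = 1, "ssrna" = 1,
    "i_single_stranded" = 1,
    "ii" = 2, "duplex rna" = 2, "duplex" = 2, "dsrna" = 2, "double-stranded rna" = 2,
    "ii_duplex" = 2,
    "iii" = 3, "trna" = 3, "iii_trna" = 3,
    "iv" = 4, "rna loop" = 4, "loop" = 4, "loop structure" = 4, "iv_loop" = 4,
    "v" = 5, "small fragment" = 5, "small rna fragment" = 5, "v_small_fragment" = 5,
    "vi" = 6, "misc" = 6, "miscellaneous" = 6, "vi_miscellaneous" = 6
  )
  hit <- lut[key]
  if (is.na(hit)) {
    stop("unmappable RNA class label '", label, "'; accepted labels: ",
         paste(unique(names(lut)), collapse = ", "))
  }
  rna_class_levels[hit]
}

# which chain does a 1-based nucleotide index (over concatenated chains) fall in
chain_of <- function(idx, lens) findInterval(idx - 1L, cumsum(c(0L, lens)))

interchain_paired_fraction <- function(cww, lens) {
  inter <- chain_of(cww$i, lens) != chain_of(cww$j, lens)
  paired_nt <- unique(c(cww$i[inter], cww$j[inter]))
  length(paired_nt) / sum(lens)
}

paired_fraction <- function(cww, total_nt) {
  length(unique(c(cww$i, cww$j))) / total_nt
}

# hairpins = innermost pairs: no other pair strictly nested inside
count_hairpins <- function(cww) {
  if (!nrow(cww)) return(0L)
  lo <- pmin(cww$i, cww$j)
  hi <- pmax(cww$i, cww$j)
  innermost <- vapply(seq_along(lo), function(k) {
    !any(lo > lo[k] & hi < hi[k])
  }, logical(1))
  sum(innermost)
}
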