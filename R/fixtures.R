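# Synthetic-input generators.  Every artifact they emit is accepted by the
# corresponding parser, so the whole pipeline is testable without structure
# downloads or external binaries.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a toy protein-RNA complex
#'
#' @param n_protein_residues Protein chain length (residues).
#' @param n_rna_nt RNA chain length (nucleotides).
#' @param protein_composition Optional sampling weights over the 20 amino
#'   acids (named, 1-letter codes).
#' @param rna_composition Optional sampling weights over A, U, G, C.
#' @param ss_string Optional DSSP-style secondary structure string of length
#'   `n_protein_residues`; generated when `NULL`.
#' @param n_basepairs Number of nested base pairs to annotate (requires
#'   `2 * n_basepairs <= n_rna_nt`).
#' @param n_cww How many of those pairs are canonical cWW (default: all).
#' @param n_bph Number of 0BPh base-phosphate entries.
#' @param rna_class_label Curated class label for the manifest row.
#' @param include_waters Add a waters-only HETATM chain.
#' @param seed Seed; fully determines the generated artifacts.
#' @return A `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n_protein_residues = 35, n_rna_nt = 8,
                             protein_composition = NULL, rna_composition = NULL,
                             ss_string = NULL, n_basepairs = 2, n_cww = NULL,
                             n_bph = 1, rna_class_label = "I",
                             include_waters = FALSE, seed = 1L) {
  if (!is.null(ss_string) && nchar(ss_string) != n_protein_residues) {
    stop("ss_string length must equal n_protein_residues")
  }
  if (2 * n_basepairs > n_rna_nt) {
    stop("n_basepairs too large for RNA of length ", n_rna_nt)
  }
  if (is.null(n_cww)) n_cww <- n_basepairs
  if (n_cww > n_basepairs) stop("n_cww cannot exceed n_basepairs")
  structure(list(n_protein_residues = n_protein_residues, n_rna_nt = n_rna_nt,
                 protein_composition = protein_composition,
                 rna_composition = rna_composition, ss_string = ss_string,
                 n_basepairs = n_basepairs, n_cww = n_cww, n_bph = n_bph,
                 rna_class_label = rna_class_label,
                 include_waters = include_waters, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

#' Generate a toy complex and matched tool outputs
#'
#' Emits a mutually consistent set of text artifacts for one synthetic
#' protein-RNA complex: a PDB file (protein chain A with CA atoms on a
#' helix-like curve, RNA chain B with P atoms, optionally a waters chain W),
#' a classic-format DSSP file over the protein chain, RNAfold
#' partition-function output over the RNA sequence, an RNAVIEW base-pair
#' listing, and a manifest row.  Coordinates are placeholders: no feature
#' consumes them.
#'
#' @param spec A [toy_complex_spec()].
#' @param complex_id Identifier used in the artifacts.
#' @return A list `pdb_text`, `dssp_text`, `rnafold_text`, `rnaview_text`,
#'   `manifest_row`, plus `protein_seq` and `rna_seq`.
#' @export
make_toy_complex <- function(spec, complex_id = "toy1") {
  stopifnot(inherits(spec, "toy_complex_spec"))
  with_seed(spec$seed, {
    aas <- names(aa_three_to_one)
    pw <- spec$protein_composition
    if (!is.null(pw)) {
      pw <- pw[aa_three_to_one[aas]]
      pw[is.na(pw)] <- 0  # unnamed residues get zero weight
    }
    prot3 <- sample(aas, spec$n_protein_residues, replace = TRUE, prob = pw)
    rw <- spec$rna_composition
    if (!is.null(rw)) {
      rw <- rw[rna_alphabet]
      rw[is.na(rw)] <- 0
    }
    rna1 <- sample(rna_alphabet, spec$n_rna_nt, replace = TRUE, prob = rw)
    ss <- if (is.null(spec$ss_string)) random_ss_string(spec$n_protein_residues)
          else strsplit(spec$ss_string, "")[[1]]
    acc <- sample(0:200, spec$n_protein_residues, replace = TRUE)
    mfe_freq <- round(runif(1, 0.05, 0.95), 6)
    div <- round(runif(1, 0.2, 8), 2)
    kd <- 10^runif(1, -11, -4)

    pdb_text <- toy_pdb_text(prot3, rna1, spec$include_waters)
    dssp_text <- toy_dssp_text(prot3, ss, acc)
    rnafold_text <- toy_rnafold_text(rna1, spec$n_basepairs, mfe_freq, div)
    rnaview_text <- toy_rnaview_text(rna1, spec$n_basepairs, spec$n_cww, spec$n_bph)
    manifest_row <- data.frame(
      complex_id = complex_id, rna_class = spec$rna_class_label,
      kd_molar = kd, temperature_k = 298, stringsAsFactors = FALSE
    )
    list(pdb_text = pdb_text, dssp_text = dssp_text,
         rnafold_text = rnafold_text, rnaview_text = rnaview_text,
         manifest_row = manifest_row,
         protein_seq = paste(aa_three_to_one[prot3], collapse = ""),
         rna_seq = paste(rna1, collapse = ""))
  })
}

random_ss_string <- function(n) {
  out <- character(0)
  states <- c("H", "E", "C", "T", "G")
  while (length(out) < n) {
    s <- sample(states, 1, prob = c(0.35, 0.25, 0.25, 0.1, 0.05))
    out <- c(out, rep(s, sample(3:7, 1)))
  }
  out[seq_len(n)]
}

toy_pdb_text <- function(prot3, rna1, include_waters = FALSE) {
  fmt <- function(rec, serial, atom, res, chain, resno, x, y, z, elem) {
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, atom, res, chain, resno, x, y, z, 1.0, 20.0, elem)
  }
  lines <- character(0)
  serial <- 0L
  helix <- function(i) c(2.3 * cos(i * 0.6), 2.3 * sin(i * 0.6), 1.5 * i)
  for (i in seq_along(prot3)) {
    serial <- serial + 1L
    p <- helix(i)
    lines <- c(lines, fmt("ATOM", serial, "CA", prot3[i], "A", i, p[1], p[2], p[3], "C"))
  }
  lines <- c(lines, "TER")
  for (i in seq_along(rna1)) {
    serial <- serial + 1L
    p <- helix(i) + c(12, 0, 0)
    lines <- c(lines, fmt("ATOM", serial, "P",
                          sprintf("%3s", rna1[i]), "B", i, p[1], p[2], p[3], "P"))
  }
  lines <- c(lines, "TER")
  if (include_waters) {
    for (i in 1:3) {
      serial <- serial + 1L
      lines <- c(lines, fmt("HETATM", serial, "O", "HOH", "W", i,
                            30 + i, 30, 30, "O"))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

toy_dssp_text <- function(prot3, ss, acc) {
  header <- c(
    "==== Secondary Structure Definition by the program DSSP, toy dialect ====",
    "REFERENCE toy fixture",
    sprintf("  %d  1  0  0  0 TOTAL NUMBER OF RESIDUES", length(prot3)),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  )
  aa1 <- aa_three_to_one[prot3]
  body <- sprintf("%5d%5d %1s %1s  %1s%17s%4d", seq_along(prot3), seq_along(prot3),
                  "A", aa1, ss, "", acc)
  paste(c(header, body), collapse = "\n")
}

toy_rnafold_text <- function(rna1, n_bp, mfe_freq, div) {
  n <- length(rna1)
  db <- rep(".", n)
  if (n_bp > 0) {
    db[seq_len(n_bp)] <- "("
    db[n - seq_len(n_bp) + 1L] <- ")"
  }
  db <- paste(db, collapse = "")
  paste(c(
    paste(rna1, collapse = ""),
    sprintf("%s ( -%.2f)", db, 1.5 * n_bp + 0.4),
    sprintf("%s [ -%.2f]", db, 1.5 * n_bp + 0.9),
    sprintf("%s { -%.2f d=%.2f}", db, 1.5 * n_bp + 0.4, div / 2),
    sprintf(" frequency of mfe structure in ensemble %.6f; ensemble diversity %.2f",
            mfe_freq, div)
  ), collapse = "\n")
}

toy_rnaview_text <- function(rna1, n_bp, n_cww, n_bph) {
  n <- length(rna1)
  lines <- c("PDB data file name: toy.pdb", "BEGIN_base-pair")
  if (n_bp > 0) {
    for (k in seq_len(n_bp)) {
      i <- k
      j <- n - k + 1L
      ann <- if (k <= n_cww) "+/+ cis         XIX" else "H/S tran        n/a"
      lines <- c(lines, sprintf("%6d_%d, B: %5d %s-%s %5d B: %s",
                                i, j, i, rna1[i], rna1[j], j, ann))
    }
  }
  lines <- c(lines, "END_base-pair")
  if (n_bph > 0) {
    lines <- c(lines, "BEGIN_base-phosphate")
    for (k in seq_len(min(n_bph, n - 1))) {
      lines <- c(lines, sprintf("%6d_%d  0BPh", k, k + 1L))
    }
    lines <- c(lines, "END_base-phosphate")
  }
  paste(lines, collapse = "\n")
}

#' Synthetic regression dataset for learner tests
#'
#' `y = f(X) + Normal(0, noise_sd)` with `f` constant, linear, or
#' piecewise-constant (three steps per informative feature) in the declared
#' informative features; all other features are pure noise.
#'
#' @param n,p Sample size and feature count.
#' @param signal One of `"piecewise"`, `"linear"`, `"constant"`.
#' @param informative Indices of informative features.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Seed; fully determines the dataset.
#' @return A list `X` (n x p, columns `x1..xp`), `y`, and `true_function`.
#' @export
make_regression_dataset <- function(n, p, signal = c("piecewise", "linear", "constant"),
                                    informative = 1L, noise_sd = 0, seed = 1L) {
  signal <- match.arg(signal)
  if (n < 2 || p < 1) stop("need n >= 2 and p >= 1")
  if (any(informative > p)) stop("informative index exceeds p")
  f <- switch(signal,
    constant = function(X) rep(1, nrow(X)),
    linear = function(X) rowSums(2 * X[, informative, drop = FALSE]),
    piecewise = function(X) rowSums(floor(3 * X[, informative, drop = FALSE]))
  )
  with_seed(seed, {
    X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- f(X) + rnorm(n, 0, noise_sd)
    list(X = X, y = y, true_function = f)
  })
}

#' Paper-shaped synthetic affinity benchmark
#'
#' Generates a benchmark mimicking the study conditions of the real affinity
#' dataset: six classes with sizes 21/34/8/9/11/20 (103 complexes), a small
#' number of planted informative features plus noise features, and deltaG
#' values confined to the observed 5-15.2 kcal/mol range.  Each class gets
#' its own signal orientation (the planted effect flips sign between
#' classes), so pooling all classes destroys the signal while per-class
#' models retain it.
#'
#' @param class_sizes Named integer vector of complexes per class (roman
#'   numerals I-VI); all sizes `>= 3`.
#' @param n_planted Number of planted informative features.
#' @param n_noise Number of uninformative features.
#' @param noise_sd Gaussian noise on deltaG, kcal/mol.
#' @param planted_families Registry families assigned to planted features
#'   (recycled), used by ablation studies on this benchmark.
#' @param seed Seed; fully determines the tables.
#' @return A list `manifest` (complex_id, rna_class), `features`
#'   (complex_id + feature columns), `affinity` (complex_id, delta_g,
#'   temperature, kd), `planted` (feature names),
#'   `feature_families` (named character vector).
#' @export
make_affinity_benchmark <- function(class_sizes = c(I = 21, II = 34, III = 8,
                                                    IV = 9, V = 11, VI = 20),
                                    n_planted = 3, n_noise = 12,
                                    noise_sd = 0.3,
                                    planted_families = c("rna_seq", "protein_seq",
                                                         "protein_struct"),
                                    seed = 1L) {
  if (any(class_sizes < 3)) stop("class sizes must be >= 3")
  n <- sum(class_sizes)
  planted <- paste0("planted_", seq_len(n_planted))
  noise_f <- paste0("noise_", seq_len(n_noise))
  feat_names <- c(planted, noise_f)
  # planted effects comparable in size; deltaG range anchored inside 5-15.2
  weights <- seq(2.5, 1.5, length.out = n_planted)
  class_sign <- rep_len(c(1, -1), length(class_sizes))
  base <- ifelse(class_sign > 0, 6.2, 13.0)
  with_seed(seed, {
    X <- matrix(runif(n * length(feat_names)), n,
                dimnames = list(NULL, feat_names))
    cls <- rep(names(class_sizes), class_sizes)
    signal <- as.numeric(X[, planted, drop = FALSE] %*% weights)
    dg <- base[match(cls, names(class_sizes))] +
      class_sign[match(cls, names(class_sizes))] * signal +
      rnorm(n, 0, noise_sd)
    dg <- pmin(pmax(dg, 5.05), 15.15)
    ids <- sprintf("syn%03d", seq_len(n))
    families <- setNames(
      c(rep_len(planted_families, n_planted),
        rep_len(c("protein_seq", "protein_struct", "rna_seq", "rna_struct"),
                n_noise)),
      feat_names)
    list(
      manifest = data.frame(complex_id = ids, rna_class = cls,
                            stringsAsFactors = FALSE),
      features = data.frame(complex_id = ids, X, stringsAsFactors = FALSE),
      affinity = data.frame(complex_id = ids, delta_g_kcal_mol = dg,
                            temperature_k = 298,
                            kd_molar = kd_from_delta_g(dg, 298),
                            stringsAsFactors = FALSE),
      planted = planted,
      feature_families = families
    )
  })
}
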