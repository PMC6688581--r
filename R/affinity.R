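# Gas constant, kcal mol^-1 K^-1
GAS_CONSTANT_KCAL <- 1.987e-3

#' Convert a dissociation constant to dissociation free energy
#'
#' `deltaG = -R * T * ln(Kd)` with `R = 1.987e-3 kcal mol^-1 K^-1`.  Under
#' this sign convention a sub-molar Kd gives a positive deltaG, and tighter
#' binding (smaller Kd) gives a larger deltaG.
#'
#' @param kd Dissociation constant in mol/L (`> 0`).
#' @param temperature Temperature in K (`> 0`).
#' @return deltaG in kcal/mol.
#' @examples
#' delta_g_from_kd(1e-6, 298.15)  # ~8.18 kcal/mol
#' @export
delta_g_from_kd <- function(kd, temperature) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be positive and finite")
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive and finite")
  }
  -GAS_CONSTANT_KCAL * temperature * log(kd)
}

#' Invert the free-energy conversion
#'
#' @param delta_g deltaG in kcal/mol.
#' @param temperature Temperature in K.
#' @return Kd in mol/L.
#' @export
kd_from_delta_g <- function(delta_g, temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive and finite")
  }
  exp(-delta_g / (GAS_CONSTANT_KCAL * temperature))
}

#' Read a tabular affinity file
#'
#' Reads a TSV with header columns `complex_id`, and either `kd_molar` plus
#' `temperature_k`, or `delta_g_kcal_mol` directly (optionally `ph` as
#' metadata).  Missing deltaG values are filled from Kd; when both are
#' present they must agree to within `tol` kcal/mol.  Rows lacking a
#' temperature default to 298 K with a warning.
#'
#' @param tsv TSV content (character scalar / lines) or a file path.
#' @param tol Consistency tolerance between supplied and recomputed deltaG.
#' @return A data.frame with `complex_id`, `kd_molar`, `temperature_k`,
#'   `delta_g_kcal_mol`, `ph`.
#' @export
read_affinity_table <- function(tsv, tol = 1e-6) {
  tab <- read_tsv_arg(tsv)
  if (!"complex_id" %in% names(tab)) stop("affinity table needs a complex_id column")
  for (col in c("kd_molar", "temperature_k", "delta_g_kcal_mol", "ph")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
    tab[[col]] <- as.numeric(tab[[col]])
  }
  no_temp <- is.na(tab$temperature_k)
  if (any(no_temp & !is.na(tab$kd_molar))) {
    warning(sum(no_temp & !is.na(tab$kd_molar)),
            " row(s) without temperature; defaulting to 298 K")
  }
  tab$temperature_k[no_temp] <- 298
  for (r in seq_len(nrow(tab))) {
    kd <- tab$kd_molar[r]
    dg <- tab$delta_g_kcal_mol[r]
    if (is.na(kd) && is.na(dg)) {
      stop("affinity row ", r, " (", tab$complex_id[r],
           "): neither kd_molar nor delta_g_kcal_mol given")
    }
    if (!is.na(kd)) {
      dg_calc <- delta_g_from_kd(kd, tab$temperature_k[r])
      if (!is.na(dg) && abs(dg - dg_calc) > tol) {
        stop("affinity row ", r, " (", tab$complex_id[r], "): delta_g ", dg,
             " inconsistent with kd (expected ", signif(dg_calc, 8), ")")
      }
      tab$delta_g_kcal_mol[r] <- dg_calc
    }
  }
  tab[, c("complex_id", "kd_molar", "temperature_k", "delta_g_kcal_mol", "ph")]
}

read_tsv_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE)
  } else {
    txt <- if (length(x) > 1L) paste(x, collapse = "\n") else x
    utils::read.delim(textConnection(txt), stringsAsFactors = FALSE)
  }
}
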