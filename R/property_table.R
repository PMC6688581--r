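#' Amino-acid property table
#'
#' Per-residue physicochemical properties used by the protein feature
#' catalogue: molecular weight, hydrogen-bonding capacity, and membership in
#' six residue classes.  The default table ships with the package as a TSV
#' config file so that alternative partitions can be swapped in and audited.
#'
#' Molecular weights are average masses of the free amino acids in Da
#' (e.g. Gly 75.07).  Hydrogen-bond capacity counts side-chain donor plus
#' acceptor sites from a standard tabulation, plus two backbone sites
#' (amide N-H donor, carbonyl acceptor) per residue.  Class memberships:
#' hydrophobic \{A,V,L,I,M,F,W,C\}; hydrophilic is the complement
#' \{R,K,D,E,N,Q,H,S,T,Y,G,P\} (the two flags are mutually exclusive);
#' aromatic \{F,W,Y,H\}; positively charged \{K,R,H\}; charged \{D,E,K,R,H\};
#' polar \{S,T,N,Q,Y,C,H\}.
#'
#' @param path Path to a property-table TSV.  Defaults to the table shipped
#'   in `inst/extdata/residue_properties.tsv`.
#' @return A data.frame with one row per standard amino acid and columns
#'   `aa` (1-letter code), `code3` (3-letter code), `molecular_weight` (Da),
#'   `hbond_capacity` (integer), and logical columns `hydrophilic`,
#'   `hydrophobic`, `aromatic`, `positively_charged`, `charged`, `polar`.
#' @examples
#' tab <- residue_property_table()
#' tab[tab$aa == "G", "molecular_weight"]
#' @export
residue_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_properties.tsv", package = "prbind")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_property_table(tab)
}

validate_property_table <- function(tab) {
  need <- c("aa", "code3", "molecular_weight", "hbond_capacity", "hydrophilic",
            "hydrophobic", "aromatic", "positively_charged", "charged", "polar")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("property table is missing columns: ", paste(missing, collapse = ", "))
  }
  for (cl in need[5:10]) tab[[cl]] <- as.logical(tab[[cl]])
  if (!setequal(tab$aa, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("property table must cover exactly the 20 standard amino acids")
  }
  if (anyNA(tab[need])) stop("property table has missing entries")
  if (any(tab$hydrophilic & tab$hydrophobic)) {
    stop("hydrophilic and hydrophobic flags must be mutually exclusive")
  }
  if (any(tab$molecular_weight <= 0) || any(tab$hbond_capacity < 0)) {
    stop("property table has non-physical weights or capacities")
  }
  rownames(tab) <- tab$aa
  tab
}

# 3-letter -> 1-letter lookup (standard residues only)
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

rna_alphabet <- c("A", "U", "G", "C")
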