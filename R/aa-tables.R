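## Reference tables used by the interface-energy and clash machinery.
##
## Residue character classes (charged / polar / apolar) follow the
## published contact-based binding-affinity predictor this package
## reimplements: Asp, Glu, Lys, Arg and His are charged; Asn, Gln, Ser,
## Thr and Tyr are polar; the rest (including Cys, Gly, Pro, Trp) are
## apolar. The same table feeds both interfacial-contact classification
## and the non-interacting-surface (NIS) composition terms.

.aa_class <- c(
  ALA = "apolar", CYS = "apolar", GLY = "apolar", ILE = "apolar",
  LEU = "apolar", MET = "apolar", PHE = "apolar", PRO = "apolar",
  TRP = "apolar", VAL = "apolar",
  ASN = "polar", GLN = "polar", SER = "polar", THR = "polar", TYR = "polar",
  ASP = "charged", GLU = "charged", HIS = "charged", LYS = "charged",
  ARG = "charged")

#' Residue character class
#'
#' @param res_name character vector of 3-letter residue codes.
#' @return character vector with values `"charged"`, `"polar"`, `"apolar"`
#'   or `NA` for non-standard residues.
#' @export
residue_class <- function(res_name) {
  unname(.aa_class[toupper(res_name)])
}

## Theoretical maximum accessible surface areas (A^2) per residue type
## (Tien et al. 2013, theoretical values), used to normalise per-residue
## SASA into relative accessibility.
.max_asa <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

## Van der Waals radii (A), Bondi set with common extensions; used both
## for SASA integration and for the clash criterion.
.vdw_radii <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  FE = 2.00, ZN = 1.39, MG = 1.73, MN = 2.00, CA = 2.00, "NA" = 2.27,
  K = 2.75, SE = 1.90)
.vdw_default <- 1.80

#' Van der Waals radius by element
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom (1.8 for unknown elements).
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}
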