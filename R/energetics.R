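## Contact-based interface binding free energy.
##
## The model is the published linear combination of interfacial-contact
## counts and non-interacting-surface composition:
##
##   dG = -0.09459*ic_cc - 0.10007*ic_ca + 0.19577*ic_pp - 0.22671*ic_pa
##        + 0.18681*%NIS_apolar + 0.13810*%NIS_charged - 15.9433
##
## in kcal/mol, negative = favourable. charged/polar and apolar/apolar
## contacts carry no weight but are counted for bookkeeping.

.dg_coef <- c(ic_cc = -0.09459, ic_ca = -0.10007, ic_pp = 0.19577,
              ic_pa = -0.22671, pct_apolar = 0.18681,
              pct_charged = 0.13810, intercept = -15.9433)

#' Predict interface binding free energy from counts and NIS terms
#'
#' @param counts a [contact_counts()].
#' @param nis a [nis_profile()].
#' @param group_a,group_b optional chain-id sets, recorded in the result.
#' @param relaxed logical flag recording whether input coordinates were
#'   side-chain relaxed (the prediction is the same; relaxation is outside
#'   this package's scope but materially changes contact counts).
#' @return object of class `binding_energy` with fields `dg` (kcal/mol),
#'   `counts`, `nis`, `group_a`, `group_b`, `relaxed`.
#' @export
predict_dG <- function(counts, nis, group_a = NULL, group_b = NULL,
                       relaxed = FALSE) {
  stopifnot(inherits(counts, "contact_counts"), inherits(nis, "nis_profile"))
  dg <- .dg_coef[["intercept"]] +
    .dg_coef[["ic_cc"]] * counts$ic_cc +
    .dg_coef[["ic_ca"]] * counts$ic_ca +
    .dg_coef[["ic_pp"]] * counts$ic_pp +
    .dg_coef[["ic_pa"]] * counts$ic_pa +
    .dg_coef[["pct_apolar"]] * nis$pct_apolar +
    .dg_coef[["pct_charged"]] * nis$pct_charged
  structure(list(dg = dg, counts = counts, nis = nis,
                 group_a = group_a, group_b = group_b, relaxed = relaxed),
            class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  cat(sprintf("<binding_energy> dG = %.2f kcal/mol (%s vs %s)\n", x$dg,
              paste(x$group_a, collapse = "+"),
              paste(x$group_b, collapse = "+")))
  invisible(x)
}

#' Interface binding free energy of a two-group complex
#'
#' Convenience wrapper: computes interfacial contacts, the complex SASA and
#' NIS profile, and the contact-based dG, in one call.
#'
#' @param model the complex as a [structure_model()].
#' @param group_a,group_b disjoint chain-id sets.
#' @param cutoff contact distance cutoff (Angstrom).
#' @param sasa_points sphere points for the SASA integration.
#' @param relaxed see [predict_dG()].
#' @return a `binding_energy`; the contact table is attached as
#'   `attr(, "contacts")`.
#' @export
binding_energy <- function(model, group_a, group_b, cutoff = 5.5,
                           sasa_points = 240, relaxed = FALSE) {
  ic <- interface_contacts(model, group_a, group_b, cutoff = cutoff)
  sub <- extract_chains(model, c(group_a, group_b))
  nis <- nis_profile(sub, n_points = sasa_points)
  be <- predict_dG(ic$counts, nis, group_a = group_a, group_b = group_b,
                   relaxed = relaxed)
  attr(be, "contacts") <- ic$contacts
  be
}

#' Classify a predicted complex as real or absent
#'
#' A predicted binding energy of magnitude below the threshold (default
#' 3 kcal/mol) signs the absence of any predicted complex; the boundary is
#' inclusive (|dG| equal to the threshold classifies as complex).
#'
#' @param be a `binding_energy` or a bare numeric dG in kcal/mol.
#' @param threshold magnitude threshold in kcal/mol.
#' @return `"complex"` or `"no_complex"`.
#' @export
classify_complex <- function(be, threshold = 3.0) {
  dg <- if (inherits(be, "binding_energy")) be$dg else as.numeric(be)
  if (abs(dg) < threshold) "no_complex" else "complex"
}
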