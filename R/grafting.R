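## Cofactor grafting and linker feasibility.
##
## Predictors do not model cofactors; heme, FMN and FAD are transferred
## from reference crystal structures by superposing the reference protein
## domain onto the model and applying the same rigid transform to the
## cofactor atoms. Linker feasibility checks whether an erased segment
## can physically bridge its two anchor residues.

#' Cofactor template
#'
#' @param reference a [structure_model()] holding the reference crystal
#'   structure (protein + cofactor).
#' @param domain_spec a [domain_spec()]: the protein region used for
#'   fitting.
#' @param cofactor_name hetero residue name of the cofactor (e.g. `"HEM"`,
#'   `"FMN"`, `"FAD"`).
#' @param cofactor_chain chain carrying the cofactor (default: the domain
#'   chain).
#' @return object of class `cofactor_template`.
#' @export
cofactor_template <- function(reference, domain_spec, cofactor_name,
                              cofactor_chain = NULL) {
  if (is.null(cofactor_chain)) cofactor_chain <- domain_spec$chain_id
  a <- reference$atoms
  sel <- a$res_name == cofactor_name & a$chain == cofactor_chain
  if (!any(sel)) {
    stop("cofactor '", cofactor_name, "' not found on chain ",
         cofactor_chain, " of the reference")
  }
  if (!all(a$is_hetero[sel])) {
    stop("cofactor '", cofactor_name, "' atoms must be hetero records")
  }
  structure(list(reference = reference, domain_spec = domain_spec,
                 cofactor_name = cofactor_name,
                 cofactor_chain = cofactor_chain),
            class = "cofactor_template")
}

#' Superpose a reference domain onto a target domain
#'
#' Least-squares rigid fit over Ca atoms paired by author residue number
#' (after adding `offset` to the reference numbering). No sequence
#' alignment is performed.
#'
#' @param reference,target [structure_model()]s.
#' @param spec_ref,spec_target [domain_spec()]s naming the fit regions.
#' @param offset integer added to reference residue numbers to match the
#'   target numbering.
#' @return list with `transform` (a [rigid_transform()] taking reference
#'   coordinates onto the target), `rmsd` (Angstrom) and `n_matched_ca`.
#' @export
superpose_by_domain <- function(reference, target, spec_ref, spec_target,
                                offset = 0L) {
  mc <- matched_ca(reference, target,
                   chain_mobile = spec_ref$chain_id,
                   chain_target = spec_target$chain_id,
                   range = c(spec_target$start, spec_target$end),
                   offset = as.integer(offset))
  if (mc$n < 3L) {
    stop("insufficient matched Ca pairs for superposition (got ",
         mc$n, ", need >= 3)")
  }
  fit <- kabsch(mc$mobile, mc$target)
  list(transform = fit$transform, rmsd = fit$rmsd, n_matched_ca = mc$n)
}

#' Graft a cofactor from a reference structure into a model
#'
#' Superposes the template's protein domain onto `spec_target` of the
#' model and transfers the cofactor atoms with the same rigid transform.
#' Pre-existing model atoms are never modified. The grafted cofactor is
#' appended as hetero records with sequential numbering on a reserved
#' chain id.
#'
#' @param template a [cofactor_template()].
#' @param target_model a [structure_model()].
#' @param spec_target [domain_spec()] of the matching region in the model.
#' @param offset numbering offset, see [superpose_by_domain()].
#' @param graft_chain chain id given to grafted atoms (default `"X"`, or
#'   the next free id if taken).
#' @param clash_tolerance tolerance for the post-graft clash report.
#' @return object of class `graft_result`: `model`, `fit_rmsd`,
#'   `n_matched_ca`, `graft_chain`, `post_graft_clashes`.
#' @export
graft_cofactor <- function(template, target_model, spec_target,
                           offset = 0L, graft_chain = "X",
                           clash_tolerance = 0.4) {
  stopifnot(inherits(template, "cofactor_template"))
  fit <- superpose_by_domain(template$reference, target_model,
                             template$domain_spec, spec_target,
                             offset = offset)
  a <- template$reference$atoms
  sel <- a$res_name == template$cofactor_name &
    a$chain == template$cofactor_chain
  cof <- a[sel, , drop = FALSE]
  xyz <- apply_transform(as.matrix(cof[, c("x", "y", "z")]), fit$transform)
  cof$x <- xyz[, 1]; cof$y <- xyz[, 2]; cof$z <- xyz[, 3]
  if (graft_chain %in% chain_ids(target_model)) {
    graft_chain <- setdiff(c("X", "Y", "Z", LETTERS, letters),
                           chain_ids(target_model))[1]
  }
  cof$chain <- graft_chain
  cof$is_hetero <- TRUE
  cof$res_number <- match(paste(cof$res_number, cof$ins_code),
                          unique(paste(cof$res_number, cof$ins_code)))
  cof$ins_code <- ""
  cof$serial <- max(target_model$atoms$serial, 0L) + seq_len(nrow(cof))
  out_atoms <- rbind(target_model$atoms, cof)
  rownames(out_atoms) <- NULL
  out <- structure_model(out_atoms, metadata = target_model$metadata)
  clashes <- detect_clashes(out, chain_ids(target_model), graft_chain,
                            tolerance = clash_tolerance,
                            include_hetero = TRUE)
  structure(list(model = out, fit_rmsd = fit$rmsd,
                 n_matched_ca = fit$n_matched_ca,
                 graft_chain = graft_chain,
                 post_graft_clashes = clashes),
            class = "graft_result")
}

#' @export
print.graft_result <- function(x, ...) {
  cat(sprintf(
    "<graft_result> fit rmsd %.3f A over %d Ca, graft chain %s, %d clash(es)\n",
    x$fit_rmsd, x$n_matched_ca, x$graft_chain,
    x$post_graft_clashes$clash_count))
  invisible(x)
}

#' Linker gap descriptor
#'
#' @param chain chain id (the logical chain the linker belongs to).
#' @param from_res author number of the residue on the C-terminal side of
#'   the gap (its backbone C is the first anchor).
#' @param to_res author number of the residue on the N-terminal side of
#'   the downstream segment (its backbone N is the second anchor).
#' @param n_missing number of missing residues in between (>= 0).
#' @param to_chain chain of the downstream anchor when it differs (seams
#'   between merged parts).
#' @return object of class `linker_gap`.
#' @export
linker_gap <- function(chain, from_res, to_res, n_missing,
                       to_chain = chain) {
  stopifnot(n_missing >= 0)
  structure(list(chain = as.character(chain),
                 from_res = as.integer(from_res),
                 to_res = as.integer(to_res),
                 n_missing = as.integer(n_missing),
                 to_chain = as.character(to_chain)),
            class = "linker_gap")
}

#' Check that a linker can bridge a gap
#'
#' The observed gap is the distance from the backbone C of the upstream
#' anchor to the backbone N of the downstream anchor; the maximal reach of
#' the missing segment is `(n_missing + 1) * per_residue_reach`, an
#' extended-chain bound with the trans Ca-Ca step of 3.8 A per residue
#' (3.5 A is a common conservative choice). The bound is this package's
#' own criterion - it asserts length sufficiency only, not that any
#' particular loop conformation exists.
#'
#' @param model a [structure_model()].
#' @param gap a [linker_gap()].
#' @param per_residue_reach Angstrom per missing residue.
#' @return list with `feasible`, `observed_gap` (Angstrom), `max_reach`
#'   (Angstrom), and the input `gap`.
#' @export
check_linker_feasibility <- function(model, gap, per_residue_reach = 3.8) {
  stopifnot(inherits(gap, "linker_gap"))
  anchor <- function(chain, res, atom) {
    a <- model$atoms
    hit <- a$chain == chain & a$res_number == res & a$name == atom &
      !a$is_hetero
    if (!any(hit)) {
      stop("anchor residue ", chain, ":", res, " lacks backbone atom ",
           atom)
    }
    as.numeric(a[which(hit)[1], c("x", "y", "z")])
  }
  c_from <- anchor(gap$chain, gap$from_res, "C")
  n_to <- anchor(gap$to_chain, gap$to_res, "N")
  observed <- sqrt(sum((c_from - n_to)^2))
  max_reach <- (gap$n_missing + 1) * per_residue_reach
  list(feasible = observed <= max_reach, observed_gap = observed,
       max_reach = max_reach, gap = gap)
}
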