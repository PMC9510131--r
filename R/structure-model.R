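#' Macromolecular structure container
#'
#' A `structure_model` stores one coordinate model as a flat atom table plus
#' free-form metadata. It is the common currency of every geometric operation
#' in the package: domain extraction, interface scoring, symmetry detection,
#' rigid-body assembly and cofactor grafting all consume and return this
#' class.
#'
#' The atom table has one row per atom with columns:
#' \describe{
#'   \item{serial}{integer atom serial}
#'   \item{name}{atom name, e.g. `"CA"`}
#'   \item{alt_loc}{alternate location indicator, `""` when absent}
#'   \item{res_name}{3-letter residue name}
#'   \item{chain}{chain identifier}
#'   \item{res_number}{author residue number (1-based)}
#'   \item{ins_code}{insertion code, `""` when absent}
#'   \item{x,y,z}{coordinates in Angstrom}
#'   \item{occupancy}{occupancy fraction}
#'   \item{b_factor}{isotropic B-factor in Angstrom^2}
#'   \item{element}{element symbol, upper case}
#'   \item{is_hetero}{logical, `TRUE` for HETATM records}
#' }
#'
#' Row order is file order: chains appear in input order and residues within
#' a chain in ascending (res_number, ins_code) order. No operation in the
#' package reorders or renumbers surviving atoms.
#'
#' @param atoms data.frame with the columns listed above.
#' @param metadata named list of free-form metadata (source path, run id...).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, metadata = list()) {
  required <- c("serial", "name", "alt_loc", "res_name", "chain",
                "res_number", "ins_code", "x", "y", "z",
                "occupancy", "b_factor", "element", "is_hetero")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L) {
    stop("atom table is missing columns: ", paste(missing, collapse = ", "))
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0L && any(!is.finite(coords))) {
    stop("atom coordinates must be finite")
  }
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1))) {
    stop("occupancy must lie in [0, 1]")
  }
  atoms$chain <- as.character(atoms$chain)
  atoms$res_number <- as.integer(atoms$res_number)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  ch <- unique(a$chain)
  cat(sprintf("<structure_model> %d atoms, %d residues, %d chain(s): %s\n",
              nrow(a), n_residues(x), length(ch),
              paste(ch, collapse = ", ")))
  invisible(x)
}

#' Number of residues in a model
#'
#' Residues are identified by the (chain, res_number, ins_code) triple.
#'
#' @param model a `structure_model`.
#' @param chain optional chain id to restrict to.
#' @return integer count.
#' @export
n_residues <- function(model, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  nrow(unique(a[, c("chain", "res_number", "ins_code")]))
}

#' Chain identifiers of a model, in order of first appearance
#' @param model a `structure_model`.
#' @return character vector.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Coordinate matrix of a model
#' @param model a `structure_model`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Replace the coordinates of a model
#' @param model a `structure_model`.
#' @param xyz numeric n x 3 matrix.
#' @return the model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

## Residue-level keys: one string per atom identifying its residue.
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$res_number, atoms$ins_code, sep = "|")
}

#' Per-residue summary table
#'
#' One row per residue in atom order, with first/last atom row indices.
#'
#' @param model a `structure_model`.
#' @return data.frame with columns chain, res_number, ins_code, res_name,
#'   n_atoms.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- residue_key(a)
  first <- !duplicated(key)
  out <- a[first, c("chain", "res_number", "ins_code", "res_name")]
  out$n_atoms <- as.integer(table(factor(key, levels = key[first])))
  rownames(out) <- NULL
  out
}

## Logical mask of heavy (non-hydrogen) atoms.
is_heavy <- function(atoms) !(atoms$element %in% c("H", "D"))

## Mask of atoms usable in interface / clash / SASA computations:
## heavy, non-water; heteroatoms excluded unless include_hetero.
geometry_mask <- function(atoms, include_hetero = FALSE) {
  m <- is_heavy(atoms) & !(atoms$res_name %in% c("HOH", "WAT", "DOD"))
  if (!include_hetero) m <- m & !atoms$is_hetero
  m
}

#' Combine several models into one
#'
#' Chains are kept in argument order. Duplicated chain ids across parts are
#' an error; rename first with [rename_chains()].
#'
#' @param ... `structure_model` objects.
#' @return a `structure_model`.
#' @export
combine_models <- function(...) {
  parts <- list(...)
  ids <- unlist(lapply(parts, chain_ids))
  if (anyDuplicated(ids)) {
    stop("duplicate chain ids across parts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  atoms <- do.call(rbind, lapply(parts, function(p) p$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, metadata = parts[[1]]$metadata)
}

#' Rename chains of a model
#' @param model a `structure_model`.
#' @param mapping named character vector, old id -> new id.
#' @return the model with renamed chains.
#' @export
rename_chains <- function(model, mapping) {
  ch <- model$atoms$chain
  hit <- ch %in% names(mapping)
  model$atoms$chain[hit] <- unname(mapping[ch[hit]])
  model
}
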