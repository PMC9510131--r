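## Steric clash detection between two atom groups.
## Criterion: heavy-atom distance < vdW_a + vdW_b - tolerance, with the
## Bondi radii table and a 0.4 A allowed overlap by default (the common
## interactive-graphics convention).

#' Detect steric clashes between two chain groups
#'
#' @param model a [structure_model()].
#' @param group_a,group_b disjoint chain-id sets.
#' @param tolerance allowed vdW overlap in Angstrom.
#' @param include_hetero include heteroatom residues.
#' @return object of class `clash_report`: list with `clash_pairs`
#'   (data.frame: serial_a, serial_b, chain_a, res_number_a, name_a,
#'   chain_b, res_number_b, name_b, distance, allowed), `clash_count` and
#'   `min_distance` (smallest cross-group heavy-atom distance, `Inf` when
#'   either group is empty).
#' @export
detect_clashes <- function(model, group_a, group_b, tolerance = 0.4,
                           include_hetero = FALSE) {
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("chain groups overlap")
  }
  a <- model$atoms[geometry_mask(model$atoms, include_hetero), , drop = FALSE]
  A <- a[a$chain %in% group_a, , drop = FALSE]
  B <- a[a$chain %in% group_b, , drop = FALSE]
  empty <- data.frame(serial_a = integer(0), serial_b = integer(0),
                      chain_a = character(0), res_number_a = integer(0),
                      name_a = character(0), chain_b = character(0),
                      res_number_b = integer(0), name_b = character(0),
                      distance = numeric(0), allowed = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    return(structure(list(clash_pairs = empty, clash_count = 0L,
                          min_distance = Inf), class = "clash_report"))
  }
  ra <- vdw_radius(A$element); rb <- vdw_radius(B$element)
  maxcut <- max(ra) + max(rb) - tolerance
  pairs <- close_atom_pairs(as.matrix(A[, c("x", "y", "z")]),
                            as.matrix(B[, c("x", "y", "z")]),
                            max(maxcut, 0))
  mind <- if (nrow(pairs) > 0L) min(pairs[, 3]) else Inf
  if (nrow(pairs) > 0L) {
    allowed <- ra[pairs[, 1]] + rb[pairs[, 2]] - tolerance
    viol <- pairs[, 3] < allowed
    pairs <- pairs[viol, , drop = FALSE]
    allowed <- allowed[viol]
  } else {
    allowed <- numeric(0)
  }
  cp <- if (nrow(pairs) > 0L) {
    ia <- pairs[, 1]; ib <- pairs[, 2]
    data.frame(serial_a = A$serial[ia], serial_b = B$serial[ib],
               chain_a = A$chain[ia], res_number_a = A$res_number[ia],
               name_a = A$name[ia], chain_b = B$chain[ib],
               res_number_b = B$res_number[ib], name_b = B$name[ib],
               distance = pairs[, 3], allowed = allowed,
               stringsAsFactors = FALSE)
  } else empty
  structure(list(clash_pairs = cp, clash_count = nrow(cp),
                 min_distance = mind),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("<clash_report> %d clashing atom pair(s), min distance %.2f A\n",
              x$clash_count, x$min_distance))
  invisible(x)
}

## Fraction of residues (over both groups) involved in at least one
## cross-group clash; the overlap-artifact statistic of member scoring.
clash_residue_fraction <- function(model, group_a, group_b,
                                   tolerance = 0.4) {
  rep <- detect_clashes(model, group_a, group_b, tolerance = tolerance)
  n_tot <- n_residues(model, chain = c(group_a, group_b))
  if (n_tot == 0L || rep$clash_count == 0L) return(0)
  cp <- rep$clash_pairs
  n_clash <- nrow(unique(rbind(
    data.frame(chain = cp$chain_a, res = cp$res_number_a),
    data.frame(chain = cp$chain_b, res = cp$res_number_b))))
  n_clash / n_tot
}
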