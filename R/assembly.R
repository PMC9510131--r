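## Symmetric rigid-body assembly of a full-length homodimer from two
## partial dimer models sharing a C2 axis: axis detection from the
## monomer-to-monomer superposition, axis alignment, clash-minimal axial
## separation, common dihedral-angle selection, and hybrid open/closed
## composition. Parts are manipulated as rigid bodies throughout.

#' C2 symmetry axis
#'
#' @param direction unit 3-vector.
#' @param point a point on the axis (Angstrom).
#' @param rotation_angle rotation angle in degrees, in (0, 360).
#' @param residual_rmsd superposition residual (Angstrom).
#' @return object of class `symmetry_axis`.
#' @export
symmetry_axis <- function(direction, point, rotation_angle,
                          residual_rmsd = NA_real_) {
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) direction <- direction / nrm
  if (!(rotation_angle > 0 && rotation_angle < 360)) {
    stop("rotation angle must lie in (0, 360) degrees")
  }
  structure(list(direction = as.numeric(direction),
                 point = as.numeric(point),
                 rotation_angle = rotation_angle,
                 residual_rmsd = residual_rmsd),
            class = "symmetry_axis")
}

#' @export
print.symmetry_axis <- function(x, ...) {
  cat(sprintf(
    "<symmetry_axis> angle %.3f deg, direction (%.4f, %.4f, %.4f), residual %.3f A\n",
    x$rotation_angle, x$direction[1], x$direction[2], x$direction[3],
    x$residual_rmsd))
  invisible(x)
}

#' Detect the C2 axis of a homodimer
#'
#' Superposes chain `chain_a` onto chain `chain_b` over sequence-matched
#' Ca positions (Kabsch); the rotation angle comes from the trace of the
#' optimal rotation, the axis direction from its fixed vector, and the
#' axis point from the screw-axis solution. Warns when the angle deviates
#' from 180 degrees by more than 10.
#'
#' @param model the dimer as a [structure_model()].
#' @param chain_a,chain_b the two chain ids (defaults: first two chains).
#' @return a [symmetry_axis()].
#' @export
detect_c2_axis <- function(model, chain_a = NULL, chain_b = NULL) {
  ch <- chain_ids(model)
  if (is.null(chain_a)) chain_a <- ch[1]
  if (is.null(chain_b)) chain_b <- ch[2]
  mc <- matched_ca(model, model, chain_mobile = chain_a,
                   chain_target = chain_b)
  if (mc$n < 3L) {
    stop("need at least 3 matched Ca pairs between chains ", chain_a,
         " and ", chain_b, " (got ", mc$n, ")")
  }
  fit <- kabsch(mc$mobile, mc$target)
  R <- fit$transform$rotation
  tv <- fit$transform$translation
  angle <- rotation_angle_deg(R)
  if (angle < 1) {
    stop("no symmetry axis: monomer-to-monomer rotation is near identity (",
         sprintf("%.2f", angle), " deg)")
  }
  if (abs(angle - 180) > 10) {
    warning(sprintf(
      "rotation angle %.1f deg deviates from 180 by more than 10 deg", angle))
  }
  n <- rotation_axis(R)
  ## screw-axis point: (I - R) p = t_perp, solved by pseudo-inverse
  t_perp <- tv - sum(tv * n) * n
  p <- as.numeric(MASS::ginv(diag(3) - R) %*% t_perp)
  symmetry_axis(n, p, angle, fit$rmsd)
}

#' Rigid transform realising a rotation about an axis line
#' @param axis a [symmetry_axis()] (its `rotation_angle` is ignored).
#' @param angle_deg rotation angle in degrees.
#' @return a [rigid_transform()].
#' @export
axis_rotation_transform <- function(axis, angle_deg) {
  R <- rotation_about_axis(axis$direction, angle_deg)
  rigid_transform(R, axis$point - as.numeric(R %*% axis$point))
}

#' Align the symmetry axis of one part onto another's
#'
#' Rigidly moves `part_b` so that its axis becomes collinear and
#' co-oriented with `axis_a`. The axial position of `part_b` is preserved
#' (only the perpendicular offset is removed); internal geometry is
#' untouched.
#'
#' @param part_a reference part (unused except for its axis; may be NULL).
#' @param axis_a the reference [symmetry_axis()].
#' @param part_b the [structure_model()] to move.
#' @param axis_b its [symmetry_axis()].
#' @return list with `model` (transformed part_b), `transform`, and `axis`
#'   (the common axis, = `axis_a`).
#' @export
align_axes <- function(part_a, axis_a, part_b, axis_b) {
  if (!inherits(axis_a, "symmetry_axis") || !inherits(axis_b, "symmetry_axis")) {
    stop("axes must be detected symmetry_axis objects")
  }
  ## a two-fold axis has no preferred orientation: pick the sign of the
  ## mobile axis that needs the smaller rotation
  nb <- axis_b$direction
  if (sum(nb * axis_a$direction) < 0) nb <- -nb
  R <- rotation_between(nb, axis_a$direction)
  pb_rot <- as.numeric(R %*% axis_b$point)
  delta <- axis_a$point - pb_rot
  delta_perp <- delta - sum(delta * axis_a$direction) * axis_a$direction
  tr <- rigid_transform(R, delta_perp + pb_rot - as.numeric(R %*% axis_b$point))
  ## note: translation leaves the rotated axial coordinate unchanged
  list(model = apply_transform(part_b, tr), transform = tr, axis = axis_a)
}

## Merge two parts, renaming part-b chains that collide with part-a ids.
merge_parts <- function(part_a, part_b) {
  ida <- chain_ids(part_a)
  idb <- chain_ids(part_b)
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)), ida)
  mapping <- character(0)
  newb <- idb
  for (i in seq_along(idb)) {
    if (idb[i] %in% ida || idb[i] %in% newb[seq_len(i - 1L)]) {
      newb[i] <- pool[1]
      pool <- pool[-1]
    } else {
      pool <- setdiff(pool, idb[i])
    }
    mapping[idb[i]] <- newb[i]
  }
  part_b2 <- rename_chains(part_b, mapping)
  model <- combine_models(part_a, part_b2)
  list(model = model, chain_map = mapping,
       groups = list(part_a = ida, part_b = unname(mapping)))
}

#' Smallest clash-free axial separation of two aligned parts
#'
#' Translates `part_b` along the common axis and returns the smallest
#' barycenter separation in the outermost clash-free contiguous interval:
#' the scan starts at a guaranteed clash-free distance (sum of the parts'
#' bounding radii plus a margin) and moves inward in steps of `step`,
#' stopping at the first clash. Scanning inward from the outside guards
#' against clash-free pockets inside interpenetrating configurations.
#' Barycenters are geometric centroids of heavy atoms.
#'
#' @param part_a,part_b [structure_model()]s with axes already aligned on
#'   `axis`.
#' @param axis the common [symmetry_axis()].
#' @param tolerance clash tolerance (Angstrom of allowed vdW overlap).
#' @param step scan step (Angstrom).
#' @return object of class `assembly_result`: `model` (merged, part-b
#'   chains renamed on collision), `separation` (Angstrom), `chain_map`,
#'   `groups`, `clash_report` (zero clashes), `dihedral_angle` (`NA`),
#'   `feasible_arcs` (`NULL`).
#' @export
min_separation <- function(part_a, part_b, axis, tolerance = 0.4,
                           step = 0.1) {
  n <- axis$direction
  ba <- heavy_centroid(part_a)
  bb <- heavy_centroid(part_b)
  ra <- max(sqrt(rowSums(sweep(coords(part_a), 2, ba)^2)))
  rb <- max(sqrt(rowSums(sweep(coords(part_b), 2, bb)^2)))
  s_max <- ra + rb + 5
  s0 <- sum((bb - ba) * n)
  place <- function(s) {
    tr <- rigid_transform(diag(3), (s - s0) * n)
    apply_transform(part_b, tr)
  }
  clash_free <- function(s) {
    mp <- merge_parts(part_a, place(s))
    detect_clashes(mp$model, mp$groups$part_a, mp$groups$part_b,
                   tolerance = tolerance)$clash_count == 0L
  }
  if (!clash_free(s_max)) {
    stop("no clash-free separation within scan bounds (clashes at ",
         sprintf("%.1f", s_max), " A)")
  }
  s_best <- s_max
  s <- s_max - step
  while (s >= 0 - step / 2) {
    s_eval <- max(s, 0)
    if (!clash_free(s_eval)) break
    s_best <- s_eval
    if (s_eval == 0) break
    s <- s - step
  }
  mp <- merge_parts(part_a, place(s_best))
  rep <- detect_clashes(mp$model, mp$groups$part_a, mp$groups$part_b,
                        tolerance = tolerance)
  structure(list(model = mp$model, separation = s_best,
                 chain_map = mp$chain_map, groups = mp$groups,
                 clash_report = rep, dihedral_angle = NA_real_,
                 feasible_arcs = NULL),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly_result> separation %.2f A, dihedral %s, %d clash(es)\n",
              x$separation,
              if (is.na(x$dihedral_angle)) "unset"
              else sprintf("%.1f deg", x$dihedral_angle),
              x$clash_report$clash_count))
  invisible(x)
}

## TRUE-run arcs of a circular feasibility mask over a degree grid.
mask_to_arcs <- function(mask, step) {
  n <- length(mask)
  if (all(mask)) return(list(c(0, 360)))
  if (!any(mask)) return(list())
  ## rotate so the sequence starts on a FALSE, then collect runs
  off <- which(!mask)[1] - 1L
  rot <- mask[((seq_len(n) - 1L + off) %% n) + 1L]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  arcs <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      i0 <- ((starts[k] - 1L + off) %% n) * step
      i1 <- ((ends[k] - 1L + off) %% n) * step
      arcs[[length(arcs) + 1L]] <- c(i0, i1)
    }
  }
  arcs
}

arc_length <- function(arc) {
  if (arc[2] >= arc[1]) arc[2] - arc[1] else 360 - arc[1] + arc[2]
}

arc_midpoint <- function(arc) {
  if (identical(arc, c(0, 360))) return(180)
  (arc[1] + arc_length(arc) / 2) %% 360
}

#' Place a part at a given axial barycenter separation
#'
#' Translates `part_b` along the axis so that the axial component of the
#' barycenter difference (b relative to `part_a`) equals `separation`.
#'
#' @param part_a,part_b [structure_model()]s with aligned axes.
#' @param axis the common [symmetry_axis()].
#' @param separation target axial separation (Angstrom).
#' @return the translated `part_b`.
#' @export
place_at_separation <- function(part_a, part_b, axis, separation) {
  n <- axis$direction
  s0 <- sum((heavy_centroid(part_b) - heavy_centroid(part_a)) * n)
  apply_transform(part_b, rigid_transform(diag(3), (separation - s0) * n))
}

#' Scan the dihedral angle between two stacked partial dimers
#'
#' Rotates each supplied variant of part B about the common axis on a
#' degree grid and records at which angles the assembly is clash-free; the
#' feasible set is the intersection across variants (a single angle must
#' be compatible with every conformational variant, e.g. both the open
#' and the closed configuration). The chosen angle is the midpoint of the
#' largest contiguous feasible arc (by convention 180 for a fully
#' feasible circle starting at 0).
#'
#' @param part_a fixed part.
#' @param part_b_variants a [structure_model()] or list of them, each
#'   already aligned on `axis` at its fixed separation.
#' @param axis the common [symmetry_axis()].
#' @param angular_step grid step in degrees.
#' @param tolerance clash tolerance (Angstrom).
#' @return list with `angle` (chosen, degrees), `feasible_arcs`
#'   (intersection, list of `c(from, to)` degree intervals),
#'   `per_variant_arcs`, and `models` (each variant rotated to the chosen
#'   angle and merged with `part_a`). Errors when the intersection is
#'   empty, with per-variant arcs in the condition message.
#' @export
scan_dihedral <- function(part_a, part_b_variants, axis, angular_step = 1,
                          tolerance = 0.4) {
  if (inherits(part_b_variants, "structure_model")) {
    part_b_variants <- list(part_b_variants)
  }
  grid <- seq(0, 360 - angular_step, by = angular_step)
  masks <- lapply(part_b_variants, function(pb) {
    vapply(grid, function(th) {
      tr <- axis_rotation_transform(axis, th)
      mp <- merge_parts(part_a, apply_transform(pb, tr))
      detect_clashes(mp$model, mp$groups$part_a, mp$groups$part_b,
                     tolerance = tolerance)$clash_count == 0L
    }, TRUE)
  })
  inter <- Reduce(`&`, masks)
  per_variant <- lapply(masks, mask_to_arcs, step = angular_step)
  if (!any(inter)) {
    msg <- paste0(
      "no dihedral angle is feasible for all variants; per-variant arcs: ",
      paste(vapply(per_variant, function(arcs) {
        if (length(arcs) == 0L) return("none")
        paste(vapply(arcs, function(a)
          sprintf("[%g,%g]", a[1], a[2]), ""), collapse = " ")
      }, ""), collapse = " | "))
    cond <- simpleError(msg)
    cond$per_variant_arcs <- per_variant
    stop(cond)
  }
  arcs <- mask_to_arcs(inter, angular_step)
  best <- arcs[[which.max(vapply(arcs, arc_length, 0))]]
  angle <- arc_midpoint(best)
  models <- lapply(part_b_variants, function(pb) {
    tr <- axis_rotation_transform(axis, angle)
    merge_parts(part_a, apply_transform(pb, tr))$model
  })
  list(angle = angle, feasible_arcs = arcs, per_variant_arcs = per_variant,
       models = models)
}

#' Compose a hybrid model from a closed and an open conformation
#'
#' Superposes the open model onto the closed one by least squares
#' restricted to the Ca atoms of `match_domains` (the domains whose
#' geometry is conserved between conformations, e.g. the P450 and FAD
#' domains), then takes one full monomer from the closed model and the
#' other from the superposed open model.
#'
#' @param closed,open [structure_model()]s with shared chain naming.
#' @param match_domains list of [domain_spec()]s defining the fit
#'   selection.
#' @param chain_from_closed chain id taken from the closed model (default:
#'   first chain); every other chain comes from the superposed open model.
#' @return list with `model` (the hybrid), `fit_rmsd` (Angstrom) and
#'   `n_matched_ca`.
#' @export
compose_hybrid <- function(closed, open, match_domains,
                           chain_from_closed = NULL) {
  if (is.null(chain_from_closed)) chain_from_closed <- chain_ids(closed)[1]
  mob <- list(); tgt <- list()
  for (spec in match_domains) {
    if (!spec$chain_id %in% chain_ids(closed) ||
        !spec$chain_id %in% chain_ids(open)) {
      stop("domain '", spec$label, "' chain ", spec$chain_id,
           " missing from one of the models")
    }
    mc <- matched_ca(open, closed, chain_mobile = spec$chain_id,
                     chain_target = spec$chain_id,
                     range = c(spec$start, spec$end))
    if (mc$n == 0L) {
      stop("domain '", spec$label, "' has no matched Ca pairs")
    }
    mob[[length(mob) + 1L]] <- mc$mobile
    tgt[[length(tgt) + 1L]] <- mc$target
  }
  M <- do.call(rbind, mob); T <- do.call(rbind, tgt)
  fit <- kabsch(M, T)
  open_fit <- apply_transform(open, fit$transform)
  other <- setdiff(chain_ids(open), chain_from_closed)
  hybrid <- combine_models(extract_chains(closed, chain_from_closed),
                           extract_chains(open_fit, other))
  list(model = hybrid, fit_rmsd = fit$rmsd, n_matched_ca = nrow(M))
}
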