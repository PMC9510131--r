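## Rigid-body geometry: transforms, Kabsch superposition, matched-Ca
## selection. All rotations are proper (det +1); reflections are never
## produced.

#' Rigid transform
#'
#' `y = R x + t` with `R` a proper rotation.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstrom).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper (det = +1)")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b `rigid_transform` objects.
#' @return the transform equivalent to applying `b` then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tr a `rigid_transform`.
#' @return the inverse transform.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$rotation),
                  -as.numeric(t(tr$rotation) %*% tr$translation))
}

#' Apply a rigid transform
#'
#' @param x a [structure_model()] or an n x 3 coordinate matrix.
#' @param tr a [rigid_transform()].
#' @return object of the same kind as `x`, transformed.
#' @export
apply_transform <- function(x, tr) {
  stopifnot(inherits(tr, "rigid_transform"))
  if (inherits(x, "structure_model")) {
    return(set_coords(x, apply_transform(coords(x), tr)))
  }
  sweep(x %*% t(tr$rotation), 2, tr$translation, `+`)
}

## Rotation angle (degrees) of a rotation matrix, in [0, 180]. atan2 on
## the antisymmetric part keeps full precision near 0 and 180, where
## acos((tr - 1) / 2) loses half the significant digits.
rotation_angle_deg <- function(R) {
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(v^2)) / 2
  c_ <- (sum(diag(R)) - 1) / 2
  atan2(s, c_) * 180 / pi
}

## Rotation axis (unit vector) of a rotation matrix. For angles near 180
## the antisymmetric part vanishes; there (R + I) = 2 n n' + O(pi - angle),
## so the largest column of the symmetrised (R + I) gives the axis to
## machine precision.
rotation_axis <- function(R) {
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(v^2)) > 1e-4) return(v / sqrt(sum(v^2)))
  S <- (R + t(R)) / 2 + diag(3)
  norms <- sqrt(colSums(S^2))
  ax <- S[, which.max(norms)]
  ax / sqrt(sum(ax^2))
}

## Rotation matrix about a unit axis by an angle in degrees (Rodrigues).
rotation_about_axis <- function(axis, angle_deg) {
  n <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Rotation taking unit vector a onto unit vector b (minimal-angle).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## opposite vectors: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- p - sum(p * a) * a
    return(rotation_about_axis(perp, 180))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid transform moving `mobile` onto `target`. Reflections
#' are excluded, so the result is always a proper rotation.
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows.
#' @return list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (Angstrom, over the matched points after superposition).
#' @export
kabsch <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target), nrow(mobile) >= 3)
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- ct - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, t, `+`)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  list(transform = rigid_transform(R, t), rmsd = rmsd)
}

#' Matched C-alpha coordinates of two chains or models
#'
#' Pairs residues by author number (plus insertion code) and returns the two
#' Ca coordinate matrices in matched order. An optional `offset` is added to
#' the mobile numbering before matching.
#'
#' @param mobile,target `structure_model`s.
#' @param chain_mobile,chain_target chain ids (default: first chain each).
#' @param range optional `c(start, end)` restriction (target numbering).
#' @param offset integer added to mobile residue numbers before matching.
#' @return list with matrices `mobile`, `target` and integer `n`.
#' @export
matched_ca <- function(mobile, target,
                       chain_mobile = NULL, chain_target = NULL,
                       range = NULL, offset = 0L) {
  pick <- function(model, chain) {
    a <- model$atoms
    if (is.null(chain)) chain <- a$chain[1]
    a <- a[a$chain == chain & a$name == "CA" & !a$is_hetero, , drop = FALSE]
    a[!duplicated(paste(a$res_number, a$ins_code)), , drop = FALSE]
  }
  am <- pick(mobile, chain_mobile)
  at <- pick(target, chain_target)
  am$match_no <- am$res_number + as.integer(offset)
  if (!is.null(range)) {
    at <- at[at$res_number >= range[1] & at$res_number <= range[2], ,
             drop = FALSE]
  }
  common <- intersect(am$match_no, at$res_number)
  am <- am[match(common, am$match_no), , drop = FALSE]
  at <- at[match(common, at$res_number), , drop = FALSE]
  list(mobile = as.matrix(am[, c("x", "y", "z")]),
       target = as.matrix(at[, c("x", "y", "z")]),
       n = length(common))
}

## Geometric centroid of heavy atoms (the "barycenter" used throughout
## assembly; geometric, not mass-weighted).
heavy_centroid <- function(model) {
  a <- model$atoms[geometry_mask(model$atoms, include_hetero = TRUE), ,
                   drop = FALSE]
  colMeans(as.matrix(a[, c("x", "y", "z")]))
}
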