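## Solvent-accessible surface area by the Shrake-Rupley method.
## Deterministic for a fixed sphere-point count: test points are a golden-
## spiral (Fibonacci) lattice, not random samples.

## n approximately evenly spaced points on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes SASA over the heavy atoms of the model (hydrogens, waters and
#' - by default - heteroatoms are excluded) and normalises per residue by
#' the Tien et al. theoretical maximum for the residue type.
#'
#' @param model a [structure_model()].
#' @param probe_radius probe sphere radius in Angstrom (water: 1.4).
#' @param n_points number of test points per atom; deterministic lattice.
#' @param include_hetero include heteroatom residues in the computation.
#' @return data.frame with one row per residue: chain, res_number, ins_code,
#'   res_name, sasa (A^2) and rel_sasa (fraction of the residue-type
#'   maximum; `NA` for residue types without a tabulated maximum).
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 240,
                         include_hetero = FALSE) {
  a <- model$atoms[geometry_mask(model$atoms, include_hetero), , drop = FALSE]
  if (nrow(a) == 0L) stop("model has no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdw_radius(a$element) + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(a)
  exposed <- numeric(n)
  ## neighbour search on a cheap grid of axis-sorted candidates
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + maxr)^2)
    nb <- nb[nb != i]
    nb <- nb[d2[nb] < (rad[i] + rad[nb])^2]
    test <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0L) {
      exposed[i] <- n_points
    } else {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
          (test[, 3] - xyz[j, 3])^2
        free <- free & (dj >= rad[j]^2)
      }
      exposed[i] <- sum(free)
    }
  }
  atom_sasa <- 4 * pi * rad^2 * exposed / n_points
  key <- residue_key(a)
  first <- !duplicated(key)
  res <- a[first, c("chain", "res_number", "ins_code", "res_name")]
  res$sasa <- as.numeric(tapply(atom_sasa, factor(key, levels = key[first]),
                                sum))
  res$rel_sasa <- res$sasa / unname(.max_asa[toupper(res$res_name)])
  rownames(res) <- NULL
  res
}

#' Non-interacting-surface composition of a complex
#'
#' Surface residues are those with relative SASA above `threshold`,
#' computed on the complex (interface residues buried on complexation drop
#' out naturally). Reports the percentage of apolar and charged residues
#' among them - the NIS terms of the contact-based binding-energy model.
#'
#' @param model the complex as a [structure_model()].
#' @param threshold relative-SASA cutoff defining surface residues.
#' @param sasa optional precomputed result of [compute_sasa()].
#' @param ... passed to [compute_sasa()].
#' @return object of class `nis_profile`: list with `pct_apolar`,
#'   `pct_charged`, `n_surface_residues`.
#' @export
nis_profile <- function(model, threshold = 0.05, sasa = NULL, ...) {
  if (is.null(sasa)) sasa <- compute_sasa(model, ...)
  cls <- residue_class(sasa$res_name)
  surf <- !is.na(sasa$rel_sasa) & sasa$rel_sasa > threshold & !is.na(cls)
  n <- sum(surf)
  out <- list(
    pct_apolar = if (n > 0) 100 * sum(cls[surf] == "apolar") / n else 0,
    pct_charged = if (n > 0) 100 * sum(cls[surf] == "charged") / n else 0,
    n_surface_residues = n)
  class(out) <- "nis_profile"
  out
}

#' @export
print.nis_profile <- function(x, ...) {
  cat(sprintf("<nis_profile> %d surface residues: %.1f%% apolar, %.1f%% charged\n",
              x$n_surface_residues, x$pct_apolar, x$pct_charged))
  invisible(x)
}
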