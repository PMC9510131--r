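## Synthetic structure generator.
##
## Produces dimers and prediction ensembles with known ground truth so the
## whole toolkit is testable without downloading anything. Domains are
## ideal poly-residue alpha-helices (parametric Ca helix with backbone and
## Cb pseudo-atoms) or Gaussian atom blobs - cheap, fully controlled
## geometry with no pretence of biological realism beyond what the
## geometric and energetic oracles need.
##
## The default helix sequence cycles through a 20-residue motif whose
## composition (60% apolar, 25% charged, 15% polar) mirrors a typical
## protein surface, so that the contact-based dG of two separated chains
## lands near zero (no-complex by the 3 kcal/mol rule) while a genuine
## packed interface scores as a complex.

## Charged and polar residues sit in the first half so that the
## palindromic ladder pairing (residue i against n+1-i) of two facing
## strands yields mostly charged/apolar and polar/apolar contacts, the
## classes the dG model weights.
.fixture_cycle <- c("GLU", "LYS", "ASP", "ARG", "GLU", "SER", "THR",
                    "ASN", "LEU", "ALA", "VAL", "ILE", "LEU", "ALA",
                    "VAL", "ILE", "LEU", "ALA", "VAL", "ILE")

## Run code with a private RNG stream; the caller's RNG state is restored.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Fixture specification
#'
#' Parameters of the synthetic C2 dimer generators. `separation` is the
#' distance between the two monomer helix axes across the symmetry axis
#' (it controls the interface spacing), `dihedral` the azimuth of monomer
#' A around the axis, and `noise_sigma` the per-atom isotropic Gaussian
#' noise applied after the symmetric construction (ground truth refers to
#' the noiseless frame).
#'
#' @param n_residues_per_domain residues per domain helix/blob.
#' @param geometry `"helix"` or `"blob"`.
#' @param axis_direction planted C2 axis direction (unit vector).
#' @param axis_point a point on the planted axis.
#' @param separation monomer axis-to-axis distance (Angstrom).
#' @param dihedral azimuth of monomer A around the axis (degrees).
#' @param noise_sigma per-atom Gaussian noise (Angstrom).
#' @param seed integer; fixes all randomness.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues_per_domain = 20L, geometry = "helix",
                         axis_direction = c(0, 0, 1),
                         axis_point = c(0, 0, 0),
                         separation = if (geometry == "strand") 7.5 else 13,
                         dihedral = 0, noise_sigma = 0, seed = 1L) {
  stopifnot(noise_sigma >= 0)
  geometry <- match.arg(geometry, c("helix", "blob", "strand"))
  structure(list(n_residues_per_domain = as.integer(n_residues_per_domain),
                 geometry = geometry,
                 axis_direction = axis_direction / sqrt(sum(axis_direction^2)),
                 axis_point = as.numeric(axis_point),
                 separation = separation, dihedral = dihedral,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fixture_spec")
}

## Atom rows for one residue at given positions (named list of xyz).
residue_atoms <- function(res_name, chain, res_number, positions) {
  el <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  data.frame(serial = 0L, name = names(positions), alt_loc = "",
             res_name = res_name, chain = chain,
             res_number = as.integer(res_number), ins_code = "",
             x = vapply(positions, `[`, 0, 1),
             y = vapply(positions, `[`, 0, 2),
             z = vapply(positions, `[`, 0, 3),
             occupancy = 1, b_factor = 0,
             element = unname(el[names(positions)]), is_hetero = FALSE,
             stringsAsFactors = FALSE)
}

#' Ideal helical chain fixture
#'
#' Parametric alpha-helix: Ca on a 2.3 A radius helix with 1.5 A rise and
#' 100 degrees twist per residue around `axis` (default z) through
#' `origin`; N, C, O and Cb pseudo-atoms are placed in the local frame (5
#' atoms per residue).
#'
#' @param n_res number of residues.
#' @param chain chain id.
#' @param start_res author number of the first residue.
#' @param origin base point of the helix axis.
#' @param axis helix axis direction.
#' @param sequence vector of 3-letter codes recycled along the chain
#'   (default: the package's mixed-composition 20-cycle); `"ALA"` gives a
#'   poly-alanine helix.
#' @param phase azimuthal phase in degrees.
#' @return a [structure_model()].
#' @export
make_helix_chain <- function(n_res, chain = "A", start_res = 1L,
                             origin = c(0, 0, 0), axis = c(0, 0, 1),
                             sequence = .fixture_cycle, phase = 0) {
  n_res <- as.integer(n_res)
  seqv <- rep_len(sequence, n_res)
  i <- seq_len(n_res) - 1L
  th <- (phase + 100 * i) * pi / 180
  r <- 2.3; rise <- 1.5
  ca <- cbind(r * cos(th), r * sin(th), rise * i)
  u <- cbind(cos(th), sin(th), 0)              # radial, outward
  tg <- cbind(-sin(th), cos(th), 0)            # tangential
  ax <- matrix(c(0, 0, 1), n_res, 3, byrow = TRUE)
  tdir <- 0.55 * tg + 0.83 * ax                # along-chain direction
  rows <- lapply(seq_len(n_res), function(k) {
    pos <- list(N = ca[k, ] - 1.46 * tdir[k, ],
                CA = ca[k, ],
                C = ca[k, ] + 1.52 * tdir[k, ],
                O = ca[k, ] + 1.52 * tdir[k, ] + 1.23 * u[k, ],
                CB = ca[k, ] + 1.53 * u[k, ])
    residue_atoms(seqv[k], chain, start_res + k - 1L, pos)
  })
  atoms <- do.call(rbind, rows)
  ## move from canonical frame (z axis through origin 0) to requested frame
  R <- rotation_between(c(0, 0, 1), axis)
  xyz <- sweep(as.matrix(atoms[, c("x", "y", "z")]) %*% t(R), 2, origin, `+`)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, metadata = list(fixture = "helix"))
}

#' Gaussian blob chain fixture
#'
#' `n_res` single-Ca pseudo-residues drawn from an isotropic Gaussian.
#'
#' @param n_res number of residues.
#' @param chain chain id.
#' @param start_res author number of the first residue.
#' @param center blob centre.
#' @param sd spatial standard deviation (Angstrom).
#' @param sequence 3-letter codes recycled along the chain.
#' @param seed RNG seed.
#' @return a [structure_model()].
#' @export
make_blob_chain <- function(n_res, chain = "A", start_res = 1L,
                            center = c(0, 0, 0), sd = 4,
                            sequence = .fixture_cycle, seed = 1L) {
  n_res <- as.integer(n_res)
  xyz <- with_seed(seed, matrix(stats::rnorm(3 * n_res, sd = sd), ncol = 3))
  xyz <- sweep(xyz, 2, center, `+`)
  seqv <- rep_len(sequence, n_res)
  rows <- lapply(seq_len(n_res), function(k) {
    residue_atoms(seqv[k], chain, start_res + k - 1L,
                  list(CA = xyz[k, ]))
  })
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, metadata = list(fixture = "blob"))
}

#' Straight beta-strand-like chain fixture
#'
#' Residues stacked along y with a 3.8 A step; backbone N/C/O near the Ca
#' column and a single Cb pseudo-atom pointing along `cb_sign * x`. Two
#' such strands facing each other form a fully controlled contact ladder:
#' with Ca columns `d` apart, facing Cb atoms meet at `d - 3.06` A, so
#' interface spacing is set exactly by construction - the workhorse of the
#' energetics, arbitration and topology fixtures.
#'
#' @param n_res number of residues.
#' @param chain chain id.
#' @param start_res author number of the first residue.
#' @param x0 x position of the Ca column.
#' @param cb_sign +1 or -1: side the Cb atoms point to.
#' @param y_center centre of the strand along y.
#' @param sequence 3-letter codes recycled along the chain.
#' @return a [structure_model()].
#' @export
make_strand_chain <- function(n_res, chain = "A", start_res = 1L, x0 = 0,
                              cb_sign = 1, y_center = 0,
                              sequence = .fixture_cycle) {
  n_res <- as.integer(n_res)
  seqv <- rep_len(sequence, n_res)
  y0 <- y_center - 3.8 * (n_res - 1) / 2
  rows <- lapply(seq_len(n_res), function(k) {
    ca <- c(x0, y0 + 3.8 * (k - 1), 0)
    pos <- list(N = ca + c(0, -1.2, 0.6),
                CA = ca,
                C = ca + c(0, 1.2, 0.6),
                O = ca + c(0, 1.2, 1.83),
                CB = ca + c(cb_sign * 1.53, 0, 0))
    residue_atoms(seqv[k], chain, start_res + k - 1L, pos)
  })
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, metadata = list(fixture = "strand"))
}

## Rigid transform from the canonical frame (C2 axis = z through origin)
## to the planted frame of a fixture_spec.
planted_frame_transform <- function(spec) {
  R <- rotation_between(c(0, 0, 1), spec$axis_direction)
  rigid_transform(R, spec$axis_point)
}

add_noise <- function(model, sigma) {
  if (sigma <= 0) return(model)
  xyz <- coords(model)
  set_coords(model, xyz + matrix(stats::rnorm(length(xyz), sd = sigma),
                                 ncol = 3))
}

#' Synthetic C2 homodimer with known axis
#'
#' Chain A is an L-shaped double helix (geometry `"helix"`; residues
#' 1..2n), a Gaussian blob, or a single facing strand (geometry
#' `"strand"`, which gives the dimer a contact-ladder interface), offset
#' by `separation / 2` from the planted axis; chain B is its exact
#' 180-degree rotation about that axis. Gaussian noise of `noise_sigma`
#' is applied afterwards, so the returned ground-truth axis refers to the
#' noiseless construction.
#'
#' @param spec a [fixture_spec()].
#' @return list with `model` (a two-chain [structure_model()]), `axis`
#'   (ground-truth [symmetry_axis()]) and `spec`.
#' @export
make_c2_dimer <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues_per_domain
  half <- spec$separation / 2
  off <- c(half, 0, 0)
  ## the helix monomer is L-shaped (a vertical arm along the axis plus a
  ## perpendicular arm pointing away from it): a single straight helix is
  ## essentially one-dimensional, which leaves the rotation about its own
  ## line - and hence the recovered C2 angle - unobservable under noise
  a <- switch(spec$geometry,
    helix = {
      arm1 <- make_helix_chain(n, chain = "A", origin = off)
      arm2 <- make_helix_chain(n, chain = "A", start_res = n + 1L,
                               origin = off + c(3, 0, 1.5 * (n - 1) + 2),
                               axis = c(1, 0, 0))
      atoms <- rbind(arm1$atoms, arm2$atoms)
      atoms$serial <- seq_len(nrow(atoms))
      structure_model(atoms)
    },
    blob = make_blob_chain(n, chain = "A", center = off,
                           seed = spec$seed + 1L),
    strand = make_strand_chain(n, chain = "A", x0 = -half, cb_sign = 1))
  if (spec$dihedral != 0) {
    a <- apply_transform(a, rigid_transform(
      rotation_about_axis(c(0, 0, 1), spec$dihedral), c(0, 0, 0)))
  }
  rot <- rotation_about_axis(c(0, 0, 1), 180)
  b <- set_coords(a, coords(a) %*% t(rot))
  b$atoms$chain <- "B"
  dimer <- combine_models(a, b)
  dimer <- apply_transform(dimer, planted_frame_transform(spec))
  dimer <- with_seed(spec$seed, add_noise(dimer, spec$noise_sigma))
  axis <- symmetry_axis(spec$axis_direction, spec$axis_point, 180, 0)
  list(model = dimer, axis = axis, spec = spec)
}

#' Synthetic two-chain, two-domain dimer with planted topology
#'
#' Each chain carries a partner domain (label `"FADd"` for
#' crossed/closed, `"P450d"` for cis/trans) and a mobile `"FMNd"` domain.
#' The two partner domains face each other across the C2 axis at
#' `separation`; each mobile domain is packed against the partner domain
#' dictated by `label` (own chain for closed/cis, other chain for
#' crossed/trans) at an interface spacing giving heavy-atom contacts
#' around 4-5.5 A with no steric clash. Chain B is the exact C2 image of
#' chain A.
#'
#' @param label `"crossed"`, `"closed"`, `"cis"` or `"trans"`.
#' @param spec a [fixture_spec()]; `n_residues_per_domain`, axis
#'   placement, `noise_sigma` and `seed` are honoured.
#' @return list with `model`, `domains` (list of [domain_spec()]s),
#'   `axis`, `label`, `partner_label`.
#' @export
make_topology_dimer <- function(label = c("crossed", "closed", "cis",
                                          "trans"),
                                spec = fixture_spec()) {
  label <- match.arg(label)
  partner_label <- if (label %in% c("cis", "trans")) "P450d" else "FADd"
  intra <- label %in% c("closed", "cis")
  n <- spec$n_residues_per_domain
  ## canonical frame: C2 axis = z. Partner strands face each other across
  ## the axis at x = -/+ 3.75 (Cb ladder at 4.44 A: the partner-partner
  ## interface present in every geometry). The mobile strand docks its Cb
  ## face onto the outer backbone face of its designated partner at a
  ## 4.5 A gap; chain B is the C2 image, so mobiles end up ~20 A apart.
  half <- 3.75
  dock <- 4.5
  partner_a <- make_strand_chain(n, chain = "A", start_res = 1L,
                                 x0 = -half, cb_sign = 1)
  mob_x <- if (intra) -(half + dock + 1.53) else (half + dock + 1.53)
  mobile_a <- make_strand_chain(n, chain = "A", start_res = 101L,
                                x0 = mob_x, cb_sign = if (intra) 1 else -1)
  ## same chain id for both domains, so bind rows directly
  atoms_a <- rbind(partner_a$atoms, mobile_a$atoms)
  atoms_a$serial <- seq_len(nrow(atoms_a))
  chain_a <- structure_model(atoms_a)
  rot <- rotation_about_axis(c(0, 0, 1), 180)
  chain_b <- set_coords(chain_a, coords(chain_a) %*% t(rot))
  chain_b$atoms$chain <- "B"
  model <- combine_models(chain_a, chain_b)
  model <- apply_transform(model, planted_frame_transform(spec))
  model <- with_seed(spec$seed, add_noise(model, spec$noise_sigma))
  domains <- list(
    domain_spec(partner_label, "A", 1L, n),
    domain_spec(partner_label, "B", 1L, n),
    domain_spec("FMNd", "A", 101L, 100L + n),
    domain_spec("FMNd", "B", 101L, 100L + n))
  axis <- symmetry_axis(spec$axis_direction, spec$axis_point, 180, 0)
  list(model = model, domains = domains, axis = axis, label = label,
       partner_label = partner_label)
}

## Non-interacting member: the two chains of a topology dimer pulled
## 100 A apart along the axis.
make_apart_dimer <- function(spec = fixture_spec()) {
  td <- make_topology_dimer("closed", spec)
  m <- td$model
  sel <- m$atoms$chain == "B"
  shift <- 100 * spec$axis_direction
  m$atoms$x[sel] <- m$atoms$x[sel] + shift[1]
  m$atoms$y[sel] <- m$atoms$y[sel] + shift[2]
  m$atoms$z[sel] <- m$atoms$z[sel] + shift[3]
  td$model <- m
  td$label <- "none"
  td
}

## Overlap-artifact member: chain B co-centred on chain A.
make_overlap_dimer <- function(spec = fixture_spec()) {
  td <- make_topology_dimer("closed", spec)
  m <- td$model
  a <- m$atoms
  sel <- a$chain == "B"
  delta <- colMeans(as.matrix(a[!sel, c("x", "y", "z")])) -
    colMeans(as.matrix(a[sel, c("x", "y", "z")]))
  a$x[sel] <- a$x[sel] + delta[1]
  a$y[sel] <- a$y[sel] + delta[2]
  a$z[sel] <- a$z[sel] + delta[3]
  td$model <- structure_model(a)
  td$label <- "overlap"
  td
}

#' Ensemble specification
#'
#' @param n_runs number of prediction runs to emulate.
#' @param proportions named fractions over geometry labels (names from
#'   `"crossed"`, `"closed"`, `"cis"`, `"trans"`, `"none"`, `"overlap"`);
#'   must sum to 1. Counts are rounded with largest-remainder correction.
#' @param seed integer seed.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_runs = 10L, proportions = c(crossed = 0.8,
                                                        closed = 0.2),
                          seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must sum to 1")
  }
  ok <- c("crossed", "closed", "cis", "trans", "none", "overlap")
  if (!all(names(proportions) %in% ok)) {
    stop("unknown geometry label(s): ",
         paste(setdiff(names(proportions), ok), collapse = ", "))
  }
  structure(list(n_runs = as.integer(n_runs), proportions = proportions,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

## Integer counts from fractions by the largest-remainder method.
largest_remainder_counts <- function(proportions, n) {
  exact <- proportions * n
  counts <- floor(exact)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Synthetic prediction ensemble with planted geometry proportions
#'
#' Generates `n_runs` members whose geometry labels follow the
#' largest-remainder counts of `proportions`; each member gets
#' per-member Gaussian coordinate jitter (seeded from `espec$seed` and
#' the run id), so members of one geometry share their contact set up to
#' noise.
#'
#' @param espec an [ensemble_spec()].
#' @param base a [fixture_spec()]; its `noise_sigma` (default here 0.3)
#'   is the per-member jitter.
#' @return list with `members` (list of [ensemble_member()]s), `truth`
#'   (character vector of planted labels by run) and `counts`.
#' @export
make_ensemble <- function(espec = ensemble_spec(),
                          base = fixture_spec(noise_sigma = 0.3)) {
  counts <- largest_remainder_counts(espec$proportions, espec$n_runs)
  labels <- rep(names(espec$proportions), counts)
  members <- vector("list", espec$n_runs)
  for (i in seq_len(espec$n_runs)) {
    mspec <- base
    mspec$seed <- espec$seed * 1000L + i
    td <- switch(labels[i],
                 none = make_apart_dimer(mspec),
                 overlap = make_overlap_dimer(mspec),
                 make_topology_dimer(labels[i], mspec))
    ptm <- with_seed(mspec$seed + 500L, stats::runif(1, 0.4, 0.9))
    members[[i]] <- ensemble_member(td$model, run_id = i, ptm_score = ptm)
  }
  list(members = members, truth = labels,
       counts = stats::setNames(counts, names(espec$proportions)))
}

#' Toy cofactor reference structure
#'
#' A 30-residue helix domain (chain A, residues 1-30) with a small planar
#' 4-atom hetero group (`HEM`-like: Fe, N, C, O) packed against it - a
#' synthetic stand-in for a crystal reference used in cofactor grafting
#' tests.
#'
#' @param n_res helix length.
#' @return a [structure_model()] with protein and hetero atoms.
#' @export
make_cofactor_reference <- function(n_res = 30L) {
  prot <- make_helix_chain(n_res, chain = "A")
  fe <- c(7.6, 0, 10)
  het <- data.frame(
    serial = 0L,
    name = c("FE", "NA", "C1", "O1"),
    alt_loc = "", res_name = "HEM", chain = "A",
    res_number = 900L, ins_code = "",
    x = c(fe[1], fe[1] + 2.0, fe[1] + 1.0, fe[1] - 1.0),
    y = c(fe[2], fe[2], fe[2] + 1.8, fe[2] - 1.8),
    z = fe[3],
    occupancy = 1, b_factor = 0,
    element = c("FE", "N", "C", "O"), is_hetero = TRUE,
    stringsAsFactors = FALSE)
  atoms <- rbind(prot$atoms, het)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, metadata = list(fixture = "cofactor_reference"))
}

#' Random carrier sequence with a motif planted at an author position
#'
#' Builds a deterministic random sequence of length `total_length` whose
#' substring starting at author position `position` is exactly `motif`,
#' and in which the motif occurs nowhere else. Used as a synthetic
#' stand-in for full-length sequences when only the motif neighbourhood
#' is specified.
#'
#' @param motif one-letter motif string.
#' @param position author position (1-based) of the motif start.
#' @param total_length total sequence length.
#' @param id record id.
#' @param seed RNG seed.
#' @return a [sequence_record()].
#' @export
make_motif_sequence <- function(motif, position, total_length,
                                id = "synthetic", seed = 1L) {
  motif <- toupper(motif)
  stopifnot(position >= 1L,
            position + nchar(motif) - 1L <= total_length)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (attempt in 0:99) {
    s <- with_seed(seed + attempt * 7919L,
                   paste(sample(aa, total_length, replace = TRUE),
                         collapse = ""))
    s <- paste0(substr(s, 1, position - 1L), motif,
                substr(s, position + nchar(motif), total_length))
    hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
    if (length(hits) == 1L && hits[1] == position) {
      return(sequence_record(id, s))
    }
  }
  stop("could not plant motif uniquely")   # practically unreachable
}
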