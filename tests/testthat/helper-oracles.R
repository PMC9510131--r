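# Brute-force oracles, written independently of the package internals:
# plain double loops, no neighbour pruning, no blocking. Deliberately slow
# and simple so they can arbitrate the optimised implementations.

# Heavy protein atoms of a model as a plain data.frame.
oracle_atoms <- function(model, chains = NULL, include_hetero = FALSE) {
  a <- model$atoms
  a <- a[!(a$element %in% c("H", "D")) & !(a$res_name %in% c("HOH", "WAT")), ]
  if (!include_hetero) a <- a[!a$is_hetero, ]
  if (!is.null(chains)) a <- a[a$chain %in% chains, ]
  a
}

# Residue-pair contacts by an O(N^2) atom scan.
oracle_contacts <- function(model, group_a, group_b, cutoff = 5.5) {
  A <- oracle_atoms(model, group_a)
  B <- oracle_atoms(model, group_b)
  best <- new.env()
  for (i in seq_len(nrow(A))) {
    dx <- B$x - A$x[i]; dy <- B$y - A$y[i]; dz <- B$z - A$z[i]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    hit <- which(d <= cutoff)
    for (j in hit) {
      key <- paste(A$chain[i], A$res_number[i], A$ins_code[i],
                   B$chain[j], B$res_number[j], B$ins_code[j], sep = "|")
      old <- best[[key]]
      if (is.null(old) || d[j] < old) best[[key]] <- d[j]
    }
  }
  keys <- ls(best)
  if (length(keys) == 0L) {
    return(data.frame(key = character(0), distance = numeric(0)))
  }
  data.frame(key = keys,
             distance = vapply(keys, function(k) best[[k]], 0),
             row.names = NULL)
}

# Contact keys of package output in the oracle's format, for comparison.
package_contact_keys <- function(contacts) {
  if (nrow(contacts) == 0L) return(character(0))
  sort(paste(contacts$chain_a, contacts$res_number_a, contacts$ins_code_a,
             contacts$chain_b, contacts$res_number_b, contacts$ins_code_b,
             sep = "|"))
}

# Clashing atom pairs by an O(N^2) scan with the Bondi criterion.
oracle_clash_count <- function(model, group_a, group_b, tolerance = 0.4,
                               include_hetero = FALSE) {
  A <- oracle_atoms(model, group_a, include_hetero)
  B <- oracle_atoms(model, group_b, include_hetero)
  ra <- vdw_radius(A$element); rb <- vdw_radius(B$element)
  count <- 0L
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B$x - A$x[i])^2 + (B$y - A$y[i])^2 + (B$z - A$z[i])^2)
    count <- count + sum(d < ra[i] + rb - tolerance)
  }
  count
}

# Shrake-Rupley without any pruning: every atom checked against every
# other atom for every sphere point. Same deterministic lattice definition
# as the package but written out independently.
oracle_sasa <- function(model, probe = 1.4, n_points = 960) {
  a <- oracle_atoms(model)
  rad <- vdw_radius(a$element) + probe
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  th <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  n <- nrow(a)
  sasa_atom <- numeric(n)
  for (k in seq_len(n)) {
    test <- pts * rad[k]
    test[, 1] <- test[, 1] + a$x[k]
    test[, 2] <- test[, 2] + a$y[k]
    test[, 3] <- test[, 3] + a$z[k]
    free <- rep(TRUE, n_points)
    for (m in seq_len(n)) {
      if (m == k) next
      d2 <- (test[, 1] - a$x[m])^2 + (test[, 2] - a$y[m])^2 +
        (test[, 3] - a$z[m])^2
      free <- free & (d2 >= rad[m]^2)
    }
    sasa_atom[k] <- 4 * pi * rad[k]^2 * mean(free)
  }
  key <- paste(a$chain, a$res_number, a$ins_code, sep = "|")
  tapply(sasa_atom, key, sum)
}

# Independent dG arithmetic from published coefficients (plain formula,
# no package code).
oracle_dg <- function(ic_cc, ic_ca, ic_pp, ic_pa, pct_apolar, pct_charged) {
  -0.09459 * ic_cc - 0.10007 * ic_ca + 0.19577 * ic_pp -
    0.22671 * ic_pa + 0.18681 * pct_apolar + 0.13810 * pct_charged -
    15.9433
}

# Jaccard similarity of two contact-key sets.
oracle_jaccard <- function(s1, s2) {
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  inter <- length(intersect(s1, s2))
  inter / (length(s1) + length(s2) - inter)
}

# Single-atom "part": one Ca pseudo-residue at a point.
one_atom_part <- function(chain, pos, res_number = 1L) {
  structure_model(data.frame(
    serial = 1L, name = "CA", alt_loc = "", res_name = "ALA",
    chain = chain, res_number = as.integer(res_number), ins_code = "",
    x = pos[1], y = pos[2], z = pos[3], occupancy = 1, b_factor = 0,
    element = "C", is_hetero = FALSE, stringsAsFactors = FALSE))
}

# Ring of single-atom residues in the z = z0 plane, optionally with an
# azimuthal gap (degrees).
ring_part <- function(chain, radius, z0, every = 5, gap = NULL) {
  az <- seq(0, 355, by = every)
  if (!is.null(gap)) az <- az[az < gap[1] | az > gap[2]]
  atoms <- do.call(rbind, lapply(seq_along(az), function(k) {
    th <- az[k] * pi / 180
    data.frame(serial = k, name = "CA", alt_loc = "", res_name = "ALA",
               chain = chain, res_number = k, ins_code = "",
               x = radius * cos(th), y = radius * sin(th), z = z0,
               occupancy = 1, b_factor = 0, element = "C",
               is_hetero = FALSE, stringsAsFactors = FALSE)
  }))
  structure_model(atoms)
}

z_axis <- function() symmetry_axis(c(0, 0, 1), c(0, 0, 0), 180, 0)

angle_between_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
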