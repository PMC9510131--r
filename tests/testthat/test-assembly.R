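test_that("C2 axis detection is exact on noiseless fixtures", {
  spec <- fixture_spec(axis_direction = c(0.2, -0.5, 0.84),
                      axis_point = c(3, -1, 2), seed = 1)
  fx <- make_c2_dimer(spec)
  ax <- detect_c2_axis(fx$model)
  expect_equal(ax$rotation_angle, 180, tolerance = 1e-6)
  expect_lt(angle_between_deg(ax$direction, fx$axis$direction), 1e-4)
  expect_lt(ax$residual_rmsd, 1e-6)

  ## the detected 180-degree transform applied twice is the identity
  tr <- axis_rotation_transform(ax, ax$rotation_angle)
  twice <- compose_transforms(tr, tr)
  xyz <- coords(fx$model)
  expect_lt(max(abs(apply_transform(xyz, twice) - xyz)), 1e-6)

  ## and it maps chain A onto chain B
  a <- extract_chains(fx$model, "A"); b <- extract_chains(fx$model, "B")
  expect_lt(max(abs(apply_transform(coords(a), tr) - coords(b))), 1e-6)
})

test_that("C2 axis recovery is accurate under noise across 20 seeds", {
  errs <- vapply(1:20, function(s) {
    fx <- make_c2_dimer(fixture_spec(noise_sigma = 0.2, seed = s))
    ax <- detect_c2_axis(fx$model)
    angle_between_deg(ax$direction, fx$axis$direction)
  }, 0)
  expect_lt(mean(errs), 0.5)
  expect_true(all(errs < 0.5))
  ## angle error bound at the stronger noise level; a larger fixture is
  ## used because the angle estimate, unlike the direction, improves only
  ## with the number of matched Ca pairs
  aerr <- vapply(1:20, function(s) {
    fx <- make_c2_dimer(fixture_spec(n_residues_per_domain = 40,
                                     noise_sigma = 0.3, seed = 100 + s))
    abs(detect_c2_axis(fx$model)$rotation_angle - 180)
  }, 0)
  expect_true(all(aerr < 0.5))
})

test_that("axis detection rejects degenerate inputs", {
  fx <- make_c2_dimer(fixture_spec(n_residues_per_domain = 2, seed = 1))
  ## 2 residues -> >= 3 matched Ca needed
  two <- structure_model(fx$model$atoms[fx$model$atoms$name == "CA", ][1:4, ])
  expect_error(detect_c2_axis(two), "matched Ca")
  ## identical chains (no rotation) -> no axis
  a <- make_strand_chain(10, chain = "A")
  b <- a; b$atoms$chain <- "B"
  expect_error(detect_c2_axis(combine_models(a, b)), "near identity")
})

test_that("align_axes makes axes collinear without deforming the part", {
  p1 <- make_c2_dimer(fixture_spec(seed = 1))$model
  p2 <- make_c2_dimer(fixture_spec(axis_direction = c(0.6, 0.64, 0.48),
                                   axis_point = c(8, -4, 1), seed = 2))$model
  ax1 <- detect_c2_axis(p1); ax2 <- detect_c2_axis(p2)
  al <- align_axes(p1, ax1, p2, ax2)
  ax2b <- detect_c2_axis(al$model)
  expect_lt(angle_between_deg(ax2b$direction, ax1$direction), 1e-4)
  ## axis points coincide up to the axial component
  dp <- ax2b$point - ax1$point
  perp <- dp - sum(dp * ax1$direction) * ax1$direction
  expect_lt(sqrt(sum(perp^2)), 1e-4)
  ## rigidity: pairwise distances unchanged
  i <- seq(1, nrow(p2$atoms), by = 7)
  expect_lt(max(abs(dist(coords(p2)[i, ]) - dist(coords(al$model)[i, ]))),
            1e-6)
  ## aligning an already aligned part is the identity
  al2 <- align_axes(p1, ax1, al$model, ax2b)
  expect_lt(max(abs(coords(al2$model) - coords(al$model))), 1e-4)
})

test_that("min_separation finds the analytic solution for single atoms", {
  a <- one_atom_part("A", c(0, 0, 0))
  b <- one_atom_part("B", c(0, 0, 1))
  ## two carbons: clash below 1.7 + 1.7 - 0.4 = 3.0 A
  asm <- min_separation(a, b, z_axis(), tolerance = 0.4, step = 0.1)
  expect_lt(abs(asm$separation - 3.0), 0.1 + 1e-9)
  expect_equal(asm$clash_report$clash_count, 0L)

  ## parts clash-free at every separation stay at 0
  b_off <- one_atom_part("B", c(10, 0, 5))
  asm0 <- min_separation(a, b_off, z_axis())
  expect_equal(asm0$separation, 0)
})

test_that("min_separation agrees with a fine brute-force scan on rings", {
  ra <- ring_part("A", radius = 6, z0 = 0)
  rb <- ring_part("B", radius = 6, z0 = 4)
  axis <- z_axis()
  asm <- min_separation(ra, rb, axis, step = 0.1)
  ## brute force at 0.01 A using the oracle clash counter
  place <- function(s) {
    shifted <- rb
    shifted$atoms$z <- shifted$atoms$z + (s - 4)
    combine_models(ra, shifted)
  }
  s_grid <- seq(8, 0, by = -0.01)
  s_star <- NA
  for (s in s_grid) {
    if (oracle_clash_count(place(s), "A", "B") > 0) break
    s_star <- s
  }
  expect_lt(abs(asm$separation - s_star), 0.1 + 1e-9)
  ## monotone in tolerance: stricter tolerance never gives smaller s*
  s_loose <- min_separation(ra, rb, axis, tolerance = 0.6)$separation
  s_strict <- min_separation(ra, rb, axis, tolerance = 0.1)$separation
  expect_gte(s_strict, s_loose)
})

test_that("clash detection follows the vdW-overlap criterion and oracle", {
  two <- function(d) combine_models(one_atom_part("A", c(0, 0, 0)),
                                    one_atom_part("B", c(d, 0, 0)))
  expect_equal(detect_clashes(two(2.0), "A", "B")$clash_count, 1L)
  expect_equal(detect_clashes(two(3.2), "A", "B")$clash_count, 0L)
  ## brute-force equivalence on a 500-atom fixture
  fx <- make_c2_dimer(fixture_spec(n_residues_per_domain = 50,
                                   separation = 8.2, seed = 31))$model
  expect_equal(detect_clashes(fx, "A", "B")$clash_count,
               oracle_clash_count(fx, "A", "B"))
  expect_gt(detect_clashes(fx, "A", "B")$clash_count, 0L)
})

test_that("dihedral scan intersects variant feasibility and picks the arc midpoint", {
  axis <- z_axis()
  ## part A: a ring with a gap around 60 degrees at radius 20; an atom
  ## circling at the same radius clears the wall only inside the gap
  pa <- ring_part("A", radius = 20, z0 = 0, every = 2, gap = c(35, 85))
  v2 <- one_atom_part("B", c(20, 0, 0))
  ## variant 1: an atom on the axis, far away: feasible everywhere
  v1 <- one_atom_part("B", c(0, 0, 40))
  sc <- scan_dihedral(pa, list(v1, v2), axis, angular_step = 1)
  expect_equal(length(sc$per_variant_arcs[[1]]), 1L)
  expect_equal(sc$per_variant_arcs[[1]][[1]], c(0, 360))
  expect_lt(abs(sc$angle - 60), 6)

  ## single fully feasible variant: convention midpoint 180
  sc1 <- scan_dihedral(pa, v1, axis, angular_step = 5)
  expect_equal(sc1$angle, 180)

  ## feasibility mask agrees with brute-force clash checks at shared angles
  for (th in seq(0, 350, by = 30)) {
    tr <- axis_rotation_transform(axis, th)
    rotated <- apply_transform(v2, tr)
    brute_free <- oracle_clash_count(combine_models(pa, rotated),
                                     "A", "B") == 0
    in_arc <- any(vapply(sc$per_variant_arcs[[2]], function(a) {
      if (a[1] <= a[2]) th >= a[1] && th <= a[2]
      else th >= a[1] || th <= a[2]
    }, TRUE))
    expect_equal(in_arc, brute_free, info = paste("angle", th))
  }

  ## empty intersection errors and reports per-variant arcs
  pb <- ring_part("B", radius = 20, z0 = 0, every = 2)   # full ring: never feasible
  err <- tryCatch(scan_dihedral(pa, pb, axis, angular_step = 10),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "per-variant arcs")
})

test_that("hybrid composition takes one monomer from each conformation", {
  spec <- fixture_spec(seed = 41)
  closed <- make_topology_dimer("closed", spec)
  open <- make_topology_dimer("crossed", spec)
  match_domains <- list(domain_spec("FADd", "A", 1, 20),
                        domain_spec("FADd", "B", 1, 20))
  ## identical inputs: hybrid equals the input
  same <- compose_hybrid(closed$model, closed$model, match_domains)
  expect_equal(same$fit_rmsd, 0, tolerance = 1e-9)
  expect_equal(coords(same$model), coords(closed$model), tolerance = 1e-9)

  ## mixed: chain A mobile domain at the closed position, chain B at open
  hy <- compose_hybrid(closed$model, open$model, match_domains)
  pick <- function(m, ch) {
    a <- m$atoms
    as.matrix(a[a$chain == ch & a$res_number > 100, c("x", "y", "z")])
  }
  expect_equal(pick(hy$model, "A"), pick(closed$model, "A"),
               tolerance = 1e-6)
  expect_equal(pick(hy$model, "B"), pick(open$model, "B"),
               tolerance = 1e-6)
  ## every domain present exactly once per monomer
  rt <- residue_table(hy$model)
  expect_equal(sum(rt$chain == "A" & rt$res_number <= 20), 20L)
  expect_equal(sum(rt$chain == "B" & rt$res_number > 100), 20L)

  ## restricted fit is optimal on its own selection: fitting on the whole
  ## model can never beat it on the matched-domain Ca atoms
  mc_a <- matched_ca(open$model, closed$model, "A", "A", range = c(1, 20))
  mc_b <- matched_ca(open$model, closed$model, "B", "B", range = c(1, 20))
  sel_mob <- rbind(mc_a$mobile, mc_b$mobile)
  sel_tgt <- rbind(mc_a$target, mc_b$target)
  all_fit <- kabsch(coords(open$model), coords(closed$model))
  moved <- apply_transform(sel_mob, all_fit$transform)
  rmsd_all <- sqrt(mean(rowSums((moved - sel_tgt)^2)))
  restricted <- kabsch(sel_mob, sel_tgt)
  expect_lte(restricted$rmsd, rmsd_all + 1e-9)
})

test_that("assembly operations are rigid and deliver clash-free models", {
  p1 <- make_c2_dimer(fixture_spec(seed = 51))$model
  p2 <- make_c2_dimer(fixture_spec(axis_direction = c(0, 0.6, 0.8),
                                   seed = 52))$model
  ax1 <- detect_c2_axis(p1)
  al <- align_axes(p1, ax1, p2, detect_c2_axis(p2))$model
  asm <- min_separation(p1, al, ax1)
  expect_equal(asm$clash_report$clash_count, 0L)
  expect_equal(detect_clashes(asm$model, asm$groups$part_a,
                              asm$groups$part_b)$clash_count, 0L)
  ## intra-part distances preserved through the whole pipeline
  i <- seq(1, nrow(p2$atoms), by = 9)
  part_b_out <- extract_chains(asm$model, asm$groups$part_b)
  expect_lt(max(abs(dist(coords(p2)[i, ]) - dist(coords(part_b_out)[i, ]))),
            1e-6)
  ## chain renaming is emitted
  expect_setequal(names(asm$chain_map), c("A", "B"))
  expect_setequal(unname(asm$chain_map), c("C", "D"))
})
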