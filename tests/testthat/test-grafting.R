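test_that("domain superposition recovers constructed transforms", {
  ref <- make_cofactor_reference()
  spec <- domain_spec("dom", "A", 1, 30)
  ## identity on a copy
  fit0 <- superpose_by_domain(ref, ref, spec, spec)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit0$transform$translation, c(0, 0, 0), tolerance = 1e-9)

  ## rotation 37 degrees about z plus translation is inverted exactly
  planted <- rigid_transform(
    dimerforge:::rotation_about_axis(c(0, 0, 1), 37), c(5, -2, 1))
  target <- apply_transform(ref, planted)
  fit <- superpose_by_domain(ref, target, spec, spec)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_lt(max(abs(fit$transform$rotation - planted$rotation)), 1e-6)
  expect_lt(max(abs(fit$transform$translation - planted$translation)), 1e-6)
  ## applying the recovered transform to matched Ca reproduces the target
  mc <- matched_ca(ref, target)
  expect_lt(max(abs(apply_transform(mc$mobile, fit$transform) - mc$target)),
            1e-6)
  ## insufficient matches error
  expect_error(superpose_by_domain(ref, target, spec,
                                   domain_spec("x", "A", 500, 510)),
               "insufficient")
})

test_that("superposition rmsd matches an independent optimiser on a 4-point toy", {
  ## mobile: unit square in xy; target: translated with one corner lifted.
  ## Translation-only residual is hand-computable (centring leaves
  ## displacements (0,0,-0.25) x3 and (0,0,0.75) -> rmsd sqrt(0.1875));
  ## the optimal rotation can only improve on it.
  mob <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  tgt <- sweep(mob, 2, c(1, 2, 3), `+`)
  tgt[4, 3] <- tgt[4, 3] + 1
  fit <- kabsch(mob, tgt)
  expect_lte(fit$rmsd, sqrt(0.1875) + 1e-9)

  ## independent oracle: direct minimisation over Euler angles
  obj <- function(par) {
    Rz1 <- dimerforge:::rotation_about_axis(c(0, 0, 1), par[1])
    Ry <- dimerforge:::rotation_about_axis(c(0, 1, 0), par[2])
    Rz2 <- dimerforge:::rotation_about_axis(c(0, 0, 1), par[3])
    R <- Rz1 %*% Ry %*% Rz2
    P <- sweep(mob, 2, colMeans(mob)); Q <- sweep(tgt, 2, colMeans(tgt))
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- Inf
  for (start in list(c(0, 0, 0), c(30, 30, 30), c(120, 60, -45),
                     c(-90, 10, 90))) {
    best <- min(best, stats::optim(start, obj)$value)
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-3)

  ## exact translation-only case is hand-computable to zero
  fit2 <- kabsch(mob, sweep(mob, 2, c(1, 2, 3), `+`))
  expect_equal(fit2$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit2$transform$translation, c(1, 2, 3), tolerance = 1e-9)
})

test_that("cofactor grafting transfers rigidly and leaves protein atoms alone", {
  ref <- make_cofactor_reference()
  spec <- domain_spec("dom", "A", 1, 30)
  tmpl <- cofactor_template(ref, spec, "HEM")
  protein_only <- function(m) {
    structure_model(m$atoms[!m$atoms$is_hetero, , drop = FALSE])
  }

  ## graft onto identical copy: cofactor coordinates unchanged
  g0 <- graft_cofactor(tmpl, protein_only(ref), spec)
  cof_ref <- ref$atoms[ref$atoms$res_name == "HEM", c("x", "y", "z")]
  cof_out <- g0$model$atoms[g0$model$atoms$res_name == "HEM",
                            c("x", "y", "z")]
  expect_lt(max(abs(as.matrix(cof_out) - as.matrix(cof_ref))), 1e-6)
  expect_equal(g0$fit_rmsd, 0, tolerance = 1e-9)

  ## graft onto translated copy: cofactor translated by the same vector
  shift <- c(-3, 7, 2)
  moved <- apply_transform(protein_only(ref),
                           rigid_transform(diag(3), shift))
  g1 <- graft_cofactor(tmpl, moved, spec)
  cof1 <- g1$model$atoms[g1$model$atoms$res_name == "HEM", c("x", "y", "z")]
  expect_lt(max(abs(as.matrix(cof1) - sweep(as.matrix(cof_ref), 2, shift,
                                            `+`))), 1e-6)

  ## internal cofactor distances preserved under a general transform
  tilted <- apply_transform(protein_only(ref), rigid_transform(
    dimerforge:::rotation_about_axis(c(1, 1, 0), 63), c(4, 4, -9)))
  g2 <- graft_cofactor(tmpl, tilted, spec)
  cof2 <- as.matrix(g2$model$atoms[g2$model$atoms$res_name == "HEM",
                                   c("x", "y", "z")])
  expect_lt(max(abs(dist(cof2) - dist(as.matrix(cof_ref)))), 1e-6)

  ## pre-existing protein atoms bit-identical
  expect_identical(
    g2$model$atoms[!g2$model$atoms$is_hetero, c("x", "y", "z")],
    tilted$atoms[, c("x", "y", "z")])

  ## clash report against protein matches brute force
  expect_equal(g2$post_graft_clashes$clash_count,
               oracle_clash_count(g2$model, "A", g2$graft_chain,
                                  include_hetero = TRUE))

  ## absent cofactor is an error
  expect_error(cofactor_template(ref, spec, "FAD"), "not found")
})

test_that("linker feasibility applies the extended-chain reach bound", {
  ## anchors 30 A apart bridged by 20 missing residues: reach 79.8 A
  a <- make_strand_chain(3, chain = "A", x0 = 0)
  b <- make_strand_chain(3, chain = "A", start_res = 24L, x0 = 30)
  atoms <- rbind(a$atoms, b$atoms); atoms$serial <- seq_len(nrow(atoms))
  m <- structure_model(atoms)
  res <- check_linker_feasibility(m, linker_gap("A", 3, 24, 20))
  expect_true(res$feasible)
  expect_equal(res$max_reach, 79.8)
  expect_lt(abs(res$observed_gap - 30), 3)   # backbone offsets off the Ca

  ## direct peptide bond: 0 missing residues at bonding distance
  n2 <- make_strand_chain(2, chain = "A")
  res0 <- check_linker_feasibility(n2, linker_gap("A", 1, 2, 0))
  expect_true(res0$feasible)
  expect_lt(res0$observed_gap, 3.8)

  ## 2 missing residues cannot span 50 A
  far <- make_strand_chain(3, chain = "A", start_res = 10L, x0 = 50)
  atoms2 <- rbind(a$atoms, far$atoms)
  atoms2$serial <- seq_len(nrow(atoms2))
  m2 <- structure_model(atoms2)
  res2 <- check_linker_feasibility(m2, linker_gap("A", 3, 10, 2))
  expect_false(res2$feasible)
  expect_equal(res2$max_reach, 11.4)

  ## monotone in n_missing
  feas <- vapply(0:15, function(k)
    check_linker_feasibility(m2, linker_gap("A", 3, 10, k))$feasible, TRUE)
  expect_false(is.unsorted(feas))   # FALSE..FALSE TRUE..TRUE

  ## missing backbone atoms are an error
  noback <- structure_model(m2$atoms[m2$atoms$name == "CB", , drop = FALSE])
  expect_error(check_linker_feasibility(noback, linker_gap("A", 3, 10, 2)),
               "backbone")
})
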