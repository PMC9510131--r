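test_that("SASA: isolated and buried atoms behave as expected", {
  ## isolated single-atom residue: every sphere point exposed
  solo <- one_atom_part("A", c(0, 0, 0))
  s <- compute_sasa(solo)
  r <- vdw_radius("C") + 1.4
  expect_equal(s$sasa, 4 * pi * r^2, tolerance = 1e-6)

  ## an atom at the centre of a dense cluster is fully occluded
  shell <- lapply(1:26, function(k) {
    d <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
    d <- d[rowSums(abs(d)) > 0, ]
    as.numeric(d[k, ]) * 1.5
  })
  atoms <- do.call(rbind, c(list(one_atom_part("A", c(0, 0, 0))$atoms),
                            lapply(seq_along(shell), function(k) {
                              p <- one_atom_part("A", shell[[k]],
                                                 res_number = k + 1L)
                              p$atoms
                            })))
  atoms$serial <- seq_len(nrow(atoms))
  m <- structure_model(atoms)
  s2 <- compute_sasa(m)
  expect_equal(s2$sasa[s2$res_number == 1], 0)
})

test_that("SASA matches a brute-force Shrake-Rupley oracle at 960 points", {
  fx <- make_c2_dimer(fixture_spec(geometry = "strand",
                                   n_residues_per_domain = 10, seed = 3))
  got <- compute_sasa(fx$model, n_points = 960)
  want <- oracle_sasa(fx$model, n_points = 960)
  key <- paste(got$chain, got$res_number, got$ins_code, sep = "|")
  expect_setequal(key, names(want))
  expect_lt(max(abs(got$sasa - as.numeric(want[key]))), 0.5)
})

test_that("interface contacts match construction and the brute-force scan", {
  ## two chains 100 A apart: no contacts
  apart <- combine_models(make_strand_chain(5, chain = "A"),
                          make_strand_chain(5, chain = "B", x0 = 100))
  expect_equal(nrow(interface_contacts(apart, "A", "B")$contacts), 0L)

  ## exactly 3 cross-group residue pairs planted at 4.0 A
  a3 <- do.call(rbind, lapply(1:3, function(k)
    one_atom_part("A", c(0, 20 * k, 0), res_number = k)$atoms))
  b3 <- do.call(rbind, lapply(1:3, function(k)
    one_atom_part("B", c(4, 20 * k, 0), res_number = k)$atoms))
  ab <- rbind(a3, b3); ab$serial <- seq_len(nrow(ab))
  planted <- structure_model(ab)
  ic <- interface_contacts(planted, "A", "B")
  expect_equal(nrow(ic$contacts), 3L)
  expect_equal(ic$contacts$distance, rep(4, 3))

  ## oracle equivalence on a set of >= 5 fixtures, both orientations
  fixtures <- c(
    lapply(c("crossed", "closed", "cis", "trans"), function(lab)
      make_topology_dimer(lab, fixture_spec(noise_sigma = 0.2,
                                            seed = match(lab, c(
                                              "crossed", "closed", "cis",
                                              "trans"))))$model),
    list(make_c2_dimer(fixture_spec(geometry = "strand", seed = 9))$model))
  for (m in fixtures) {
    got <- interface_contacts(m, "A", "B")$contacts
    want <- oracle_contacts(m, "A", "B")
    expect_setequal(package_contact_keys(got), sort(want$key))
    ## and symmetric in group order up to orientation
    rev <- interface_contacts(m, "B", "A")$contacts
    expect_equal(nrow(rev), nrow(got))
  }
})

test_that("dG formula reduces to the intercept and is linear in counts", {
  z <- contact_counts(NULL)
  nis0 <- structure(list(pct_apolar = 0, pct_charged = 0,
                         n_surface_residues = 0), class = "nis_profile")
  expect_equal(predict_dG(z, nis0)$dg, -15.9433, tolerance = 1e-6)

  ## linearity: doubling every count moves dG by the sum of contact terms
  ct <- data.frame(class_pair = c(rep("charged/charged", 2),
                                  rep("charged/apolar", 5),
                                  rep("polar/polar", 1),
                                  rep("polar/apolar", 3)))
  c1 <- contact_counts(ct)
  c2 <- contact_counts(rbind(ct, ct))
  nis <- structure(list(pct_apolar = 57, pct_charged = 22,
                        n_surface_residues = 100), class = "nis_profile")
  d1 <- predict_dG(c1, nis)$dg
  d2 <- predict_dG(c2, nis)$dg
  step <- -0.09459 * 2 - 0.10007 * 5 + 0.19577 * 1 - 0.22671 * 3
  expect_equal(d2 - d1, step, tolerance = 1e-9)
  ## and the absolute value agrees with independent arithmetic
  expect_equal(d1, oracle_dg(2, 5, 1, 3, 57, 22), tolerance = 1e-9)
})

test_that("end-to-end dG agrees with independent recomputation on complexes", {
  specs <- list(fixture_spec(geometry = "strand", seed = 21),
                fixture_spec(geometry = "strand", n_residues_per_domain = 14,
                             seed = 22),
                fixture_spec(geometry = "strand", noise_sigma = 0.15,
                             seed = 23))
  for (sp in specs) {
    m <- make_c2_dimer(sp)$model
    be <- binding_energy(m, "A", "B")
    ## independent route: oracle contacts classified by hand + package NIS
    want <- oracle_contacts(m, "A", "B")
    cls <- function(k) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      rt <- m$atoms$res_name[m$atoms$chain == parts[1] &
                               m$atoms$res_number == as.integer(parts[2])][1]
      residue_class(rt)
    }
    pair_class <- vapply(want$key, function(k) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      a <- cls(paste(parts[1], parts[2], parts[3], sep = "|"))
      b <- cls(paste(parts[4], parts[5], parts[6], sep = "|"))
      paste(sort(c(a, b)), collapse = "/")
    }, "")
    n_of <- function(x) sum(pair_class == x)
    dg_ind <- oracle_dg(n_of("charged/charged"), n_of("apolar/charged"),
                        n_of("polar/polar"), n_of("apolar/polar"),
                        be$nis$pct_apolar, be$nis$pct_charged)
    expect_equal(be$dg, dg_ind, tolerance = 0.1)
  }
})

test_that("complex classification follows the 3 kcal/mol magnitude rule", {
  expect_equal(classify_complex(-2.0), "no_complex")
  expect_equal(classify_complex(-9.3), "complex")
  expect_equal(classify_complex(-3.0), "complex")   # boundary inclusive
  expect_equal(classify_complex(2.9), "no_complex") # magnitude, not sign

  ## separated chains classify from the honestly computed value
  apart <- combine_models(make_strand_chain(20, chain = "A"),
                          make_strand_chain(20, chain = "B", x0 = 120))
  be <- binding_energy(apart, "A", "B")
  tot <- be$counts$ic_cc + be$counts$ic_ca + be$counts$ic_pp +
    be$counts$ic_pa + be$counts$ic_cp + be$counts$ic_aa
  expect_equal(tot, 0L)
  expect_true(abs(be$dg) < 3)
  expect_equal(classify_complex(be), "no_complex")

  ## bound strand dimer with a ~4.4 A interface is a complex
  bound <- make_c2_dimer(fixture_spec(geometry = "strand", seed = 2))
  expect_equal(classify_complex(binding_energy(bound$model, "A", "B")),
               "complex")
})
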