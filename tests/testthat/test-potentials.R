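test_that("bond parameter table carries the expected pairs and units", {
  p <- bond_params()
  expect_equal(p$pair_type, c("C-C", "C-O", "O-O", "P-O", "P=O"))
  expect_equal(p$r_e, c(1.54, 1.43, 1.48, 1.64, 1.50))
  expect_equal(p$D_e, c(3.61, 3.73, 1.50, 3.47, 5.64))
  expect_equal(p$k_e, c(5e5, 5e5, 5e5, 5e5, 10e5))
  expect_true(all(p$alpha > 0))
})

test_that("bond parameters load from a CSV override", {
  csv <- system.file("extdata", "bond_params.csv", package = "cgdamage")
  expect_true(nzchar(csv))
  p <- bond_params(csv)
  expect_equal(p, bond_params())
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(bond_params(bad), "columns")
})

test_that("force constants follow bond order", {
  expect_equal(force_constant(c("single", "double", "triple")),
               c(5e5, 10e5, 15e5))
  expect_error(force_constant("quadruple"), "unknown bond order")
})

test_that("Morse width agrees with an independent unit conversion", {
  p <- bond_params()
  # recompute in SI from scratch: dyn/cm -> N/m, eV -> J, 1/m -> 1/A
  manual <- sqrt((p$k_e * 1e-3) / (2 * p$D_e * 1.602176634e-19)) * 1e-10
  expect_equal(alpha_from_force_constant(p$k_e, p$D_e), manual,
               tolerance = 1e-12)
  expect_error(alpha_from_force_constant(-1, 3), "positive")
  expect_error(alpha_from_force_constant(5e5, 0), "positive")
})

test_that("Morse potential has the standard well shape", {
  r_e <- 1.54; D_e <- 3.61; k_e <- 5e5
  a <- alpha_from_force_constant(k_e, D_e)
  expect_equal(morse_energy(r_e, r_e, D_e, alpha = a), -D_e)
  # dissociation limit
  expect_lt(abs(morse_energy(50, r_e, D_e, alpha = a)), 1e-10)
  # minimum: energy rises on both sides of r_e
  expect_gt(morse_energy(r_e + 0.05, r_e, D_e, alpha = a), -D_e)
  expect_gt(morse_energy(r_e - 0.05, r_e, D_e, alpha = a), -D_e)
  # curvature at the minimum equals the force constant: U'' = 2 a^2 D_e
  h <- 1e-4
  num <- (morse_energy(r_e + h, r_e, D_e, alpha = a) +
            morse_energy(r_e - h, r_e, D_e, alpha = a) + 2 * D_e) / h^2
  expect_equal(num, 2 * a^2 * D_e, tolerance = 1e-4)
  # k_e route gives the same value as the explicit alpha
  expect_equal(morse_energy(1.6, r_e, D_e, k_e = k_e),
               morse_energy(1.6, r_e, D_e, alpha = a))
  expect_error(morse_energy(1.6, r_e, D_e), "alpha or k_e")
  expect_error(morse_energy(-1, r_e, D_e, alpha = a), "positive")
})

test_that("Lennard-Jones potential has minimum -D_e at r_e and zero at sigma", {
  r_e <- 1.48; D_e <- 1.50
  expect_equal(lj_energy(r_e, r_e, D_e), -D_e, tolerance = 1e-12)
  s <- r_e / 2^(1 / 6)
  expect_equal(lj_energy(s, r_e, D_e), 0, tolerance = 1e-12)
  expect_gt(lj_energy(0.8 * s, r_e, D_e), 0)     # repulsive core
  expect_gt(lj_energy(3 * r_e, r_e, D_e), -D_e)  # shallow tail
  expect_lt(lj_energy(3 * r_e, r_e, D_e), 0)
})

test_that("pair enumeration separates bonded from non-bonded pairs", {
  tpl <- nucleotide_template()
  ph <- tpl[tpl$moiety == "phosphate", ]
  pr <- enumerate_pairs(ph)
  expect_equal(nrow(pr$bonded), 3)     # P-OP1, P-OP2, P-O5'
  expect_equal(nrow(pr$nonbonded), 3)  # the three O-O contacts
  expect_setequal(pr$nonbonded$pair_type, "O-O")
  expect_error(enumerate_pairs(ph[0, ]), "no atoms")
  weird <- data.frame(name = "XX", element = "X", x = 0, y = 0, z = 0)
  expect_error(enumerate_pairs(weird), "absent from the nucleotide")
})

test_that("boundary atoms contribute only their covalent bond", {
  tpl <- nucleotide_template()
  su <- tpl[tpl$moiety == "deoxyribose", ]
  o5 <- tpl[tpl$name == "O5'", ]
  with_b <- enumerate_pairs(su, boundary_atoms = o5)
  without <- enumerate_pairs(su)
  expect_equal(nrow(with_b$bonded), nrow(without$bonded) + 1)
  expect_equal(nrow(with_b$nonbonded), nrow(without$nonbonded))
  extra <- setdiff(paste(with_b$bonded$a, with_b$bonded$b),
                   paste(without$bonded$a, without$bonded$b))
  expect_equal(extra, "C5' O5'")
})

test_that("cluster potential equals a direct all-pairs oracle sum", {
  tpl <- nucleotide_template()
  cols <- c("name", "element", "x", "y", "z")
  ph <- tpl[tpl$moiety == "phosphate", cols]
  su <- tpl[tpl$moiety == "deoxyribose", cols]
  o5 <- tpl[tpl$name == "O5'", cols]
  expect_equal(cluster_potential(ph)$U_total, oracle_cluster_energy(ph),
               tolerance = 1e-12)
  expect_equal(cluster_potential(su, boundary_atoms = o5)$U_total,
               oracle_cluster_energy(su, o5), tolerance = 1e-12)
})

test_that("cluster potential rejects pairs without parameters", {
  atoms <- data.frame(name = c("C1'", "N9"), element = c("C", "N"),
                      x = c(0, 1.47), y = 0, z = 0)
  expect_error(cluster_potential(atoms), "no parameters")
})

test_that("backbone thresholds are positive, sugar above phosphate", {
  bt <- backbone_thresholds()
  expect_named(bt, c("phosphate", "deoxyribose"))
  expect_true(all(bt > 0))
  expect_gt(bt["deoxyribose"], bt["phosphate"])
})
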