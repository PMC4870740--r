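test_that("angle factor matches the sigma-hole charge model", {
  # iodine at 177.8 deg: the published worked-example value
  expect_equal(angle_factor(177.8, "I"), 0.998, tolerance = 0.001)
  # perfectly linear contact: ratio of charges is exactly 1
  for (el in c("Cl", "Br", "I")) {
    expect_identical(angle_factor(180, el), 1)
    t0 <- xbsf_params()$halogens[[el]]$theta0
    expect_identical(angle_factor(t0, el), 0)        # electroneutral angle
    expect_identical(angle_factor(t0 - 10, el), 0)   # below cutoff
  }
  expect_equal(angle_factor(120, "I"), 0)
  expect_error(angle_factor(181, "I"), "\\[0, 180\\]")
  expect_error(angle_factor(-1, "Cl"), "\\[0, 180\\]")
  expect_error(angle_factor(170, "F"), "halogen")
})

test_that("angle factor agrees with the closed-form oracle on a grid", {
  thetas <- seq(0, 180, by = 0.5)
  for (el in c("Cl", "Br", "I")) {
    got <- angle_factor(thetas, el)
    want <- vapply(thetas, oracle_phi, numeric(1), halogen = el)
    expect_equal(got, want, tolerance = 1e-12)
    # monotone non-decreasing above the electroneutral angle
    t0 <- oracle_constants$theta0[[el]]
    above <- got[thetas >= t0]
    expect_true(all(diff(above) >= -1e-12))
  }
})

test_that("custom charge-model coefficients override the default", {
  # nu = 1, A = 1, B = -cos(58 deg) is exactly the iodine default
  p <- xbsf_params(charge = list(I = list(A = 1, B = -cos(58 * pi / 180),
                                          nu = 1)))
  expect_equal(angle_factor(160, "I", p), angle_factor(160, "I"),
               tolerance = 1e-12)
  # a different B changes the value but keeps the anchors
  p2 <- xbsf_params(charge = list(I = list(B = -0.4)))
  expect_identical(angle_factor(180, "I", p2), 1)
  expect_identical(angle_factor(121, "I", p2), 0)
  expect_false(isTRUE(all.equal(angle_factor(150, "I", p2),
                                angle_factor(150, "I"))))
})

test_that("distance factor reproduces the overlap interpolation", {
  # worked example: I...O 3.354 A at 177.8 deg, overlap 0.546 A
  overlap <- (2.2 + 1.7) - 3.354
  expect_equal(round(overlap, 3), 0.546)
  expect_equal(distance_factor(3.354, 177.8, "I", "O"), 0.992,
               tolerance = 0.002)
  # boundaries: d = 0 at the radii sum; saturation below -delta
  expect_identical(distance_factor(3.90, 175, "I", "O"), 0)
  expect_identical(distance_factor(3.30, 170, "I", "O"), 1)
  expect_identical(distance_factor(5.0, 179, "I", "O"), 0)
  expect_error(distance_factor(3.0, 170, "I", "Xx"), "acceptor")
  expect_error(distance_factor(-1, 170, "I", "O"), "positive")
})

test_that("delta selection follows the angle-ranged table with extension", {
  # iodine: 0.55 / 0.45 / 0.35 across the three bins
  d <- 3.9 - 0.2  # overlap 0.2 A
  expect_equal(distance_factor(d, 170, "I", "O"), 0.2 / 0.55)
  expect_equal(distance_factor(d, 160, "I", "O"), 0.2 / 0.45)
  expect_equal(distance_factor(d, 140, "I", "O"), 0.2 / 0.35)
  # extension below the lowest tabulated range
  expect_equal(distance_factor(d, 130, "I", "O"), 0.2 / 0.35)
  # chlorine has no 135-150 row: lowest delta extends down
  dc <- 3.5 - 0.1
  expect_equal(distance_factor(dc, 147, "Cl", "O"), 0.1 / 0.15)
  # zero mode instead kills D below the tabulated ranges
  pz <- xbsf_params(delta_extension = "zero")
  expect_identical(distance_factor(dc, 147, "Cl", "O", params = pz), 0)
  expect_identical(distance_factor(d, 130, "I", "O", params = pz), 0)
  expect_equal(distance_factor(d, 160, "I", "O", params = pz), 0.2 / 0.45)
})

test_that("halogen weights are the tabled energy-well depths", {
  expect_identical(halogen_weight("Cl"), -0.265)
  expect_identical(halogen_weight("Br"), -0.32)
  expect_identical(halogen_weight("I"), -0.4)
  expect_error(halogen_weight("F"), "halogen")
})

test_that("score_interaction composes E = W * Phi * D", {
  sc <- score_interaction("I", "O", 3.354, 177.8)
  expect_equal(sc$pre_weight, 0.990, tolerance = 0.002)
  expect_equal(sc$energy, -0.4 * sc$pre_weight)
  expect_equal(sc$energy, -0.396, tolerance = 0.002)
  # below the electroneutral angle the whole term vanishes
  expect_identical(score_interaction("Br", "N", 3.1, 120)$energy, 0)
})

test_that("score_complex matches the exhaustive-pair oracle", {
  withr::local_seed(202)
  for (rep in 1:10) {
    spec <- random_geometry_spec()
    cx <- make_complex(halogen = spec$halogen, acceptor = spec$acceptor,
                       distance = spec$distance, theta = spec$theta,
                       decoy_atoms = 4, seed = rep)
    sc <- score_complex(cx$protein, cx$ligand)
    expect_equal(sc$total, oracle_total_energy(cx$protein, cx$ligand),
                 tolerance = 1e-12)
    expect_equal(sc$total, sum(sc$interactions$energy))
  }
})

test_that("many-halogen complexes sum over all donor/acceptor pairs", {
  # 3 halogens x 4 acceptors assembled by translation of single fixtures
  base <- make_complex(halogen = "I", acceptor = "O", distance = 3.3,
                       theta = 172, cx_bond_length = 1.79, decoy_atoms = 0)
  lig_at <- base$ligand$atoms
  prot_at <- base$protein$atoms
  lig <- list(); prot <- list()
  for (k in 0:2) {
    a <- lig_at; a$x <- a$x + 20 * k; a$serial <- a$serial + 10L * k
    a$element[2] <- c("I", "Br", "Cl")[k + 1]
    a$name[2] <- paste0(toupper(a$element[2]), "1")
    lig[[k + 1]] <- a
  }
  for (k in 0:3) {
    a <- prot_at; a$x <- a$x + 20 * (k %% 3); a$z <- a$z + 3 * (k %/% 3)
    a$serial <- a$serial + 10L * k; a$resno <- a$resno + k
    a$element[1] <- c("O", "N", "S", "O")[k + 1]
    prot[[k + 1]] <- a
  }
  ligand <- structure(list(atoms = do.call(rbind, lig), model_id = 1L,
                           resolution = NA_real_), class = "xbsf_structure")
  protein <- structure(list(atoms = do.call(rbind, prot), model_id = 1L,
                            resolution = NA_real_), class = "xbsf_structure")
  sc <- score_complex(protein, ligand)
  expect_equal(sc$total, oracle_total_energy(protein, ligand),
               tolerance = 1e-12)
  expect_gt(nrow(sc$interactions), 1)
  # deterministic ordering by halogen serial then acceptor serial
  o <- order(sc$interactions$hal_serial, sc$interactions$acc_serial)
  expect_equal(o, seq_len(nrow(sc$interactions)))
})

test_that("scores are invariant under rigid motion of the complex", {
  cx <- make_complex(halogen = "Br", acceptor = "S", distance = 3.45,
                     theta = 158, seed = 9)
  sc0 <- score_complex(cx$protein, cx$ligand)
  R <- rbind(c(0.36, 0.48, -0.8), c(-0.8, 0.6, 0), c(0.48, 0.64, 0.6))
  expect_equal(max(abs(R %*% t(R) - diag(3))), 0, tolerance = 1e-12)
  tr <- c(11.2, -7.9, 3.3)
  sc1 <- score_complex(transform_structure(cx$protein, R, tr),
                       transform_structure(cx$ligand, R, tr))
  expect_equal(sc1$total, sc0$total, tolerance = 1e-6)
  expect_equal(sc1$interactions$phi, sc0$interactions$phi, tolerance = 1e-6)
  expect_equal(sc1$interactions$dfac, sc0$interactions$dfac,
               tolerance = 1e-6)
})

test_that("non-halogenated ligands score exactly zero", {
  cx <- make_complex()
  lig <- cx$ligand
  lig$atoms <- lig$atoms[lig$atoms$element == "C", , drop = FALSE]
  sc <- score_complex(cx$protein, lig)
  expect_identical(sc$total, 0)
  expect_equal(nrow(sc$interactions), 0)
  expect_identical(rescore_poses(cx$protein, list(lig, lig))$xb_energy,
                   c(0, 0))
})

test_that("parameter config round-trips byte-identically through YAML", {
  p <- xbsf_params()
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_xbsf_params(p, f1)
  back <- read_xbsf_params(f1)
  expect_equal(back$halogens$I$weight, -0.4)
  expect_equal(back$halogens$Cl$theta0, 146)
  expect_equal(unname(back$acceptors["N"]), 1.8)
  write_xbsf_params(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a hand-edited radius survives the round trip
  p2 <- xbsf_params(sulfur_radius = 1.85)
  write_xbsf_params(p2, f1)
  expect_equal(unname(read_xbsf_params(f1)$acceptors["S"]), 1.85)
})
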