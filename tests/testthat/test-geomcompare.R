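test_that("planar trans and cis chains give 180 and 0 degrees", {
  trans <- make_torsion_structure(180)
  cis <- make_torsion_structure(0)
  expect_equal(dihedral_angle(trans, 1:4), 180)
  expect_equal(dihedral_angle(cis, 1:4), 0)
  # parametric fixture hits the requested angle across the circle
  for (phi in c(-179, -90, -30, 45, 90, 179)) {
    expect_equal(dihedral_angle(make_torsion_structure(phi), 1:4), phi,
                 tolerance = 1e-9)
  }
})

test_that("dihedrals match the independent normal-vector oracle", {
  set.seed(21)
  for (k in 1:50) {
    s <- structure(list(elements = rep("C", 4),
                        coords = matrix(rnorm(12, 0, 2), 4, 3),
                        comment = "", annotations = NULL),
                   class = "xyz_structure")
    expect_equal(dihedral_angle(s, 1:4), oracle_dihedral(s$coords, 1:4),
                 tolerance = 1e-9)
  }
})

test_that("collinear and malformed dihedral inputs error", {
  s <- structure(list(elements = rep("C", 4),
                      coords = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                     c(3, 1, 0)),
                      comment = "", annotations = NULL),
                 class = "xyz_structure")
  expect_error(dihedral_angle(s, 1:4), "collinear")
  expect_error(dihedral_angle(s, c(1, 1, 2, 3)), "distinct")
  expect_error(dihedral_angle(s, c(1, 2, 3, 9)), "in-range")
})

test_that("atom_distance is Euclidean and isometry-invariant", {
  s <- structure(list(elements = c("C", "C", "C"),
                      coords = rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0)),
                      comment = "", annotations = NULL),
                 class = "xyz_structure")
  expect_equal(atom_distance(s, c(1, 2)), 5)
  expect_equal(atom_distance(s, c(1, 3)), 0)  # coincident points

  set.seed(33)
  ch <- make_chain_structure(10)
  for (k in 1:10) {
    moved <- apply_isometry(ch)
    expect_equal(atom_distance(moved, c(1, 10)), atom_distance(ch, c(1, 10)),
                 tolerance = 1e-9)
    expect_equal(dihedral_angle(moved, c(2, 3, 4, 5)),
                 dihedral_angle(ch, c(2, 3, 4, 5)), tolerance = 1e-9)
  }
})

test_that("internal-coordinate comparison wraps, summarizes and validates", {
  a <- make_chain_structure(12)
  expect_equal(compare_internal_coordinates(a, a)$dihedrals$mad, 0)

  # periodic wrap: test 179 vs reference -179 is a -2 degree deviation
  # (179 - (-179) = 358 wraps into (-180, 180]), never 358 itself
  s179 <- make_torsion_structure(179)
  sm179 <- make_torsion_structure(-179)
  dev <- compare_internal_coordinates(sm179, s179)$dihedrals$deviations
  expect_equal(unname(dev["tor"]), -2, tolerance = 1e-9)
  expect_true(all(dev > -180 & dev <= 180))

  b <- a
  names(b$annotations$dihedrals)[1] <- "zeta"
  err <- expect_error(compare_internal_coordinates(a, b))
  expect_match(conditionMessage(err), "zeta")
})

test_that("injected deviations are recovered exactly with known summaries", {
  spec <- synthetic_spec(seed = 2)
  base <- make_chain_structure(12)
  inj <- c(phi = 5, psi = -3, chi = 1)
  gen <- gen_perturbed_structures(spec, base, dihedral_dev = inj,
                                  distance_dev = numeric(0),
                                  rigid_motion = TRUE)
  rep <- compare_internal_coordinates(gen$reference, gen$perturbed)
  expect_equal(rep$dihedrals$deviations[names(inj)],
               inj, tolerance = 1e-8)
  expect_equal(rep$dihedrals$mad, 3, tolerance = 1e-8)
  expect_equal(unname(rep$dihedrals$range), c(-3, 5), tolerance = 1e-8)
  expect_equal(unname(rep$dihedrals$range["min"]), -3, tolerance = 1e-8)
})

test_that("rigid motion alone leaves internal coordinates untouched", {
  spec <- synthetic_spec(seed = 4)
  base <- make_chain_structure(12)
  gen <- gen_perturbed_structures(spec, base,
                                  dihedral_dev = numeric(0),
                                  distance_dev = numeric(0),
                                  rigid_motion = TRUE)
  rep <- compare_internal_coordinates(gen$reference, gen$perturbed)
  expect_lt(max(abs(rep$dihedrals$deviations)), 1e-9)
  expect_lt(max(abs(rep$distances$deviations)), 1e-9)
})

test_that("Kabsch superposition: exactness, optimality, chirality", {
  ch <- make_chain_structure(12)
  sub <- ch$annotations$phenyl$ring

  expect_equal(kabsch_superpose(ch, ch, sub)$rmsd, 0, tolerance = 1e-12)

  set.seed(55)
  moved <- apply_isometry(ch)
  fit <- kabsch_superpose(ch, moved, sub)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(fit$transformed - ch$coords)), 1e-8)

  # noisy copy: matches the brute-force Euler-angle optimizer to 1e-6
  noisy <- apply_isometry(ch)
  noisy$coords <- noisy$coords + matrix(rnorm(36, 0, 0.05), 12, 3)
  fit <- kabsch_superpose(ch, noisy, sub)
  oracle <- oracle_superpose_rmsd(ch$coords[sub, ], noisy$coords[sub, ])
  expect_equal(fit$rmsd, oracle, tolerance = 1e-6)

  # no randomly drawn rigid transform beats the Kabsch optimum
  qa <- sweep(ch$coords[sub, ], 2, colMeans(ch$coords[sub, ]))
  qb <- sweep(noisy$coords[sub, ], 2, colMeans(noisy$coords[sub, ]))
  for (k in 1:100) {
    r <- oracle_rotation()
    expect_gte(sqrt(mean(rowSums((qb %*% t(r) - qa)^2))) + 1e-12, fit$rmsd)
  }

  # mirror images are not superposable (proper rotations only)
  mirror <- ch
  mirror$coords[, 1] <- -mirror$coords[, 1]
  fitm <- kabsch_superpose(ch, mirror, sub)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0.1)
})

test_that("degenerate superposition subsets are rejected", {
  line <- structure(list(elements = rep("C", 4),
                         coords = cbind(0:3, 0, 0), comment = "",
                         annotations = NULL),
                    class = "xyz_structure")
  expect_error(kabsch_superpose(line, line, 1:4), "collinear")
  ch <- make_chain_structure(8)
  expect_error(kabsch_superpose(ch, ch, 1:2), ">= 3")
})
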