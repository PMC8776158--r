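frag_cycle <- function(n) rep_len(c("phenyl_1", "phenyl_2", "peptide_bond_1",
                                    "peptide_bond_2", "other"), n)

test_that("rank-1 and diagonal amplitude matrices decompose as expected", {
  m <- matrix(0, 3, 4)
  m[2, 3] <- 0.7
  amp <- transition_amplitudes(m, frag_cycle(3), frag_cycle(4))
  ntos <- nto_decompose(amp)
  w <- vapply(ntos$pairs, `[[`, 0, "weight")
  expect_equal(w[1], 1, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-10)

  d <- diag(c(1 / sqrt(2), 1 / sqrt(2)))
  amp <- transition_amplitudes(d, c("phenyl_1", "phenyl_2"),
                               c("phenyl_1", "phenyl_2"))
  w <- vapply(nto_decompose(amp)$pairs, `[[`, 0, "weight")
  expect_equal(w, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("weights equal the normalized eigenvalues of M M^T", {
  set.seed(31)
  m <- matrix(rnorm(40), 5, 8)
  amp <- transition_amplitudes(m, frag_cycle(5), frag_cycle(8))
  ntos <- nto_decompose(amp)
  w <- vapply(ntos$pairs, `[[`, 0, "weight")
  ev <- eigen(m %*% t(m), symmetric = TRUE)$values
  expect_equal(w, ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(w), 1, tolerance = 1e-10)
  # occupied vectors orthonormal within their set
  u <- vapply(ntos$pairs, `[[`, numeric(5), "occupied")
  expect_equal(t(u) %*% u, diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("orthogonal mixing of an orbital block preserves the spectrum", {
  set.seed(37)
  m <- matrix(rnorm(42), 6, 7)
  w0 <- vapply(nto_decompose(
    transition_amplitudes(m, frag_cycle(6), frag_cycle(7)))$pairs,
    `[[`, 0, "weight")
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  w1 <- vapply(nto_decompose(
    transition_amplitudes(q %*% m, frag_cycle(6), frag_cycle(7)))$pairs,
    `[[`, 0, "weight")
  expect_equal(w1, w0, tolerance = 1e-10)
})

test_that("zero matrices and bad fragments are rejected", {
  expect_error(transition_amplitudes(matrix(0, 2, 2), frag_cycle(2),
                                     frag_cycle(2)), "zero amplitude")
  expect_error(transition_amplitudes(diag(2), c("phenyl_1", "ring"),
                                     frag_cycle(2)), "unknown fragment")
  expect_error(transition_amplitudes(diag(2), "phenyl_1", frag_cycle(2)),
               "cover every")
})

test_that("definition cases classify as local, CT and npi*", {
  pair <- function(w, occ, virt) {
    comp <- function(frag) {
      v <- stats::setNames(numeric(5), frag_cycle(5))
      v[frag] <- 1
      v
    }
    list(weight = w, occ_composition = comp(occ),
         virt_composition = comp(virt))
  }
  expect_equal(classify_character(list(pair(1, "phenyl_1", "phenyl_1")))$label,
               "pipi*")
  expect_equal(classify_character(list(
    pair(1, "peptide_bond_2", "phenyl_1")))$label, "CT")
  expect_equal(classify_character(list(
    pair(1, "peptide_bond_1", "peptide_bond_1")))$label, "npi*_CO(1)")

  # dominant 80% keeps its label; below the 0.70 threshold it is mixed
  two <- list(pair(0.8, "peptide_bond_2", "peptide_bond_2"),
              pair(0.2, "phenyl_1", "phenyl_1"))
  lab <- classify_character(two)
  expect_equal(lab$label, "npi*_CO(2)")
  expect_equal(unname(lab$contributions["pipi*"]), 0.2)

  mixed <- list(pair(0.6, "peptide_bond_2", "peptide_bond_2"),
                pair(0.4, "phenyl_1", "phenyl_1"))
  lab <- classify_character(mixed)
  expect_equal(lab$label, "mixed")
  expect_equal(lab$dominant, "npi*_CO(2)")
  expect_equal(sum(lab$contributions), 1)

  # order permutation does not change the outcome
  lab2 <- classify_character(rev(mixed))
  expect_equal(lab2$label, lab$label)
  expect_equal(lab2$contributions, lab$contributions)

  broken <- list(list(weight = 1))
  expect_error(classify_character(broken), "fragment composition")
})

test_that("synthetic amplitude blocks round-trip through classification", {
  spec <- synthetic_spec(seed = 41)
  pure <- gen_transition_amplitudes(spec, "phenyl_1", "phenyl_1")
  expect_equal(classify_character(nto_decompose(pure$amplitudes))$label,
               "pipi*")
  ct <- gen_transition_amplitudes(spec, "peptide_bond_1", "phenyl_2")
  expect_equal(classify_character(nto_decompose(ct$amplitudes))$label, "CT")

  mix <- gen_transition_amplitudes(spec, "peptide_bond_2", "peptide_bond_2",
                                   contamination = 0.2,
                                   contam_occ = "phenyl_1",
                                   contam_virt = "phenyl_1")
  lab <- classify_character(nto_decompose(mix$amplitudes))
  expect_equal(lab$label, "npi*_CO(2)")
  expect_equal(unname(lab$contributions["npi*_CO(2)"]), 0.8,
               tolerance = 0.02)
  expect_equal(unname(lab$contributions["pipi*"]), 0.2, tolerance = 0.02)
})

test_that("amplitude CSV + fragment files read back and report", {
  dir <- withr::local_tempdir()
  m <- matrix(c(0.9, 0, 0, 0.1, 0, 0), 2, 3)
  write.table(m, file.path(dir, "amp.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE)
  writeLines(c("occ: peptide_bond_1 peptide_bond_2",
               "virt: phenyl_1 phenyl_2 other"),
             file.path(dir, "frags.txt"))
  amp <- read_amplitudes(file.path(dir, "amp.csv"),
                         file.path(dir, "frags.txt"))
  ntos <- nto_decompose(amp)
  expect_equal(classify_character(ntos)$label, "CT")
  rep_path <- file.path(dir, "nto.csv")
  write_nto_report(ntos, rep_path)
  rep <- read.csv(rep_path)
  expect_equal(rep$label[1], "CT")
  expect_true(rep$reportable[1])
})
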