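test_that("energy tables parse with missing cells as NA, never zero", {
  path <- write_lines_tmp(c(
    "system,conformer,method,e_vert_eV,e_ad_eV,e00_eV",
    "Fa,B,CC2,,,4.770",
    "Fa,A,wB97X-D,5.3,5.0,4.9"
  ))
  en <- read_energy_table(path)
  expect_s3_class(en, "energy_table")
  expect_equal(nrow(en), 2L)
  expect_equal(en$e_00[1], 4.770)
  expect_true(is.na(en$e_vert[1]) && is.na(en$e_ad[1]))
  expect_equal(en$family, c("wavefunction", "dft"))
})

test_that("energy table error paths name the offending column and row", {
  hdr_bad <- write_lines_tmp(c("system,conformer,method,e_vert_eV,e_ad_eV",
                               "Fa,A,CC2,1,2"))
  expect_error(read_energy_table(hdr_bad), "e00_eV")

  cell_bad <- write_lines_tmp(c(
    "system,conformer,method,e_vert_eV,e_ad_eV,e00_eV",
    "Fa,A,CC2,,,abc"
  ))
  expect_error(read_energy_table(cell_bad), "row 2")

  empty <- write_lines_tmp("system,conformer,method,e_vert_eV,e_ad_eV,e00_eV")
  expect_equal(nrow(read_energy_table(empty)), 0L)
})

test_that("hartree unit column converts at the CODATA factor", {
  path <- write_lines_tmp(c(
    "system,conformer,method,e_vert_eV,e_ad_eV,e00_eV,unit",
    "Fa,A,CC2,,,0.2,hartree",
    "Fa,B,CC2,,,4.770,eV"
  ))
  en <- read_energy_table(path)
  expect_equal(en$e_00, c(0.2 * 27.211386245988, 4.770))
  bad <- write_lines_tmp(c(
    "system,conformer,method,e_vert_eV,e_ad_eV,e00_eV,unit",
    "Fa,A,CC2,,,0.2,kJ"
  ))
  expect_error(read_energy_table(bad), "unit")
})

test_that("frequency tables parse, validate and round-trip", {
  path <- write_lines_tmp(c(
    paste0("system,conformer,method,state,mode_class,site_label,",
           "value_cm1,coupled,experimental_cm1"),
    "GFa,A,wB97X-D,S1,NH,NH_Phe,3440,true,",
    "GFa,A,wB97X-D,S0,NH,NH_Phe,3450.5,,3412",
    "Fa,A,CC2,S0,NH2sym,NH2_sym,3560.25,false,3480",
    "Fa,A,CC2,S1,NH2anti,NH2_anti,3640,false,",
    "Fa,B,CC2,S0,NH,NH_Phe,3425.125,false,3395"
  ))
  fr <- read_frequency_table(path)
  expect_equal(nrow(fr), 5L)
  expect_true(fr$coupled[1])
  expect_false(fr$coupled[2])  # empty cell defaults to false
  expect_true(is.na(fr$experimental[1]))

  out <- withr::local_tempfile(fileext = ".csv")
  write_frequency_table(fr, out)
  expect_equal(read_frequency_table(out), fr)
})

test_that("frequency validation rejects bad states, modes and values", {
  base <- paste0("system,conformer,method,state,mode_class,site_label,",
                 "value_cm1,coupled,experimental_cm1")
  expect_error(
    read_frequency_table(
      write_lines_tmp(c(base, "Fa,A,CC2,S0,NHx,NH_Phe,3400,false,"))),
    "NH, NH2sym, NH2anti")
  expect_error(
    read_frequency_table(
      write_lines_tmp(c(base, "Fa,A,CC2,S0,NH,NH_Phe,-10,false,"))),
    "> 0")
  expect_error(
    read_frequency_table(
      write_lines_tmp(c(base, "Fa,A,CC2,S2,NH,NH_Phe,3400,false,"))),
    "state")
})

test_that("energy table round-trip is lossless at 6+ decimals", {
  en <- make_energy_table(
    system = "SYN", conformer = c("C1", "C2"), method = "M",
    e_vert = c(5.123456789, NA), e_ad = c(4.87654321, 4.5),
    e_00 = c(4.7654321, 4.444444)
  )
  out <- withr::local_tempfile(fileext = ".csv")
  write_energy_table(en, out)
  back <- read_energy_table(out)
  expect_equal(back$e_vert, en$e_vert, tolerance = 1e-10)
  expect_equal(back$e_00, en$e_00, tolerance = 1e-10)
})

test_that("XYZ parsing validates the declared atom count", {
  water <- write_lines_tmp(c("3", "water", "O 0.0 0.0 0.0",
                             "h 0.76 0.59 0.0", "H -0.76 0.59 0.0"))
  s <- read_xyz(water)
  expect_equal(nrow(s$coords), 3L)
  expect_equal(s$elements, c("O", "H", "H"))  # symbols normalized

  short <- write_lines_tmp(c("5", "bad", "O 0 0 0", "H 1 0 0", "H 0 1 0",
                             "H 0 0 1"))
  expect_error(read_xyz(short), "declares 5")
})

test_that("a 30-atom structure round-trips within 1e-6 Angstrom", {
  set.seed(42)
  s <- make_chain_structure(30)
  s$coords <- s$coords + matrix(rnorm(90, 0, 0.01), 30, 3)
  out <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s, out)
  back <- read_xyz(out)
  expect_equal(back$elements, s$elements)
  expect_lt(max(abs(back$coords - s$coords)), 1e-6)
})

test_that("annotation files parse 0-based indices into 1-based lists", {
  ann <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("dihedral chi1: 0 1 4 7",
               "distance NH..pi: 3 12",
               "phenyl ring1: 10 11 12 13 14 15"), ann)
  a <- read_annotations(ann)
  expect_equal(a$dihedrals$chi1, c(1L, 2L, 5L, 8L))
  expect_equal(a$distances$`NH..pi`, c(4L, 13L))
  expect_equal(a$phenyl$ring1, 11:16)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("dihedral chi1: 0 1 4", bad)
  expect_error(read_annotations(bad), "4 indices")
})

test_that("bundled benchmark matches the printed tables", {
  bench <- load_bundled_benchmark()
  expect_equal(nrow(bench$conformers), 11L)
  expect_equal(sum(bench$conformers$residue_count == 1), 4L)
  expect_equal(sum(bench$conformers$residue_count == 2), 7L)

  q <- function(sys, conf, m) {
    with(bench$energies,
         e_00[system == sys & conformer == conf & method == m])
  }
  expect_equal(q("FFa", "C", "wB97X-D"), 4.219)
  expect_equal(q("QFa", "A", "experiment"), 4.662)
  expect_equal(q("Fa", "C", "experiment"), 4.663)  # default from the
  # 11-row table; the alternate printed value is kept aside:
  expect_equal(bench$alternates$value[
    bench$alternates$system == "Fa" & bench$alternates$conformer == "C"],
    4.653)

  # every method's energy rows cover all 11 conformers
  for (m in c("CC2", "wB97X-D", "P1", "P2", "experiment")) {
    expect_equal(sum(bench$energies$method == m), 11L)
  }
  expect_equal(sum(bench$energies$method == "CAM-B3LYP"), 4L)
  expect_true(all(is.finite(bench$energies$e_00)))

  # coupled flags: exactly the starred table entries
  expect_equal(sum(bench$shifts$coupled), 6L)
  expect_true(all(bench$shifts$coupled[bench$shifts$coupled] ==
                    (bench$shifts$method[bench$shifts$coupled] == "wB97X-D")))
})
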