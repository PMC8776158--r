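# In-code fixtures shared across test files.

# Non-planar helical chain structure with chain-topology annotations:
# rotations about any backbone bond move only downstream atoms.
make_chain_structure <- function(n = 12) {
  i <- seq_len(n)
  coords <- cbind(1.5 * cos(0.9 * i) + 0.2 * i,
                  1.5 * sin(0.9 * i),
                  0.35 * i)
  s <- structure(
    list(elements = rep(c("C", "N", "O"), length.out = n),
         coords = coords, comment = "synthetic chain fixture",
         annotations = list(
           dihedrals = list(phi = c(1L, 2L, 3L, 4L),
                            psi = c(4L, 5L, 6L, 7L),
                            chi = c(7L, 8L, 9L, 10L)),
           distances = list(d_end = c(1L, n), d_mid = c(3L, 8L)),
           phenyl = list(ring = c(2L, 4L, 5L, 7L, 8L, 9L))
         )),
    class = "xyz_structure")
  s
}

# Four-atom structure whose dihedral (1,2,3,4) equals phi_deg by
# construction: b2 along z, p1 on x, p4 offset by (cos, sin) in the xy plane.
make_torsion_structure <- function(phi_deg) {
  a <- phi_deg * pi / 180
  coords <- rbind(c(1, 0, 0),
                  c(0, 0, 0),
                  c(0, 0, 1),
                  c(cos(a), sin(a), 1))
  structure(list(elements = c("C", "C", "C", "C"), coords = coords,
                 comment = "torsion fixture",
                 annotations = list(dihedrals = list(tor = 1:4),
                                    distances = list(), phenyl = list())),
            class = "xyz_structure")
}

make_energy_table <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (!"family" %in% names(df)) df$family <- method_family(df$method)
  for (col in c("e_vert", "e_ad", "e_00")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  }
  df <- df[c("system", "conformer", "method", "family",
             "e_vert", "e_ad", "e_00")]
  class(df) <- c("energy_table", "data.frame")
  df
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
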