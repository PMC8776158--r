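#' @name geomcompare
#' @title Internal-coordinate comparison and rigid superposition
#'
#' @description
#' Conformer geometries optimized at different levels of theory are compared
#' on rotation-invariant internal coordinates (named dihedrals and
#' intramolecular distances from the annotation file), summarized as signed
#' deviations, MAD, range and RMSD. Rigid superposition (Kabsch, proper
#' rotation only) on an atom subset -- typically the phenyl ring -- is kept
#' separate, for overlays and subset RMSD.
NULL

#' Dihedral angle
#'
#' IUPAC sign convention: looking from atom 2 to atom 3, a clockwise
#' rotation of the 3-4 bond relative to the 1-2 bond is positive; result in
#' (-180, 180] degrees.
#'
#' @param s `xyz_structure`.
#' @param indices four distinct 1-based atom indices.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(s, indices) {
  p <- atom_coords(s, indices, 4L)
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("collinear atoms: dihedral is undefined", call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Interatomic distance
#'
#' @param s `xyz_structure`.
#' @param indices two distinct 1-based atom indices.
#' @return Euclidean distance (Angstrom).
#' @export
atom_distance <- function(s, indices) {
  p <- atom_coords(s, indices, 2L)
  sqrt(sum((p[1, ] - p[2, ])^2))
}

atom_coords <- function(s, indices, n_needed) {
  stopifnot(inherits(s, "xyz_structure"))
  indices <- as.integer(indices)
  if (length(indices) != n_needed || anyDuplicated(indices) ||
      any(indices < 1L) || any(indices > nrow(s$coords))) {
    stop("need ", n_needed, " distinct in-range atom indices", call. = FALSE)
  }
  s$coords[indices, , drop = FALSE]
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angular difference to (-180, 180]
#'
#' @param x angle difference(s), degrees.
#' @return wrapped values.
#' @export
wrap_angle <- function(x) {
  out <- (x + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

deviation_report <- function(dev, units) {
  structure(
    list(deviations = dev,
         mad = mean(abs(dev)),
         range = c(min = min(dev), max = max(dev)),
         rmsd = sqrt(mean(dev^2)),
         n = length(dev), units = units),
    class = "deviation_report"
  )
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("<deviation_report> n = ", x$n, " (", x$units, "): MAD = ",
      format(x$mad, digits = 3), ", range = [",
      format(x$range[["min"]], digits = 3), ", ",
      format(x$range[["max"]], digits = 3), "], RMSD = ",
      format(x$rmsd, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Compare two structures on their annotated internal coordinates
#'
#' Signed deviations are `b - a` per named coordinate; dihedral deviations
#' are wrapped to (-180, 180] so that 179 vs -179 counts as -2, not 358.
#'
#' @param a,b `xyz_structure`s carrying identical annotation names.
#' @return list with `deviation_report`s `$dihedrals` (degrees) and
#'   `$distances` (Angstrom); a family absent from the annotations is
#'   `NULL`.
#' @export
compare_internal_coordinates <- function(a, b) {
  stopifnot(inherits(a, "xyz_structure"), inherits(b, "xyz_structure"))
  if (is.null(a$annotations) || is.null(b$annotations)) {
    stop("both structures need annotations", call. = FALSE)
  }
  check_annotations(a); check_annotations(b)
  for (fam in c("dihedrals", "distances")) {
    mismatch <- c(setdiff(names(a$annotations[[fam]]),
                          names(b$annotations[[fam]])),
                  setdiff(names(b$annotations[[fam]]),
                          names(a$annotations[[fam]])))
    if (length(mismatch)) {
      stop("annotation mismatch in ", fam, ": ",
           paste(unique(mismatch), collapse = ", "), call. = FALSE)
    }
  }
  dih <- NULL
  if (length(a$annotations$dihedrals)) {
    nms <- names(a$annotations$dihedrals)
    dev <- vapply(nms, function(nm) {
      wrap_angle(dihedral_angle(b, b$annotations$dihedrals[[nm]]) -
                   dihedral_angle(a, a$annotations$dihedrals[[nm]]))
    }, numeric(1))
    dih <- deviation_report(dev, "degrees")
  }
  dst <- NULL
  if (length(a$annotations$distances)) {
    nms <- names(a$annotations$distances)
    dev <- vapply(nms, function(nm) {
      atom_distance(b, b$annotations$distances[[nm]]) -
        atom_distance(a, a$annotations$distances[[nm]])
    }, numeric(1))
    dst <- deviation_report(dev, "angstrom")
  }
  list(dihedrals = dih, distances = dst)
}

#' Export deviation reports to CSV
#'
#' @param reports output of [compare_internal_coordinates()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_deviation_report <- function(reports, path) {
  rows <- list()
  for (fam in names(reports)) {
    r <- reports[[fam]]
    if (is.null(r)) next
    rows[[fam]] <- data.frame(
      family = fam, coordinate = names(r$deviations),
      deviation = unname(r$deviations), units = r$units,
      mad = r$mad, range_min = r$range[["min"]], range_max = r$range[["max"]],
      rmsd = r$rmsd, stringsAsFactors = FALSE
    )
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Kabsch rigid superposition on an atom subset
#'
#' Least-squares proper rotation (determinant +1: mirror images are
#' rejected, preserving chirality) plus translation mapping the subset of
#' `b` onto the subset of `a`.
#'
#' @param a,b `xyz_structure`s; subsets must have matched atom order.
#' @param subset 1-based atom indices (>= 3 non-collinear atoms); defaults
#'   to the first phenyl annotation of `a` when present.
#' @return list: `rotation` (3x3), `translation` (length-3; the transform is
#'   `x %*% t(rotation) + translation`), `rmsd` over the subset (Angstrom),
#'   `transformed` (all of `b`'s coordinates, transformed).
#' @export
kabsch_superpose <- function(a, b, subset = NULL) {
  stopifnot(inherits(a, "xyz_structure"), inherits(b, "xyz_structure"))
  if (is.null(subset)) {
    if (is.null(a$annotations) || !length(a$annotations$phenyl)) {
      stop("no subset given and no phenyl annotation available",
           call. = FALSE)
    }
    subset <- a$annotations$phenyl[[1]]
  }
  subset <- as.integer(subset)
  if (length(subset) < 3L || any(subset < 1L) ||
      any(subset > nrow(a$coords)) || any(subset > nrow(b$coords))) {
    stop("subset must hold >= 3 valid atom indices", call. = FALSE)
  }
  pa <- a$coords[subset, , drop = FALSE]
  pb <- b$coords[subset, , drop = FALSE]
  ca <- colMeans(pa)
  cb <- colMeans(pb)
  qa <- sweep(pa, 2, ca)
  qb <- sweep(pb, 2, cb)
  # collinearity: rank of the centered subset < 2
  if (svd(qa)$d[2] < 1e-8 || svd(qb)$d[2] < 1e-8) {
    stop("degenerate (collinear) superposition subset", call. = FALSE)
  }
  h <- t(qb) %*% qa
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ca - as.vector(rot %*% cb)
  fit <- sweep(qb %*% t(rot), 2, ca, `+`)
  rmsd <- sqrt(mean(rowSums((fit - pa)^2)))
  transformed <- sweep(b$coords %*% t(rot), 2, trans, `+`)
  list(rotation = rot, translation = trans, rmsd = rmsd,
       transformed = transformed)
}
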