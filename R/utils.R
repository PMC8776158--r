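#' Round half away from zero
#'
#' Reporting convention used throughout: `round()` in base R rounds halves to
#' even, while the printed benchmark tables round halves away from zero
#' (e.g. 0.025 eV -> 0.03, -37.5 cm^-1 -> -38).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector rounded half-away-from-zero.
#' @export
#' @examples
#' round_half_away(c(0.025, -0.025), 2)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# eV per hartree (CODATA 2018)
EV_PER_HARTREE <- 27.211386245988

#' Parse a plain-text key-value file
#'
#' Lines of the form `key: value` (or `key = value`); blank lines and lines
#' starting with `#` are ignored. Used for protocol definitions, geometry
#' annotations, scaling-function serialization and synthetic-run specs.
#'
#' @param path file path.
#' @return named character vector.
#' @export
read_keyvalue <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regexpr("[:=]", lines)
  if (any(m < 0)) {
    stop("malformed key-value line: ", lines[which(m < 0)[1]], call. = FALSE)
  }
  keys <- trimws(substr(lines, 1L, m - 1L))
  vals <- trimws(substr(lines, m + 1L, nchar(lines)))
  stats::setNames(vals, keys)
}

#' Write a plain-text key-value file
#'
#' @param x named vector or list of scalars.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_keyvalue <- function(x, path) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  writeLines(paste0(names(x), ": ", vapply(x, format, "")), path)
  invisible(path)
}

# Internal: check scalar finiteness with a contextual error.
check_finite <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop("missing or non-finite ", what, call. = FALSE)
  }
  invisible(x)
}
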