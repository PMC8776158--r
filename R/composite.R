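#' @name composite
#' @title Composite 0-0 excitation-energy assembly
#'
#' @description
#' The adiabatic ZPVE-corrected excitation energy decomposes as
#' \deqn{\Delta E_{00} = \Delta E_v + \Delta\Delta E_{ad} + \Delta\Delta E_{00}}
#' with \eqn{\Delta\Delta E_{ad} = \Delta E_{ad} - \Delta E_v} (excited-state
#' relaxation) and \eqn{\Delta\Delta E_{00} = \Delta E_{00} - \Delta E_{ad}}
#' (S1-S0 ZPVE difference). A composite protocol takes each term from a
#' possibly different electronic-structure method: the bundled P1 takes only
#' \eqn{\Delta E_v} from the wavefunction (CC2) level, P2 takes
#' \eqn{\Delta E_v} and the relaxation term from CC2 and only the ZPVE term
#' from DFT/TD-DFT.
NULL

#' Excited-state relaxation term
#'
#' @param e_ad adiabatic energy difference (eV).
#' @param e_vert vertical excitation energy (eV).
#' @return `e_ad - e_vert` (eV); typically negative.
#' @export
delta_delta_ad <- function(e_ad, e_vert) {
  check_finite(e_ad, "adiabatic energy (e_ad)")
  check_finite(e_vert, "vertical excitation energy (e_vert)")
  e_ad - e_vert
}

#' S1-S0 ZPVE difference term
#'
#' @param e_00 ZPVE-corrected 0-0 energy (eV).
#' @param e_ad adiabatic energy difference (eV).
#' @return `e_00 - e_ad` (eV).
#' @export
delta_delta_00 <- function(e_00, e_ad) {
  check_finite(e_00, "0-0 energy (e_00)")
  check_finite(e_ad, "adiabatic energy (e_ad)")
  e_00 - e_ad
}

#' Define a composite protocol
#'
#' @param name protocol label.
#' @param e_vert_source method supplying the vertical excitation energy.
#' @param dd_ad_source method supplying the relaxation term
#'   (needs that method's `e_vert` and `e_ad`).
#' @param dd_00_source method supplying the ZPVE term
#'   (needs that method's `e_ad` and `e_00`).
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(name, e_vert_source, dd_ad_source, dd_00_source) {
  stopifnot(is.character(name), nzchar(name),
            nzchar(e_vert_source), nzchar(dd_ad_source), nzchar(dd_00_source))
  structure(list(name = name,
                 e_vert_source = e_vert_source,
                 dd_ad_source = dd_ad_source,
                 dd_00_source = dd_00_source),
            class = "protocol_spec")
}

#' Read a protocol definition file
#'
#' Key-value text with keys `name`, `e_vert_source`, `dd_ad_source`,
#' `dd_00_source`.
#'
#' @param path file path.
#' @return `protocol_spec`.
#' @export
read_protocol <- function(path) {
  kv <- read_keyvalue(path)
  need <- c("name", "e_vert_source", "dd_ad_source", "dd_00_source")
  missing <- setdiff(need, names(kv))
  if (length(missing)) {
    stop("protocol file missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  protocol_spec(kv[["name"]], kv[["e_vert_source"]], kv[["dd_ad_source"]],
                kv[["dd_00_source"]])
}

#' Bundled protocol definitions
#'
#' @param name `"P1"` or `"P2"`; the DFT/TD-DFT placeholder source is
#'   resolved to `dft_method`.
#' @param dft_method concrete DFT/TD-DFT method label (default `"wB97X-D"`).
#' @return `protocol_spec`.
#' @export
bundled_protocol <- function(name = c("P1", "P2"), dft_method = "wB97X-D") {
  name <- match.arg(name)
  p <- read_protocol(system.file("extdata", "protocols",
                                 paste0(name, ".txt"),
                                 package = "excitbench", mustWork = TRUE))
  for (f in c("e_vert_source", "dd_ad_source", "dd_00_source")) {
    if (p[[f]] == "DFT/TD-DFT") p[[f]] <- dft_method
  }
  p
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec> ", x$name, ": e_vert(", x$e_vert_source,
      ") + dd_ad(", x$dd_ad_source, ") + dd_00(", x$dd_00_source, ")\n",
      sep = "")
  invisible(x)
}

need_term <- function(energies, system, conformer, method, field, term) {
  row <- energies[energies$system == system &
                    energies$conformer == conformer &
                    energies$method == method, , drop = FALSE]
  if (nrow(row) == 0L || is.na(row[[field]][1])) {
    stop("missing term '", term, "': method '", method, "' has no ", field,
         " for conformer ", system, " ", conformer, call. = FALSE)
  }
  row[[field]][1]
}

#' Assemble a composite 0-0 excitation energy
#'
#' Evaluates \eqn{\Delta E_{00} = \Delta E_v(\mathrm{src_1}) +
#' [\Delta E_{ad}-\Delta E_v](\mathrm{src_2}) +
#' [\Delta E_{00}-\Delta E_{ad}](\mathrm{src_3})} for one conformer.
#' Any missing input field is a hard error: a composite energy with a
#' silently substituted term would be a different protocol.
#'
#' @param protocol `protocol_spec`.
#' @param energies `energy_table` holding one row per (conformer, method)
#'   with the needed fields.
#' @param system,conformer conformer identity.
#' @return object of class `composite_result`: `e_00` plus a `terms`
#'   data.frame audit trail (term, source method, value in eV).
#' @export
assemble_composite <- function(protocol, energies, system, conformer) {
  stopifnot(inherits(protocol, "protocol_spec"))
  e_vert <- need_term(energies, system, conformer, protocol$e_vert_source,
                      "e_vert", "e_vert")
  dd_ad <- delta_delta_ad(
    need_term(energies, system, conformer, protocol$dd_ad_source,
              "e_ad", "dd_ad"),
    need_term(energies, system, conformer, protocol$dd_ad_source,
              "e_vert", "dd_ad")
  )
  dd_00 <- delta_delta_00(
    need_term(energies, system, conformer, protocol$dd_00_source,
              "e_00", "dd_00"),
    need_term(energies, system, conformer, protocol$dd_00_source,
              "e_ad", "dd_00")
  )
  terms <- data.frame(
    term = c("e_vert", "dd_ad", "dd_00"),
    source = c(protocol$e_vert_source, protocol$dd_ad_source,
               protocol$dd_00_source),
    value_eV = c(e_vert, dd_ad, dd_00),
    stringsAsFactors = FALSE
  )
  structure(
    list(system = system, conformer = conformer, protocol = protocol,
         e_00 = e_vert + dd_ad + dd_00, terms = terms),
    class = "composite_result"
  )
}

#' @export
print.composite_result <- function(x, ...) {
  cat("<composite_result> ", x$protocol$name, " ", x$system, " ",
      x$conformer, ": e_00 = ", format(x$e_00, digits = 10), " eV\n",
      sep = "")
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Assemble a protocol over every conformer of an energy table
#'
#' @inheritParams assemble_composite
#' @return `energy_table` rows with `method = protocol$name` and assembled
#'   `e_00` (terms dropped; use [assemble_composite()] for the audit trail).
#' @export
assemble_all <- function(protocol, energies) {
  key <- unique(energies[c("system", "conformer")])
  res <- lapply(seq_len(nrow(key)), function(i) {
    r <- assemble_composite(protocol, energies, key$system[i],
                            key$conformer[i])
    data.frame(system = r$system, conformer = r$conformer,
               method = protocol$name,
               family = "composite",
               e_vert = NA_real_, e_ad = NA_real_, e_00 = r$e_00,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("energy_table", "data.frame")
  out
}
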