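#' @name statechar
#' @title Natural transition orbitals and excited-state character
#'
#' @description
#' A singlet excitation described by an occupied x virtual transition
#' amplitude matrix is compacted by singular value decomposition into
#' natural transition orbital (NTO) pairs; the squared singular values of
#' the Frobenius-normalized matrix are the pair weights and sum to one.
#' With a fragment label per orbital (phenyl rings, peptide bonds, other),
#' each NTO pair classifies as locally pipi* (hole and particle on the same
#' phenyl), npi*_CO(k) (both on peptide bond k), or charge transfer
#' (backbone hole, phenyl particle); the weight-averaged contributions give
#' the state label, `mixed` when no character dominates.
NULL

FRAGMENT_VOCAB <- c("phenyl_1", "phenyl_2", "peptide_bond_1",
                    "peptide_bond_2", "other")

#' Construct a transition-amplitude object
#'
#' @param matrix numeric occupied x virtual amplitude matrix (nonzero).
#' @param occ_fragments fragment label per occupied orbital (row).
#' @param virt_fragments fragment label per virtual orbital (column).
#' @return object of class `transition_amplitudes`.
#' @export
transition_amplitudes <- function(matrix, occ_fragments, virt_fragments) {
  matrix <- as.matrix(matrix)
  stopifnot(is.numeric(matrix), all(is.finite(matrix)))
  if (length(occ_fragments) != nrow(matrix) ||
      length(virt_fragments) != ncol(matrix)) {
    stop("fragment labels must cover every occupied/virtual orbital",
         call. = FALSE)
  }
  bad <- setdiff(c(occ_fragments, virt_fragments), FRAGMENT_VOCAB)
  if (length(bad)) {
    stop("unknown fragment label(s): ", paste(unique(bad), collapse = ", "),
         "; allowed: ", paste(FRAGMENT_VOCAB, collapse = ", "),
         call. = FALSE)
  }
  if (sqrt(sum(matrix^2)) <= 0) {
    stop("zero amplitude matrix: decomposition undefined", call. = FALSE)
  }
  structure(list(matrix = matrix, occ_fragments = occ_fragments,
                 virt_fragments = virt_fragments),
            class = "transition_amplitudes")
}

#' Read a transition-amplitude matrix with fragment assignments
#'
#' The matrix is a headerless CSV of numbers (rows = occupied orbitals);
#' the fragment file is key-value text with keys `occ` and `virt`, each a
#' space-separated fragment label list.
#'
#' @param matrix_path CSV matrix path.
#' @param fragments_path key-value fragment file path.
#' @return `transition_amplitudes`.
#' @export
read_amplitudes <- function(matrix_path, fragments_path) {
  m <- as.matrix(utils::read.csv(matrix_path, header = FALSE))
  dimnames(m) <- NULL
  kv <- read_keyvalue(fragments_path)
  if (!all(c("occ", "virt") %in% names(kv))) {
    stop("fragment file needs keys 'occ' and 'virt'", call. = FALSE)
  }
  transition_amplitudes(
    m,
    strsplit(trimws(kv[["occ"]]), "[[:space:]]+")[[1]],
    strsplit(trimws(kv[["virt"]]), "[[:space:]]+")[[1]]
  )
}

fragment_composition <- function(vec, fragments) {
  w <- vec^2
  comp <- vapply(split(w, factor(fragments, levels = FRAGMENT_VOCAB)), sum,
                 0)
  comp / sum(comp)
}

#' Decompose transition amplitudes into NTO pairs
#'
#' SVD of the amplitude matrix after Frobenius normalization; pair weights
#' are squared singular values (descending, summing to 1). Pairs whose
#' weight exceeds `threshold` are flagged `reportable`, the printed-table
#' convention.
#'
#' @param t `transition_amplitudes`.
#' @param threshold reportable-weight threshold (default 0.10).
#' @return object of class `nto_decomposition`: list of pairs, each with
#'   `weight`, `occupied`/`virtual` vectors (orthonormal within their set),
#'   fragment compositions, `reportable` flag.
#' @export
nto_decompose <- function(t, threshold = 0.10) {
  stopifnot(inherits(t, "transition_amplitudes"))
  m <- t$matrix / sqrt(sum(t$matrix^2))
  sv <- svd(m)
  weights <- sv$d^2
  pairs <- lapply(seq_along(weights), function(i) {
    list(weight = weights[i],
         occupied = sv$u[, i],
         virtual = sv$v[, i],
         occ_composition = fragment_composition(sv$u[, i], t$occ_fragments),
         virt_composition = fragment_composition(sv$v[, i],
                                                 t$virt_fragments),
         reportable = weights[i] > threshold)
  })
  structure(list(pairs = pairs, threshold = threshold),
            class = "nto_decomposition")
}

#' @export
print.nto_decomposition <- function(x, ...) {
  cat("<nto_decomposition> ", length(x$pairs), " pairs; reportable (> ",
      format(100 * x$threshold), "%): ",
      paste(sprintf("%.0f%%",
                    100 * vapply(Filter(function(p) p$reportable, x$pairs),
                                 `[[`, 0, "weight")), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

dominant_fragment <- function(comp) names(comp)[which.max(comp)]

classify_pair <- function(p) {
  occ <- dominant_fragment(p$occ_composition)
  virt <- dominant_fragment(p$virt_composition)
  if (startsWith(occ, "phenyl") && identical(occ, virt)) {
    "pipi*"
  } else if (startsWith(occ, "peptide_bond") && identical(occ, virt)) {
    paste0("npi*_CO(", sub("peptide_bond_", "", occ), ")")
  } else if (startsWith(occ, "peptide_bond") && startsWith(virt, "phenyl")) {
    "CT"
  } else {
    "other"
  }
}

#' Classify excited-state character from NTO pairs
#'
#' Each pair is labeled from its dominant hole/particle fragments; the
#' state-level contributions are the weight-renormalized per-character
#' sums. When the dominant character holds less than `mixed_threshold` of
#' the total, the label is `"mixed"` and the dominant character is reported
#' separately.
#'
#' @param ntos `nto_decomposition` (or list of pairs with weights and
#'   fragment compositions).
#' @param mixed_threshold dominance fraction below which the state is
#'   labeled mixed (default 0.70).
#' @return object of class `character_label`: `label`, `dominant`,
#'   `contributions` (named fractions summing to 1).
#' @export
classify_character <- function(ntos, mixed_threshold = 0.70) {
  pairs <- if (inherits(ntos, "nto_decomposition")) ntos$pairs else ntos
  if (!length(pairs)) stop("no NTO pairs to classify", call. = FALSE)
  for (p in pairs) {
    if (is.null(p$occ_composition) || is.null(p$virt_composition)) {
      stop("missing fragment composition on an NTO pair", call. = FALSE)
    }
  }
  w <- vapply(pairs, `[[`, 0, "weight")
  lab <- vapply(pairs, classify_pair, "")
  contrib <- vapply(split(w, lab), sum, 0)
  contrib <- sort(contrib / sum(contrib), decreasing = TRUE)
  dominant <- names(contrib)[1]
  label <- if (contrib[[1]] < mixed_threshold) "mixed" else dominant
  structure(list(label = label, dominant = dominant,
                 contributions = contrib),
            class = "character_label")
}

#' @export
print.character_label <- function(x, ...) {
  cat("<character_label> ", x$label,
      if (x$label == "mixed") paste0(" (dominant ", x$dominant, ")") else "",
      ": ", paste(sprintf("%s %.0f%%", names(x$contributions),
                          100 * x$contributions), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write an NTO report CSV
#'
#' One row per pair: weight, dominant hole/particle fragments, pair label,
#' reportable flag.
#'
#' @param ntos `nto_decomposition`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nto_report <- function(ntos, path) {
  stopifnot(inherits(ntos, "nto_decomposition"))
  df <- do.call(rbind, lapply(seq_along(ntos$pairs), function(i) {
    p <- ntos$pairs[[i]]
    data.frame(pair = i, weight = p$weight,
               occ_fragment = dominant_fragment(p$occ_composition),
               virt_fragment = dominant_fragment(p$virt_composition),
               label = classify_pair(p), reportable = p$reportable,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
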