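#' @name freqscale
#' @title Mode-dependent harmonic-frequency scaling and S1-S0 shifts
#'
#' @description
#' Harmonic N-H stretch (amide A) frequencies computed at correlated or
#' TD-DFT levels overestimate experiment through method, basis-set and
#' anharmonicity errors. A linear scaling function
#' \eqn{\nu_{exp} = a\,\nu_{theo} + b} is fitted per mode class (single N-H
#' stretch `NH`, symmetric `NH2sym` and antisymmetric `NH2anti` NH2
#' stretches) and per electronic state (S0 calibration set vs S1), and
#' applied to absolute frequencies before differencing, giving
#' mode-dependent corrected S1-S0 shifts.
NULL

#' Fit a linear frequency scaling function
#'
#' Ordinary least squares of experimental on theoretical harmonic
#' frequencies.
#'
#' @param nu_theo theoretical harmonic frequencies (cm^-1), length >= 2 with
#'   at least two distinct values.
#' @param nu_exp matched experimental frequencies (cm^-1).
#' @param mode_class one of `"NH"`, `"NH2sym"`, `"NH2anti"`.
#' @param state `"S0"` or `"S1"`.
#' @param method optional method tag (fits are method-specific).
#' @return object of class `scaling_function` with fields `a`, `b`,
#'   `n_points`, `rmse` (cm^-1), `se_a`, `se_b` (standard errors; `NA` for
#'   an exact two-point fit).
#' @export
fit_scaling <- function(nu_theo, nu_exp,
                        mode_class = c("NH", "NH2sym", "NH2anti"),
                        state = c("S0", "S1"), method = NA_character_) {
  mode_class <- match.arg(mode_class)
  state <- match.arg(state)
  ok <- is.finite(nu_theo) & is.finite(nu_exp)
  nu_theo <- nu_theo[ok]
  nu_exp <- nu_exp[ok]
  if (length(nu_theo) < 2L || length(unique(nu_theo)) < 2L) {
    stop("scaling fit needs >= 2 points with distinct nu_theo values",
         call. = FALSE)
  }
  fit <- stats::lm(nu_exp ~ nu_theo)
  co <- stats::coef(fit)
  a <- unname(co["nu_theo"])
  b <- unname(co["(Intercept)"])
  if (a <= 0) {
    warning("fitted slope a = ", format(a),
            " is not positive; scaling function is physically suspect")
  }
  # closed-form OLS standard errors (avoids summary.lm's perfect-fit warning)
  se <- if (length(nu_theo) > 2L) {
    n <- length(nu_theo)
    s2 <- sum(stats::residuals(fit)^2) / (n - 2)
    sxx <- sum((nu_theo - mean(nu_theo))^2)
    c(sqrt(s2 * (1 / n + mean(nu_theo)^2 / sxx)), sqrt(s2 / sxx))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(mode_class = mode_class, state = state, method = method,
         a = a, b = b, n_points = length(nu_theo),
         rmse = sqrt(mean(stats::residuals(fit)^2)),
         se_a = unname(se[2]), se_b = unname(se[1])),
    class = "scaling_function"
  )
}

#' Construct a scaling function from known coefficients
#'
#' @param a slope (dimensionless). @param b intercept (cm^-1).
#' @inheritParams fit_scaling
#' @return `scaling_function`.
#' @export
scaling_function <- function(a, b, mode_class = c("NH", "NH2sym", "NH2anti"),
                             state = c("S0", "S1"),
                             method = NA_character_) {
  structure(list(mode_class = match.arg(mode_class),
                 state = match.arg(state), method = method,
                 a = a, b = b, n_points = NA_integer_, rmse = NA_real_,
                 se_a = NA_real_, se_b = NA_real_),
            class = "scaling_function")
}

#' @export
print.scaling_function <- function(x, ...) {
  cat("<scaling_function> ", x$mode_class, "/", x$state,
      if (!is.na(x$method)) paste0("/", x$method) else "",
      ": nu_exp = ", format(x$a, digits = 6), " * nu_theo + ",
      format(x$b, digits = 6),
      if (!is.na(x$n_points)) paste0("  (n = ", x$n_points, ", rmse = ",
                                     format(x$rmse, digits = 3), " cm-1)")
      else "", "\n", sep = "")
  invisible(x)
}

#' Apply a scaling function to a harmonic frequency
#'
#' @param f `scaling_function`.
#' @param nu harmonic frequency (cm^-1), > 0.
#' @param mode_class optional mode class of the record being corrected; if
#'   supplied and different from `f$mode_class`, an error is raised.
#' @return corrected frequency `a * nu + b` (cm^-1), unrounded.
#' @export
apply_scaling <- function(f, nu, mode_class = NULL) {
  stopifnot(inherits(f, "scaling_function"))
  if (any(!is.finite(nu) | nu <= 0)) {
    stop("frequency must be positive and finite", call. = FALSE)
  }
  if (!is.null(mode_class) && !identical(mode_class, f$mode_class)) {
    stop("scaling function is for mode class '", f$mode_class,
         "' but the record is '", mode_class, "'", call. = FALSE)
  }
  f$a * nu + f$b
}

#' Serialize / deserialize a scaling function
#'
#' Key-value text with keys `mode_class`, `state`, `method`, `a`, `b`,
#' `n_points`, `rmse`.
#'
#' @param f `scaling_function`. @param path file path.
#' @return `path` / `scaling_function`.
#' @export
write_scaling <- function(f, path) {
  stopifnot(inherits(f, "scaling_function"))
  write_keyvalue(list(
    mode_class = f$mode_class, state = f$state,
    method = if (is.na(f$method)) "NA" else f$method,
    a = format(f$a, digits = 15), b = format(f$b, digits = 15),
    n_points = f$n_points, rmse = format(f$rmse, digits = 15)
  ), path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  kv <- read_keyvalue(path)
  f <- scaling_function(as.numeric(kv[["a"]]), as.numeric(kv[["b"]]),
                        kv[["mode_class"]], kv[["state"]],
                        if (identical(kv[["method"]], "NA")) NA_character_
                        else kv[["method"]])
  f$n_points <- as.integer(kv[["n_points"]])
  f$rmse <- as.numeric(kv[["rmse"]])
  f
}

#' S1-S0 frequency shift, harmonic and mode-dependent corrected
#'
#' The harmonic shift is `nu_S1 - nu_S0` (red shift negative); the corrected
#' shift applies the state-specific scaling functions to the absolute
#' frequencies first and then differences. Both are rounded
#' half-away-from-zero to integer cm^-1, the printing convention of
#' benchmark shift tables; unrounded values are kept alongside.
#'
#' @param nu_s1,nu_s0 harmonic frequencies (cm^-1), > 0.
#' @param f_s1,f_s0 `scaling_function`s for S1 and S0, either both given or
#'   both `NULL`.
#' @return list with `harmonic_shift`, `corrected_shift` (integer cm^-1, the
#'   latter `NA` without scaling functions) and unrounded `harmonic_raw`,
#'   `corrected_raw`.
#' @export
compute_shift <- function(nu_s1, nu_s0, f_s1 = NULL, f_s0 = NULL) {
  if (any(!is.finite(c(nu_s1, nu_s0))) || nu_s1 <= 0 || nu_s0 <= 0) {
    stop("frequencies must be positive and finite", call. = FALSE)
  }
  if (is.null(f_s1) != is.null(f_s0)) {
    stop("scaling functions must be given for both states or neither",
         call. = FALSE)
  }
  harm <- nu_s1 - nu_s0
  corr <- if (!is.null(f_s1)) {
    apply_scaling(f_s1, nu_s1) - apply_scaling(f_s0, nu_s0)
  } else {
    NA_real_
  }
  list(harmonic_shift = as.integer(round_half_away(harm)),
       corrected_shift = if (is.na(corr)) NA_integer_
                         else as.integer(round_half_away(corr)),
       harmonic_raw = harm, corrected_raw = corr)
}

#' RMSD between predicted and observed shifts
#'
#' @param predicted,observed equal-length shift vectors (cm^-1); pairs with
#'   a missing side are dropped here with a count.
#' @return list with `rmsd` (unrounded, cm^-1), `rmsd_rounded` (integer),
#'   `n`, `n_dropped`.
#' @export
shift_rmsd <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed shift vectors differ in length",
         call. = FALSE)
  }
  ok <- is.finite(predicted) & is.finite(observed)
  if (!any(ok)) {
    stop("empty comparison: no overlapping predicted/observed shift pairs",
         call. = FALSE)
  }
  d <- predicted[ok] - observed[ok]
  rmsd <- sqrt(mean(d^2))
  list(rmsd = rmsd, rmsd_rounded = as.integer(round_half_away(rmsd)),
       n = sum(ok), n_dropped = sum(!ok))
}

#' RMSD of bundled corrected shifts against experiment
#'
#' Convenience wrapper over the bundled amide-A shift table: selects one
#' method's mode-dependent corrected shifts that have experimental
#' counterparts and computes [shift_rmsd()].
#'
#' @param bench dataset from [load_bundled_benchmark()].
#' @param method method label (default `"wB97X-D"`).
#' @param systems restrict to these systems (default: the capped dipeptide
#'   series, i.e. everything but the one-residue reference system `Fa`).
#' @param include_coupled keep modes flagged as coupled (default `TRUE`,
#'   the printed-table convention).
#' @return as [shift_rmsd()].
#' @export
bundled_shift_rmsd <- function(bench = load_bundled_benchmark(),
                               method = "wB97X-D",
                               systems = c("GFa", "FFa", "QFa"),
                               include_coupled = TRUE) {
  sh <- bench$shifts
  sh <- sh[sh$method == method & sh$system %in% systems, , drop = FALSE]
  if (!include_coupled) sh <- sh[!sh$coupled, , drop = FALSE]
  shift_rmsd(sh$corrected_shift, sh$experimental_shift)
}
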