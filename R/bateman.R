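# Analytic kinetics of the irreversible sequential photocycle chain
# (first intermediate at unit concentration at t = 0, each species decaying
# into the next with rate 1/tau) and the linear maps between species- and
# decay-associated difference spectra.

#' Sequential photocycle scheme
#'
#' An irreversible chain of photointermediates (e.g. K -> L -> O -> ground),
#' each decaying first-order with its own time constant.
#'
#' @param labels intermediate names in chain order.
#' @param tau_s decay time constants, seconds, strictly positive, one per
#'   intermediate.
#' @return object of class `sequential_scheme`.
#' @export
sequential_scheme <- function(labels, tau_s) {
  if (!is.numeric(tau_s) || any(!is.finite(tau_s)) || any(tau_s <= 0)) {
    fail_field("tau_s", "must be strictly positive")
  }
  if (length(labels) != length(tau_s)) {
    fail_field("labels", "must match the number of time constants")
  }
  structure(list(labels = as.character(labels), tau_s = as.numeric(tau_s)),
            class = "sequential_scheme")
}

#' @export
print.sequential_scheme <- function(x, ...) {
  cat("Sequential scheme:",
      paste(sprintf("%s (tau %.4g ms)", x$labels, 1000 * x$tau_s),
            collapse = " -> "),
      "-> ground\n")
  invisible(x)
}

# Exponential-basis coefficients of the Bateman solution: A[j, i] is the
# coefficient of exp(-k_i t) in c_j(t), lower triangular. Exactly coincident
# rates are split by a 1e-9 relative nudge (the closed form is stable for
# merely near-equal rates).
bateman_coefficients <- function(tau_s) {
  k <- 1 / tau_s
  n <- length(k)
  if (n > 1) {
    repeat {
      d <- abs(outer(k, k, "-")) / max(k)
      diag(d) <- Inf
      if (min(d) > 1e-12) break
      dup <- which(d == min(d), arr.ind = TRUE)[1, ]
      k[dup[1]] <- k[dup[1]] * (1 + 1e-9)
      k[dup[2]] <- k[dup[2]] * (1 - 1e-9)
    }
  }
  A <- matrix(0, n, n)
  A[1, 1] <- 1
  if (n > 1) {
    for (j in 2:n) {
      pref <- prod(k[1:(j - 1)])
      for (i in 1:j) {
        A[j, i] <- pref / prod(k[setdiff(1:j, i)] - k[i])
      }
    }
  }
  list(A = A, k = k)
}

#' Bateman concentrations of a sequential chain
#'
#' Closed-form concentrations of each intermediate in the irreversible
#' sequential scheme: `c_1(t) = exp(-t/tau_1)`, and for `j > 1`
#' `dc_j/dt = c_{j-1}/tau_{j-1} - c_j/tau_j` with `c_j(0) = 0`.
#'
#' @param scheme a [sequential_scheme()].
#' @param times_s nonnegative times, seconds.
#' @return matrix `[species x time]` of concentrations in `[0, 1]`.
#' @examples
#' sch <- sequential_scheme(c("K", "L"), c(1, 2))
#' bateman_concentrations(sch, c(0, 1, 2))
#' @export
bateman_concentrations <- function(scheme, times_s) {
  stopifnot(inherits(scheme, "sequential_scheme"))
  if (!is.numeric(times_s) || any(!is.finite(times_s)) || any(times_s < 0)) {
    fail_field("times_s", "must be finite and >= 0")
  }
  bc <- bateman_coefficients(scheme$tau_s)
  # E[i, t] = exp(-k_i t); concentrations = A %*% E
  E <- exp(-outer(bc$k, times_s))
  out <- bc$A %*% E
  rownames(out) <- scheme$labels
  out
}

#' Noiseless forward model of a sequential photocycle
#'
#' `deltaA(lambda, t) = sum_j sads[, j] * c_j(t)` with Bateman
#' concentrations; exact, no noise.
#'
#' @param scheme a [sequential_scheme()].
#' @param sads matrix `[wavelength x species]` of species-associated
#'   difference spectra.
#' @param wavelengths_nm ascending wavelength grid matching `nrow(sads)`.
#' @param times_s strictly ascending positive times.
#' @return a [transient_dataset()].
#' @export
forward_model <- function(scheme, sads, wavelengths_nm, times_s) {
  stopifnot(inherits(scheme, "sequential_scheme"))
  sads <- as.matrix(sads)
  if (ncol(sads) != length(scheme$tau_s)) {
    fail_field("sads", "column count must equal the number of species")
  }
  if (nrow(sads) != length(wavelengths_nm)) {
    fail_field("sads", "row count must match the wavelength grid")
  }
  conc <- bateman_concentrations(scheme, times_s)
  transient_dataset(wavelengths_nm, times_s, sads %*% conc)
}

check_distinct_taus <- function(tau_s, what) {
  k <- 1 / tau_s
  if (length(k) > 1) {
    d <- abs(outer(k, k, "-")) / max(k)
    diag(d) <- Inf
    if (min(d) <= 1e-9) {
      stop(sprintf(paste("%s: coincident time constants make the transform",
                         "singular; perturb the taus or use the degenerate",
                         "(nudged) Bateman path via bateman_concentrations()"),
                   what), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Convert species-associated to decay-associated difference spectra
#'
#' Expanding the Bateman concentrations in the exponential basis
#' `exp(-t/tau_i)` turns the species representation into the decay
#' representation: `DADS = SADS %*% A`, where `A[j, i]` is the coefficient of
#' `exp(-k_i t)` in `c_j(t)`. The two representations reconstruct the same
#' matrix.
#'
#' @param scheme a [sequential_scheme()] with distinct time constants.
#' @param sads matrix `[wavelength x species]`.
#' @return dads matrix `[wavelength x n_exp]`.
#' @export
dads_from_sads <- function(scheme, sads) {
  stopifnot(inherits(scheme, "sequential_scheme"))
  check_distinct_taus(scheme$tau_s, "dads_from_sads")
  sads <- as.matrix(sads)
  if (ncol(sads) != length(scheme$tau_s)) {
    fail_field("sads", "column count must equal the number of species")
  }
  sads %*% bateman_coefficients(scheme$tau_s)$A
}

#' Convert decay-associated to species-associated difference spectra
#'
#' Inverse of [dads_from_sads()]; the round trip is the identity.
#'
#' @param scheme a [sequential_scheme()] with distinct time constants.
#' @param dads matrix `[wavelength x n_exp]`.
#' @return sads matrix `[wavelength x species]`.
#' @export
sads_from_dads <- function(scheme, dads) {
  stopifnot(inherits(scheme, "sequential_scheme"))
  check_distinct_taus(scheme$tau_s, "sads_from_dads")
  dads <- as.matrix(dads)
  if (ncol(dads) != length(scheme$tau_s)) {
    fail_field("dads", "column count must equal the number of exponentials")
  }
  dads %*% solve(bateman_coefficients(scheme$tau_s)$A)
}
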