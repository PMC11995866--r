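# Global multi-exponential fitting of transient absorption matrices by
# variable projection: the shared time constants are optimized nonlinearly
# while the per-wavelength amplitudes (DADS) are solved exactly as the
# conditionally linear subproblem at every step.

# rss of the variable-projection objective at log-taus, plus the solved
# DADS. A component that has fully decayed before the first observation (or
# a numerically collinear basis) is rejected: it could otherwise soak up
# noise with unbounded amplitudes.
vp_solve <- function(log_tau, Y, times_s) {
  tau <- exp(log_tau)
  E <- exp(-outer(times_s, 1 / tau))        # [time x n_exp]
  if (any(apply(E, 2, max) < 1e-3)) {
    return(list(rss = Inf, dads = NULL, E = E))
  }
  qe <- qr(E)
  if (qe$rank < length(tau)) {
    return(list(rss = Inf, dads = NULL, E = E))
  }
  coef <- qr.coef(qe, t(Y))                 # [n_exp x wavelength]
  resid <- t(Y) - E %*% coef
  list(rss = sum(resid * resid), dads = t(coef), E = E)
}

vp_rss <- function(log_tau, Y, times_s) vp_solve(log_tau, Y, times_s)$rss

# Deterministic multi-start grid: n_exp log-spaced taus placed at various
# quantile spans of the observed time range.
default_starts <- function(times_s, n_exp, n_starts = 8) {
  lo <- log(min(times_s))
  hi <- log(max(times_s))
  spans <- list(c(0.05, 0.60), c(0.20, 0.80), c(0.40, 0.95), c(0.05, 0.95),
                c(0.10, 0.50), c(0.50, 0.90), c(0.25, 0.75), c(0.05, 0.35))
  spans <- spans[seq_len(min(n_starts, length(spans)))]
  lapply(spans, function(sp) {
    if (n_exp == 1) {
      mean(lo + sp * (hi - lo))
    } else {
      seq(lo + sp[1] * (hi - lo), lo + sp[2] * (hi - lo), length.out = n_exp)
    }
  })
}

#' Global multi-exponential fit of a transient absorption matrix
#'
#' Fits `deltaA(lambda, t) = sum_i DADS_i(lambda) exp(-t / tau_i)` with the
#' time constants shared across all wavelengths (global target analysis of
#' the irreversible sequential scheme). Time constants are log-parameterized
#' (hence positive) and optimized by multi-start quasi-Newton search;
#' amplitudes are solved by linear least squares at each step (variable
#' projection). Species-associated difference spectra (SADS) are derived
#' from the fitted DADS under the sequential scheme with the fitted taus in
#' ascending order.
#'
#' @param data a [transient_dataset()].
#' @param n_exp number of exponentials (chain length), >= 1.
#' @param init optional numeric vector(s) of initial taus in seconds (a
#'   vector of length `n_exp` or a list of such vectors); prepended to the
#'   default multi-start grid.
#' @param wavelengths_nm optional subset of wavelengths to fit (rows are
#'   matched to the nearest grid value), e.g. `c(470, 570, 600)` for
#'   selected-wavelength fitting; default uses the full matrix.
#' @param n_starts number of multi-start initializations (default 8).
#' @return object of class `global_fit` with elements `scheme`
#'   (ascending-tau [sequential_scheme()] with provisional labels), `dads`,
#'   `sads` (matrices `[wavelength x n]`), `rss`, `per_tau_stderr`,
#'   `converged`, `degenerate` (TRUE when two fitted taus are within ratio
#'   1.05), and the fitted grids. Non-convergence is reported through
#'   `converged = FALSE`, never as an error.
#' @export
fit_global <- function(data, n_exp, init = NULL, wavelengths_nm = NULL,
                       n_starts = 8) {
  stopifnot(inherits(data, "transient_dataset"))
  check_scalar(n_exp, "n_exp", positive = TRUE)
  n_exp <- as.integer(n_exp)
  if (length(data$times_s) < 2 * n_exp) {
    fail_field("n_exp", "data must have at least 2 * n_exp time points")
  }
  wl <- data$wavelengths_nm
  Y <- data$deltaA
  if (!is.null(wavelengths_nm)) {
    rows <- vapply(wavelengths_nm, function(w) which.min(abs(wl - w)),
                   integer(1))
    rows <- sort(unique(rows))
    wl <- wl[rows]
    Y <- Y[rows, , drop = FALSE]
  }
  tt <- data$times_s

  starts <- default_starts(tt, n_exp, n_starts)
  if (!is.null(init)) {
    if (!is.list(init)) init <- list(init)
    init <- lapply(init, function(v) {
      if (length(v) != n_exp || any(v <= 0)) {
        fail_field("init", "each initial tau vector must be positive with length n_exp")
      }
      log(sort(v))
    })
    starts <- c(init, starts)
  }

  # taus confined to the observable window: below ~t_min/7 a component has
  # decayed before the first sample, far above t_max it is indistinguishable
  # from a constant
  bound_lo <- log(min(tt) / 7)
  bound_hi <- log(max(tt) * 20)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::nlminb(pmin(pmax(s, bound_lo), bound_hi), vp_rss,
                    Y = Y, times_s = tt,
                    lower = bound_lo, upper = bound_hi,
                    control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                   iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$objective)) next
    cand <- list(log_tau = sort(opt$par), rss = opt$objective,
                 ok = opt$convergence == 0)
    if (is.null(best)) {
      best <- cand
    } else if (cand$rss < best$rss * (1 - 1e-12)) {
      best <- cand
    } else if (cand$rss <= best$rss * (1 + 1e-12)) {
      # rss tie: keep the lexicographically smallest sorted tau vector
      cmp <- cand$log_tau - best$log_tau
      first <- which(abs(cmp) > 1e-12)[1]
      if (!is.na(first) && cmp[first] < 0) best <- cand
    }
  }
  if (is.null(best)) {
    best <- list(log_tau = starts[[1]], rss = vp_rss(starts[[1]], Y, tt),
                 ok = FALSE)
  }

  # Polish from the best start with a looser tolerance; the optimizer often
  # reports "false convergence" at machine-precision rss even though the
  # minimum is reached, so convergence is declared when no meaningful
  # further descent is possible.
  polish <- tryCatch(
    stats::nlminb(best$log_tau, vp_rss, Y = Y, times_s = tt,
                  lower = bound_lo, upper = bound_hi,
                  control = list(rel.tol = 1e-12, iter.max = 200)),
    error = function(e) NULL
  )
  if (!is.null(polish) && is.finite(polish$objective) &&
      polish$objective <= best$rss) {
    no_descent <- polish$objective >= best$rss * (1 - 1e-8)
    best <- list(log_tau = sort(polish$par), rss = polish$objective,
                 ok = best$ok || polish$convergence == 0 || no_descent)
  }
  # an rss at round-off level relative to the data norm is a converged fit,
  # whatever relative-descent diagnostics say down there
  if (best$rss <= 1e-18 * max(sum(Y * Y), 1)) best$ok <- TRUE

  log_tau <- sort(best$log_tau)
  sol <- vp_solve(log_tau, Y, tt)
  tau <- exp(log_tau)
  labels <- paste0("S", seq_len(n_exp))
  scheme <- sequential_scheme(labels, tau)

  ratio_ok <- if (n_exp > 1) min(tau[-1] / tau[-n_exp]) >= 1.05 else TRUE
  if (!ratio_ok) {
    warning("fitted time constants are nearly degenerate (ratio < 1.05)",
            call. = FALSE)
  }

  sads <- if (ratio_ok) sads_from_dads(scheme, sol$dads) else
    matrix(NA_real_, nrow(sol$dads), ncol(sol$dads))

  per_tau_stderr <- tau_stderr(log_tau, Y, tt, best$rss, n_exp)

  structure(
    list(scheme = scheme, dads = sol$dads, sads = sads, rss = best$rss,
         per_tau_stderr = per_tau_stderr, converged = isTRUE(best$ok),
         degenerate = !ratio_ok, wavelengths_nm = wl, times_s = tt),
    class = "global_fit"
  )
}

# Asymptotic standard errors of the taus from the curvature of the
# variable-projection rss surface in log-tau.
tau_stderr <- function(log_tau, Y, times_s, rss, n_exp) {
  n_obs <- length(Y)
  n_par <- n_exp + n_exp * nrow(Y)
  dof <- max(n_obs - n_par, 1)
  sigma2 <- rss / dof
  h <- 1e-5
  p <- length(log_tau)
  H <- matrix(0, p, p)
  f0 <- rss
  fp <- numeric(p); fm <- numeric(p)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h)
    fp[i] <- vp_rss(log_tau + ei, Y, times_s)
    fm[i] <- vp_rss(log_tau - ei, Y, times_s)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (p > 1) {
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      ei <- replace(numeric(p), i, h)
      ej <- replace(numeric(p), j, h)
      fpp <- vp_rss(log_tau + ei + ej, Y, times_s)
      H[i, j] <- H[j, i] <-
        (fpp - fp[i] - fp[j] + f0) / h^2
    }
  }
  cov <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
  if (is.null(cov)) return(rep(NA_real_, p))
  v <- diag(cov)
  se_log <- ifelse(v > 0, sqrt(v), NA_real_)
  exp(log_tau) * se_log
}

#' Reconstruct the fitted matrix from a global fit
#'
#' @param fit a `global_fit`.
#' @param from `"dads"` (exponential basis) or `"sads"` (Bateman
#'   concentrations); both agree to numerical precision.
#' @return matrix `[wavelength x time]`.
#' @export
reconstruct_fit <- function(fit, from = c("dads", "sads")) {
  from <- match.arg(from)
  if (from == "dads") {
    E <- exp(-outer(fit$times_s, 1 / fit$scheme$tau_s))
    fit$dads %*% t(E)
  } else {
    fit$sads %*% bateman_concentrations(fit$scheme, fit$times_s)
  }
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global %d-exponential fit (%s, rss %.4g)\n",
              length(x$scheme$tau_s),
              if (x$converged) "converged" else "NOT converged", x$rss))
  cat("  tau:",
      paste(sprintf("%.4g ms", 1000 * x$scheme$tau_s), collapse = ", "), "\n")
  if (x$degenerate) cat("  warning: nearly degenerate time constants\n")
  invisible(x)
}

#' Assign photointermediate labels from fitted SADS
#'
#' Labels each species of a sequential-scheme fit by the position of its
#' positive SADS maximum: species whose positive band lies red of their own
#' bleach minimum, with the fastest decay, are K-like; a positive maximum in
#' 440--500 nm is L-like; in 590--640 nm, O-like. Labels are never
#' duplicated; species without a positive lobe are labeled `"bleach-only"`,
#' anything else keeps a generic `S<j>` name.
#'
#' @param fit a `global_fit` (or any list with `scheme`, `sads`,
#'   `wavelengths_nm`).
#' @param l_window,o_window wavelength windows (nm) for the L- and O-like
#'   assignments.
#' @return the fit with `scheme$labels` replaced by assigned labels.
#' @export
assign_intermediates <- function(fit, l_window = c(440, 500),
                                 o_window = c(590, 640)) {
  sads <- fit$sads
  if (is.null(sads) || anyNA(sads)) {
    stop("assign_intermediates: fit has no usable SADS (degenerate taus?)",
         call. = FALSE)
  }
  wl <- fit$wavelengths_nm
  n <- ncol(sads)
  scale <- max(abs(sads))
  labels <- rep(NA_character_, n)
  peak_pos <- rep(NA_real_, n)
  red_shifted <- rep(FALSE, n)
  for (j in seq_len(n)) {
    s <- sads[, j]
    if (scale == 0 || max(s) <= 1e-3 * scale) {
      labels[j] <- "bleach-only"
      next
    }
    peak_pos[j] <- wl[which.max(s)]
    if (min(s) < 0) {
      red_shifted[j] <- peak_pos[j] > wl[which.min(s)]
    } else {
      red_shifted[j] <- FALSE
    }
  }
  open <- function(lbl) !lbl %in% labels
  # K: only the earliest (fastest-tau) species qualifies, and only when its
  # positive band is red-shifted relative to its own bleach; later
  # red-shifted species are left to the O window rule.
  if (n >= 1 && is.na(labels[1]) && red_shifted[1]) labels[1] <- "K"
  for (j in seq_len(n)) {
    if (!is.na(labels[j])) next
    p <- peak_pos[j]
    if (p >= l_window[1] && p <= l_window[2] && open("L")) {
      labels[j] <- "L"
    } else if (p >= o_window[1] && p <= o_window[2] && open("O")) {
      labels[j] <- "O"
    }
  }
  labels[is.na(labels)] <- paste0("S", which(is.na(labels)))
  fit$scheme$labels <- labels
  fit
}

#' Detect accumulation of the red-shifted O intermediate
#'
#' Scores the fit as the largest positive SADS amplitude inside the O band
#' (590--640 nm by default, any species) relative to the bleach depth (the
#' most negative SADS value in 520--590 nm, any species). Accumulation is
#' declared when the score reaches `threshold`.
#'
#' For nearly degenerate fits (two taus within ratio 1.05) the most weakly
#' weighted component (smallest DADS norm) is dropped and the SADS of the
#' reduced scheme are used, since the full linear map to SADS is
#' ill-conditioned there.
#'
#' @param fit a `global_fit`.
#' @param threshold score at or above which accumulation is declared
#'   (default 0.10).
#' @param o_window,bleach_window wavelength windows, nm.
#' @return list with `accumulating` (logical), `score`, `threshold`.
#' @export
detect_o_accumulation <- function(fit, threshold = 0.10,
                                  o_window = c(590, 640),
                                  bleach_window = c(520, 590)) {
  sads <- fit$sads
  if (is.null(sads) || anyNA(sads)) {
    sads <- reduced_sads(fit)
  }
  wl <- fit$wavelengths_nm
  in_o <- wl >= o_window[1] & wl <= o_window[2]
  in_b <- wl >= bleach_window[1] & wl <= bleach_window[2]
  bleach <- -min(sads[in_b, , drop = FALSE], 0)
  if (bleach == 0) {
    warning("detect_o_accumulation: zero bleach amplitude, score undefined",
            call. = FALSE)
    return(list(accumulating = FALSE, score = NA_real_,
                threshold = threshold))
  }
  pos <- max(sads[in_o, , drop = FALSE], 0)
  score <- pos / bleach
  list(accumulating = score >= threshold, score = score,
       threshold = threshold)
}

# SADS of the fit after dropping the weakest exponential component; used
# when near-coincident taus make the full DADS->SADS map ill-conditioned.
reduced_sads <- function(fit) {
  dads <- fit$dads
  tau <- fit$scheme$tau_s
  if (length(tau) < 2) return(dads)
  norms <- sqrt(colSums(dads^2))
  drop <- which.min(norms)
  keep <- setdiff(seq_along(tau), drop)
  scheme <- sequential_scheme(fit$scheme$labels[keep], tau[keep])
  sads_from_dads(scheme, dads[, keep, drop = FALSE])
}
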