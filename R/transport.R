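# Transport-activity statistics: initial slope of light-induced pH traces,
# expression normalization, permutation many-to-one comparison against WT,
# and cross-anion correlation.

#' Initial-slope transport activity from a pH trace
#'
#' The activity statistic is the ordinary least-squares slope of pH over the
#' first `window_s` seconds of illumination, corrected (by default) for the
#' baseline drift estimated by OLS on the pre-illumination segment.
#' Alkalization (pH increase) is positive; traces with decreasing pH report
#' negative activity.
#'
#' @param trace a [ph_trace()].
#' @param window_s slope window after light-on, seconds (default 10).
#' @param drift_correct subtract the pre-illumination drift (default TRUE).
#' @return object of class `activity_result`: `slope` (pH/s, drift-corrected
#'   when requested), `drift` (pH/s), `raw_slope`, `window_s`, `n_window`.
#' @export
initial_slope <- function(trace, window_s = 10, drift_correct = TRUE) {
  stopifnot(inherits(trace, "ph_trace"))
  tt <- trace$times_s
  on <- trace$light_on_s
  off <- trace$light_off_s
  pre <- tt < on
  if (on - min(tt) < 30) {
    fail_field("light_on_s", "pre-illumination segment must be >= 30 s")
  }
  w_end <- on + window_s
  if (w_end > off) {
    warning(sprintf("slope window truncated at light-off (%.3g s)", off),
            call. = FALSE)
    w_end <- off
  }
  win <- tt >= on & tt <= w_end
  if (sum(win) < 5) {
    fail_field("window_s", "need at least 5 samples in the slope window")
  }
  ols <- function(t, y) {
    tc <- t - mean(t)
    sum(tc * y) / sum(tc * tc)
  }
  drift <- ols(tt[pre], trace$pH[pre])
  raw <- ols(tt[win], trace$pH[win])
  structure(
    list(slope = if (drift_correct) raw - drift else raw,
         drift = drift, raw_slope = raw,
         window_s = w_end - on, n_window = sum(win)),
    class = "activity_result"
  )
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("Initial slope: %.4g pH/s over %.3g s (drift %.3g pH/s)\n",
              x$slope, x$window_s, x$drift))
  invisible(x)
}

#' Expression-normalized panel activities
#'
#' Divides each replicate slope by the mutant's relative expression level
#' (WT = 1), then summarizes per mutant and anion as mean, SD and n, with
#' activities relative to WT.
#'
#' @param panel a [mutant_panel()].
#' @return data.frame with columns `mutant`, `anion`, `mean`, `sd`, `n`,
#'   `relative_to_wt`; WT rows have `relative_to_wt = 1`.
#' @export
normalize_panel <- function(panel) {
  panel <- mutant_panel(panel)
  norm <- panel$slope / panel$expression
  key <- interaction(panel$mutant, panel$anion, drop = TRUE)
  agg <- data.frame(
    mutant = tapply(panel$mutant, key, `[`, 1),
    anion = tapply(panel$anion, key, `[`, 1),
    mean = as.numeric(tapply(norm, key, mean)),
    sd = as.numeric(tapply(norm, key, stats::sd)),
    n = as.integer(tapply(norm, key, length)),
    stringsAsFactors = FALSE
  )
  wt <- agg[agg$mutant == "WT", ]
  agg$relative_to_wt <- agg$mean /
    wt$mean[match(agg$anion, wt$anion)]
  rownames(agg) <- NULL
  agg[order(agg$mutant != "WT", agg$mutant, agg$anion), ]
}

#' Many-to-one comparison of mutants against WT (permutation maxT)
#'
#' Compares each mutant's expression-normalized activities with WT under
#' family-wise error control, in the spirit of Dunnett's many-to-one test
#' but using a permutation maxT null instead of multivariate-t quantiles
#' (robust at n = 3--5 replicates). The statistic per mutant is the absolute
#' two-sample t against WT with pooled variance; group labels are permuted
#' jointly across the whole panel and the maximum statistic over the family
#' is recorded, giving single-step adjusted p values.
#'
#' @param panel a [mutant_panel()].
#' @param anion which condition to test (`"Cl"` or `"SO4"`).
#' @param n_perm number of permutations (default 1999).
#' @param alpha family-wise level for the `significant` flag (default 0.05).
#' @return data.frame with columns `mutant`, `statistic`, `p_adj`,
#'   `significant`; mutants with fewer than 3 replicates are skipped with a
#'   warning. With a single mutant the procedure reduces to an unadjusted
#'   two-sample permutation test.
#' @export
compare_to_wt <- function(panel, anion = c("Cl", "SO4"), n_perm = 1999,
                          alpha = 0.05) {
  panel <- mutant_panel(panel)
  anion <- match.arg(anion)
  sub <- panel[panel$anion == anion, ]
  sub$norm <- sub$slope / sub$expression
  counts <- table(sub$mutant)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    warning(sprintf("skipping mutants with < 3 replicates: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    sub <- sub[!sub$mutant %in% small, ]
  }
  mutants <- setdiff(unique(sub$mutant), "WT")
  if (!length(mutants) || !"WT" %in% sub$mutant) {
    stop("compare_to_wt: need WT and at least one mutant with >= 3 replicates",
         call. = FALSE)
  }
  values <- sub$norm
  groups <- factor(sub$mutant, levels = c("WT", mutants))
  idx <- split(seq_along(values), groups)
  n <- lengths(idx)
  t_stats <- function(v) {
    m <- vapply(idx, function(ii) mean(v[ii]), numeric(1))
    ss <- vapply(idx, function(ii) { vi <- v[ii]; sum((vi - mean(vi))^2) },
                 numeric(1))
    pooled <- sum(ss) / sum(n - 1)
    se <- sqrt(pooled * (1 / n[1] + 1 / n[-1]))
    abs(m[-1] - m[1]) / se
  }
  obs <- t_stats(values)
  max_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    max_null[b] <- max(t_stats(sample(values)))
  }
  p_adj <- vapply(obs, function(o) (1 + sum(max_null >= o)) / (n_perm + 1),
                  numeric(1))
  data.frame(mutant = mutants, statistic = as.numeric(obs),
             p_adj = p_adj, significant = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between chloride and sulfate transport activities
#'
#' Pearson correlation and OLS regression between the per-mutant
#' expression-normalized mean activities in the two anion conditions, over
#' all mutants (none excluded by default).
#'
#' @param panel a [mutant_panel()].
#' @param exclude optional character vector of mutants to drop.
#' @return object of class `correlation_result`: `R`, `p_value`, `slope`,
#'   `intercept`, `n`.
#' @export
correlate_anions <- function(panel, exclude = NULL) {
  norm <- normalize_panel(panel)
  if (!is.null(exclude)) norm <- norm[!norm$mutant %in% exclude, ]
  cl <- norm[norm$anion == "Cl", c("mutant", "mean")]
  so4 <- norm[norm$anion == "SO4", c("mutant", "mean")]
  merged <- merge(cl, so4, by = "mutant", suffixes = c("_cl", "_so4"))
  if (nrow(merged) < 3) {
    stop("correlate_anions: need >= 3 mutants measured in both conditions",
         call. = FALSE)
  }
  x <- merged$mean_cl
  y <- merged$mean_so4
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlate_anions: zero variance in one condition, R undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(
    list(R = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), n = nrow(merged)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Cl vs SO4 activity correlation: R = %.3f (p = %.3g, n = %d)\n",
              x$R, x$p_value, x$n))
  invisible(x)
}
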