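#' Bias-corrected and accelerated (BCa) bootstrap test of a mean
#'
#' Resamples the participant-level values with replacement (`n_boot`
#' draws), takes the mean of each resample, and forms BCa confidence
#' intervals: the bias correction `z0` is the normal quantile of the
#' fraction of bootstrap means below the observed mean, and the
#' acceleration `a` comes from the jackknife skewness. The two-sided
#' p-value is the smallest significance level, on a grid of resolution
#' 1e-4, at which the BCa interval excludes zero, floored at
#' `1 / n_boot`. Deterministic given `seed`.
#'
#' @param values Per-participant measures (length >= 3).
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Integer seed.
#' @param level Confidence level for the reported interval.
#' @param keep_boot Keep the bootstrap means in the result (`boot_means`)
#'   for diagnostics.
#' @return An object of class `bootstrap_result`: list with
#'   `observed_stat`, `n_boot`, `ci_low`, `ci_high`, `level`, `p_value`,
#'   `bias_correction_z0`, `acceleration_a`, `seed`, `n`.
#' @export
bca_bootstrap_test <- function(values, n_boot = 2000L, seed = 1L,
                               level = 0.95, keep_boot = FALSE) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  n_boot <- as.integer(n_boot)
  if (n_boot < 1000) stop("n_boot must be >= 1000")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  obs <- mean(x)

  if (max(x) == min(x)) {
    # no resampling variance: degenerate interval
    p <- if (obs == 0) 1 else 1 / n_boot
    return(structure(list(observed_stat = obs, n_boot = n_boot,
                          ci_low = obs, ci_high = obs, level = level,
                          p_value = p, bias_correction_z0 = 0,
                          acceleration_a = 0, seed = seed, n = n),
                     class = "bootstrap_result"))
  }

  bm <- with_seed(child_seed(seed, "bca"), {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(x[idx], n, n_boot))
  })
  sbm <- sort(bm)

  frac_below <- (sum(bm < obs) + 0.5 * sum(bm == obs)) / n_boot
  frac_below <- min(max(frac_below, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- stats::qnorm(frac_below)

  jk <- (sum(x) - x) / (n - 1)
  u <- mean(jk) - jk
  a <- if (sum(u^2) == 0) 0 else sum(u^3) / (6 * sum(u^2)^1.5)

  q_bca <- function(alpha_tail) {
    z <- stats::qnorm(alpha_tail)
    adj <- z0 + (z0 + z) / (1 - a * (z0 + z))
    q <- stats::pnorm(adj)
    sbm[min(max(ceiling(q * n_boot), 1L), n_boot)]
  }
  ci_at <- function(lv) {
    al <- (1 - lv) / 2
    c(q_bca(al), q_bca(1 - al))
  }
  ci <- ci_at(level)

  # smallest alpha (grid 1e-4) whose (1 - alpha) interval excludes zero
  excludes <- function(alpha) {
    iv <- ci_at(1 - alpha)
    iv[1] > 0 || iv[2] < 0
  }
  grid <- 1e-4
  lo <- 1L; hi <- as.integer(1 / grid) # alpha indices: grid..1
  if (!excludes(hi * grid - grid / 2)) {
    p <- 1
  } else if (excludes(lo * grid)) {
    p <- lo * grid
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (excludes(mid * grid)) hi <- mid else lo <- mid
    }
    p <- hi * grid
  }
  p <- max(p, 1 / n_boot)

  out <- structure(list(observed_stat = obs, n_boot = n_boot,
                        ci_low = ci[1], ci_high = ci[2], level = level,
                        p_value = min(p, 1), bias_correction_z0 = z0,
                        acceleration_a = a, seed = seed, n = n),
                   class = "bootstrap_result")
  if (keep_boot) out$boot_means <- bm
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("BCa bootstrap: mean = %.4g, %d%% CI [%.4g, %.4g], p = %.4g (n = %d, B = %d)\n",
              x$observed_stat, round(100 * x$level), x$ci_low, x$ci_high,
              x$p_value, x$n, x$n_boot))
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size and caps at 1.
#'
#' @param p_values Probabilities in `[0, 1]`.
#' @param family Family size (defaults to `length(p_values)`).
#' @return Adjusted p-values.
#' @examples
#' bonferroni_adjust(0.01, family = 4) # 0.04
#' @export
bonferroni_adjust <- function(p_values, family = length(p_values)) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, p_values * family)
}

#' Aggregate channel-level peak measures into ROI cells
#'
#' Unweighted means of `d` (and `snr`) per anteriority x laterality cell
#' of the layout, separately per target frequency. Channels present in
#' the data but absent from the layout are excluded (their count is
#' reported in the `n_unmapped` attribute); a requested cell with no
#' contributing channel raises an error naming the cell.
#'
#' @param peaks Channel-level table from [peak_measures()].
#' @param layout A [default_roi_layout()]-style mapping.
#' @return data.frame `target_freq`, `anteriority`, `laterality`, `d`,
#'   `snr`, `n_channels`.
#' @export
roi_aggregate <- function(peaks, layout = default_roi_layout()) {
  m <- match(peaks$channel, layout$channel)
  n_unmapped <- length(unique(peaks$channel[is.na(m)]))
  peaks <- peaks[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  peaks$anteriority <- layout$anteriority[m]
  peaks$laterality <- layout$laterality[m]
  cells <- expand.grid(anteriority = c("frontal", "central", "posterior"),
                       laterality = c("left", "medial", "right"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(unique(peaks$target_freq), function(f) {
    sub <- peaks[peaks$target_freq == f, ]
    res <- cells
    res$target_freq <- f
    res$d <- res$snr <- NA_real_
    res$n_channels <- 0L
    for (i in seq_len(nrow(cells))) {
      sel <- sub$anteriority == cells$anteriority[i] &
        sub$laterality == cells$laterality[i]
      if (!any(sel))
        stop("empty ROI cell: ", cells$anteriority[i], "/", cells$laterality[i])
      res$d[i] <- mean(sub$d[sel])
      res$snr[i] <- mean(sub$snr[sel])
      res$n_channels[i] <- sum(sel)
    }
    res[, c("target_freq", "anteriority", "laterality", "d", "snr", "n_channels")]
  }))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Pearson correlation between two per-participant peak measures
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return List with `r`, `r_squared`, `p` (two-sided, t-distribution),
#'   and `defined` (FALSE when either vector has zero variance, in which
#'   case the other fields are `NA`).
#' @export
peak_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  n <- length(a)
  if (n < 3) stop("need at least 3 paired values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                defined = FALSE))
  r <- stats::cor(a, b)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, r_squared = r^2, p = min(p, 1), defined = TRUE)
}

#' Behavioral sensitivity (d-prime)
#'
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)` with the log-linear correction
#' `(x + 0.5) / (n + 1)` applied to both rates, which keeps the measure
#' finite at perfect performance.
#'
#' @param n_hit,n_miss,n_fa,n_cr Signal-detection counts.
#' @return An object of class `dprime`: list with `hit_rate`, `fa_rate`
#'   (corrected) and `dprime`.
#' @export
dprime <- function(n_hit, n_miss, n_fa, n_cr) {
  n_sig <- n_hit + n_miss
  n_noise <- n_fa + n_cr
  if (n_sig < 1 || n_noise < 1)
    stop("need at least one signal and one noise trial")
  hr <- (n_hit + 0.5) / (n_sig + 1)
  fr <- (n_fa + 0.5) / (n_noise + 1)
  structure(list(hit_rate = hr, fa_rate = fr,
                 dprime = stats::qnorm(hr) - stats::qnorm(fr)),
            class = "dprime")
}

#' @export
print.dprime <- function(x, ...) {
  cat(sprintf("d' = %.3f (corrected hit %.3f, fa %.3f)\n",
              x$dprime, x$hit_rate, x$fa_rate))
  invisible(x)
}
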