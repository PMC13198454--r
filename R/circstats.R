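# Circular statistics: mean direction and resultant, Rayleigh uniformity
# test, Zar's 95% confidence interval for the mean direction, the
# Mardia-Watson-Wheeler uniform-scores two-sample test, and fixed-width
# binning for rose plots.  All angles are degrees; internal computation is
# double precision in radians.

#' Circular mean direction and resultant length
#'
#' @param angles_deg numeric vector of angles, degrees (n >= 1).
#' @return a list with `mu_deg` (mean direction in `[0, 360)`, `NA` when the
#'   resultant vanishes), `r` (mean resultant length in `[0, 1]`), `R`
#'   (resultant magnitude, `= n * r`) and `n`.
#' @examples
#' circ_mean_and_r(c(10, 350))  # mu = 0, r = cos(10 deg)
#' @export
circ_mean_and_r <- function(angles_deg) {
  if (!length(angles_deg)) stop("empty angle vector", call. = FALSE)
  a <- deg2rad(angles_deg)
  C <- sum(cos(a)); S <- sum(sin(a))
  R <- sqrt(C^2 + S^2)
  n <- length(a)
  mu <- if (R < n * 1e-12) NA_real_ else wrap360(rad2deg(atan2(S, C)))
  list(mu_deg = mu, r = min(R / n, 1), R = R, n = n)
}

#' Rayleigh test p-value
#'
#' Upper-tail probability of the Rayleigh statistic `Z = n * r^2` under
#' circular uniformity, using the standard approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`, clipped to `[0, 1]`.
#' Accurate to 3 decimals at the sample sizes used here (n around 15).
#'
#' @param Z Rayleigh statistic (>= 0).
#' @param n sample size (>= 2).
#' @return p-value in `[0, 1]`.
#' @export
rayleigh_p <- function(Z, n) {
  stopifnot(Z >= 0, n >= 2)
  R <- sqrt(n * Z)
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  min(max(p, 0), 1)
}

#' 95% confidence interval for the mean direction (Zar)
#'
#' Two-branch large-sample formula: for `r <= 0.9` the half-width is
#' `acos(sqrt(2n (2R^2 - n chi^2) / (R^2 (4n - chi^2))))` and for `r > 0.9`
#' it is `acos(sqrt(n^2 - (n^2 - R^2) exp(chi^2 / n)) / R)`, with `chi^2` the
#' 0.95 quantile of chi-squared on 1 df.  The interval is reported as
#' unreliable (bounds `NA`) when the formula degenerates (arccos argument
#' outside `[0, 1]`, low concentration) or when the Rayleigh test is not
#' significant at 0.05 — the "not reliable due to low concentration" rule.
#'
#' @param angles_deg numeric vector of angles, degrees (n >= 2).
#' @return a list with `lo_deg`, `hi_deg` (`NA` when unreliable),
#'   `half_width_deg` and `reliable`.
#' @export
ci95_mean <- function(angles_deg) {
  s <- circ_mean_and_r(angles_deg)
  n <- s$n; R <- s$R; r <- s$r
  stopifnot(n >= 2)
  chi2 <- stats::qchisq(0.95, df = 1)
  half <- NA_real_
  if (!is.na(s$mu_deg)) {
    if (r <= 0.9) {
      num <- 2 * n * (2 * R^2 - n * chi2)
      den <- R^2 * (4 * n - chi2)
      arg2 <- num / den
      if (is.finite(arg2) && arg2 >= 0) {
        arg <- sqrt(arg2)
        if (arg <= 1) half <- rad2deg(acos(arg))
      }
    } else {
      arg2 <- n^2 - (n^2 - R^2) * exp(chi2 / n)
      if (arg2 >= 0) {
        arg <- sqrt(arg2) / R
        if (arg <= 1) half <- rad2deg(acos(arg))
      }
    }
  }
  p <- rayleigh_p(n * r^2, n)
  reliable <- !is.na(half) && p < 0.05
  list(lo_deg = if (reliable) wrap360(s$mu_deg - half) else NA_real_,
       hi_deg = if (reliable) wrap360(s$mu_deg + half) else NA_real_,
       half_width_deg = half, reliable = reliable)
}

#' Rayleigh uniformity test with full circular summary
#'
#' @param angles_deg numeric vector of angles, degrees (n >= 2).
#' @return an object of class `circ_summary`: `n`, `R`, `r`, `Z` (`= n r^2`),
#'   `p`, `mu_deg` (`NA` when the resultant vanishes), `ci_lo_deg`,
#'   `ci_hi_deg`, `ci_half_width_deg`, `ci_reliable`.
#' @examples
#' rayleigh_test(c(170, 180, 175, 185, 190))
#' @export
rayleigh_test <- function(angles_deg) {
  if (length(angles_deg) < 2) stop("Rayleigh test needs n >= 2", call. = FALSE)
  s <- circ_mean_and_r(angles_deg)
  ci <- ci95_mean(angles_deg)
  structure(list(n = s$n, R = s$R, r = s$r, Z = s$n * s$r^2,
                 p = rayleigh_p(s$n * s$r^2, s$n), mu_deg = s$mu_deg,
                 ci_lo_deg = ci$lo_deg, ci_hi_deg = ci$hi_deg,
                 ci_half_width_deg = ci$half_width_deg,
                 ci_reliable = ci$reliable),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("circular summary: n = %d, r = %.3f, Z = %.3f, p = %s\n",
              x$n, x$r, x$Z,
              if (x$p < 0.001) "< 0.001" else sprintf("%.3f", x$p)))
  if (is.na(x$mu_deg)) cat("  mean direction undefined (zero resultant)\n")
  else cat(sprintf("  mean direction mu = %.3f deg\n", x$mu_deg))
  if (x$ci_reliable)
    cat(sprintf("  95%% CI = %.3f - %.3f deg (half-width %.3f)\n",
                x$ci_lo_deg, x$ci_hi_deg, x$ci_half_width_deg))
  else cat("  95% CI not reliable (low concentration)\n")
  invisible(x)
}

#' Chi-squared tail probability for the Mardia-Watson-Wheeler statistic
#'
#' Under the null, `W` is asymptotically chi-squared with 2 df, whose upper
#' tail is `exp(-W/2)`.
#'
#' @param W uniform-scores statistic (>= 0).
#' @return p-value in `[0, 1]`.
#' @export
mww_chisq_p <- function(W) {
  stopifnot(W >= 0)
  exp(-W / 2)
}

# uniform-scores W for a combined sample given midranks-derived scores beta
# (radians) and the indices of sample 1
mww_W <- function(beta, idx1, n1, n2) {
  C1 <- sum(cos(beta[idx1])); S1 <- sum(sin(beta[idx1]))
  C2 <- sum(cos(beta[-idx1])); S2 <- sum(sin(beta[-idx1]))
  2 * ((C1^2 + S1^2) / n1 + (C2^2 + S2^2) / n2)
}

#' Mardia-Watson-Wheeler two-sample test
#'
#' Nonparametric test for a common circular distribution.  The combined
#' sample is ranked around the circle (midranks for ties), ranks are mapped
#' to uniform scores `beta = 2 pi rank / N`, and
#' `W = 2 [ (C1^2 + S1^2)/n1 + (C2^2 + S2^2)/n2 ]` with `C_i`, `S_i` the
#' score resultants per sample.  The p-value comes from the chi-squared
#' 2-df tail or from Monte-Carlo permutation of the sample labels;
#' `method = "auto"` uses chi-squared when both samples have at least 10
#' observations, permutation otherwise.
#'
#' @param a,b numeric vectors of angles, degrees (each n >= 2).
#' @param method `"auto"`, `"chi2"` or `"permutation"`.
#' @param n_perm number of random relabelings for the permutation p-value.
#'   Permutations draw from the current RNG state; set a seed for
#'   reproducibility.
#' @return an object of class `mww_result`: `W`, `p`, `method` (the one
#'   actually used), `n1`, `n2`, `degenerate` (all combined angles
#'   identical, in which case `W = 0`, `p = 1`).
#' @export
mww_test <- function(a, b, method = c("auto", "chi2", "permutation"),
                     n_perm = 1999) {
  method <- match.arg(method)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("both samples need n >= 2", call. = FALSE)
  all_ang <- wrap360(c(a, b))
  if (length(unique(all_ang)) == 1L)
    return(structure(list(W = 0, p = 1, method = "degenerate", n1 = n1, n2 = n2,
                          degenerate = TRUE), class = "mww_result"))
  N <- n1 + n2
  rk <- rank(all_ang, ties.method = "average")  # midranks
  beta <- 2 * pi * rk / N
  idx1 <- seq_len(n1)
  W <- mww_W(beta, idx1, n1, n2)
  use <- if (method == "auto") { if (min(n1, n2) >= 10) "chi2" else "permutation" } else method
  if (use == "chi2") {
    p <- mww_chisq_p(W)
  } else {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (mww_W(beta, sample.int(N, n1), n1, n2) >= W - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(list(W = W, p = p, method = use, n1 = n1, n2 = n2, degenerate = FALSE),
            class = "mww_result")
}

#' @export
print.mww_result <- function(x, ...) {
  cat(sprintf("Mardia-Watson-Wheeler test: W = %.3f, p = %.3f (%s), n1 = %d, n2 = %d%s\n",
              x$W, x$p, x$method, x$n1, x$n2,
              if (x$degenerate) " [degenerate: all angles identical]" else ""))
  invisible(x)
}

#' Bin angles into fixed-width sectors
#'
#' Half-open bins `[0, w), [w, 2w), ...` after wrapping to `[0, 360)`;
#' counts sum to the sample size.
#'
#' @param angles_deg numeric vector of angles, degrees.
#' @param width_deg bin width; must divide 360.
#' @return named integer vector of counts, names = lower bin edges.
#' @examples
#' bin_angles(c(5, 15, 15), 10)
#' @export
bin_angles <- function(angles_deg, width_deg = 10) {
  k <- 360 / width_deg
  if (abs(k - round(k)) > 1e-9) stop("`width_deg` must divide 360", call. = FALSE)
  k <- as.integer(round(k))
  idx <- floor(wrap360(angles_deg) / width_deg) + 1L
  idx[idx > k] <- 1L  # guard against wrap360 returning exactly 360 by rounding
  counts <- tabulate(idx, nbins = k)
  names(counts) <- format((seq_len(k) - 1L) * width_deg, trim = TRUE)
  counts
}
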