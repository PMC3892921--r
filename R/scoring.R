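# Similarity scoring and score statistics: Tanimoto fraction, Z-scores with
# iterative outlier trimming, and extreme-value (Gumbel) tail p-values.

EULER_MASCHERONI <- 0.5772157

#' Tanimoto score of similarity
#'
#' \code{T = N_C / (N_A + N_B - N_C)}: the fraction of the combined atom sets
#' in correspondence. Symmetric in \code{n_a}, \code{n_b}.
#'
#' @param n_c atoms in common.
#' @param n_a,n_b atom counts of the two clefts (each >= 1).
#' @return Fraction in [0, 1].
#' @export
tanimoto <- function(n_c, n_a, n_b) {
  if (any(n_a < 1) || any(n_b < 1))
    cm_input_error("tanimoto: cleft atom counts must be >= 1")
  if (any(n_c < 0) || any(n_c > pmin(n_a, n_b)))
    cm_input_error("tanimoto: n_c must lie in [0, min(n_a, n_b)]")
  n_c / (n_a + n_b - n_c)
}

population_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Standard scores over a score population
#'
#' \code{z_i = (v_i - mu) / sigma} with the mean and population standard
#' deviation taken over the full list. A zero-spread population is flagged
#' degenerate and every z is set to 0.
#'
#' @param values numeric vector (length >= 2).
#' @return Numeric z vector with attributes \code{mu}, \code{sigma} and
#'   \code{degenerate}.
#' @export
zscores <- function(values) {
  if (length(values) < 2) cm_input_error("zscores: need at least 2 values")
  mu <- mean(values)
  sigma <- population_sd(values)
  degenerate <- sigma == 0
  z <- if (degenerate) rep(0, length(values)) else (values - mu) / sigma
  structure(z, mu = mu, sigma = sigma, degenerate = degenerate)
}

#' Z-scores with iterative outlier trimming
#'
#' Points with \code{z < -3} or \code{z > 7} are removed and the mean and
#' standard deviation recomputed; the process repeats until no point is
#' removed, up to a hard cap of five passes. Final z-scores for \emph{all}
#' original values are computed against the final trimmed mu/sigma. If fewer
#' than two points survive, the untrimmed statistics are used and flagged.
#'
#' @param values numeric vector (length >= 2).
#' @param lower,upper trimming bounds on z (defaults -3 and 7).
#' @return List with \code{z} (for all original values) and \code{stats}
#'   (list: \code{mu}, \code{sigma}, \code{n_trim_iters}, \code{trimmed_count},
#'   \code{degenerate}, \code{fallback}).
#' @export
trimmed_z <- function(values, lower = -3, upper = 7) {
  if (length(values) < 2) cm_input_error("trimmed_z: need at least 2 values")
  keep <- rep(TRUE, length(values))
  iters <- 0L
  mu <- mean(values); sigma <- population_sd(values)
  fallback <- FALSE
  for (pass in 1:5) {
    iters <- pass
    surv <- values[keep]
    if (length(surv) < 2) { fallback <- TRUE; break }
    mu <- mean(surv); sigma <- population_sd(surv)
    if (sigma == 0) break
    z <- (values - mu) / sigma
    out <- keep & (z < lower | z > upper)
    if (!any(out)) break
    keep <- keep & !out
  }
  if (fallback || sum(keep) < 2) {
    fallback <- TRUE
    mu <- mean(values); sigma <- population_sd(values)
  } else if (iters == 5L) {
    # cap reached after a removal pass: recompute stats on the survivors
    mu <- mean(values[keep]); sigma <- population_sd(values[keep])
  }
  degenerate <- sigma == 0
  z <- if (degenerate) rep(0, length(values)) else (values - mu) / sigma
  list(z = z,
       stats = list(mu = mu, sigma = sigma, n_trim_iters = iters,
                    trimmed_count = sum(!keep), degenerate = degenerate,
                    fallback = fallback))
}

#' Extreme-value distribution p-value of a Z-score
#'
#' Tail probability of a standardized Gumbel distribution:
#' \deqn{p = 1 - \exp(-e^{-z \pi/\sqrt{6} + \gamma})}{p = 1 - exp(-exp(-z*pi/sqrt(6) + 0.5772157))}
#' with \eqn{\gamma = 0.5772157} the Euler-Mascheroni constant. The
#' \eqn{\pi/\sqrt 6} scale is the standardization of a unit-variance Gumbel;
#' a literal \eqn{\pi/6} variant is kept behind the \code{scale} switch for
#' comparison.
#'
#' @param z numeric Z-score(s).
#' @param scale \code{"pi/sqrt6"} (default) or \code{"pi/6"}.
#' @return p-value(s) in (0, 1), strictly decreasing in \code{z}.
#' @export
evd_pvalue <- function(z, scale = c("pi/sqrt6", "pi/6")) {
  scale <- match.arg(scale)
  k <- if (scale == "pi/sqrt6") pi / sqrt(6) else pi / 6
  if (any(!is.finite(z))) cm_input_error("evd_pvalue: z must be finite")
  -expm1(-exp(-z * k + EULER_MASCHERONI))
}
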