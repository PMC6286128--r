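# Inferential machinery: R2-weighted bootstrap with two-tailed p, FDR,
# MAD outlier rejection, Rayleigh non-uniformity test, Fisher transform.

#' Weighted bootstrap of a voxel statistic
#'
#' Resamples observations with replacement and recomputes a weighted
#' statistic (default: the weighted mean, with weights applied inside the
#' statistic, not in the resampling probabilities). The two-tailed p-value
#' against `threshold` is twice the smaller of the fractions of bootstrap
#' samples below and above it, floored at `2/n_boot`. Resamples on which
#' the statistic is undefined (NA) are redrawn, counted and capped.
#'
#' @param values Numeric vector (n >= 2).
#' @param weights Non-negative weights, not all zero (default: uniform).
#' @param statistic Function `f(values, weights)`; NULL uses the weighted
#'   mean (fast path).
#' @param n_boot Number of bootstrap resamples.
#' @param threshold Null value for the p-value.
#' @param seed Seed.
#' @param keep_samples If TRUE the bootstrap draws are returned as
#'   `samples`.
#' @return List of class `bootstrap_result`: `estimate` (full-sample
#'   statistic), `ci` (2.5/97.5 percentiles), `p`, `n_boot`, `seed`,
#'   `n_redrawn` (and optionally `samples`).
#' @export
weighted_bootstrap <- function(values, weights = NULL, statistic = NULL,
                               n_boot = 1e5, threshold = 0, seed = 1L,
                               keep_samples = FALSE) {
  n <- length(values)
  .stop_if(n < 2, "need at least two values")
  if (is.null(weights)) weights <- rep(1, n)
  .stop_if(any(weights < 0) || sum(weights) == 0,
           "weights must be non-negative and not all zero")
  n_boot <- as.integer(n_boot)
  n_redrawn <- 0L
  boots <- .with_seed(seed, {
    if (is.null(statistic)) {
      out <- numeric(n_boot)
      done <- 0L
      chunk <- max(1L, min(n_boot, ceiling(2e6 / n)))
      while (done < n_boot) {
        b <- min(chunk, n_boot - done)
        ix <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
        vm <- matrix(values[ix], nrow = n)
        wm <- matrix(weights[ix], nrow = n)
        out[done + seq_len(b)] <- colSums(vm * wm) / colSums(wm)
        done <- done + b
      }
      out
    } else {
      out <- numeric(n_boot)
      attempts <- 0L
      i <- 1L
      while (i <= n_boot && attempts < 10L * n_boot) {
        attempts <- attempts + 1L
        ix <- sample.int(n, n, replace = TRUE)
        s <- statistic(values[ix], weights[ix])
        if (is.na(s)) { n_redrawn <- n_redrawn + 1L; next }
        out[i] <- s
        i <- i + 1L
      }
      out[seq_len(i - 1L)]
    }
  })
  est <- if (is.null(statistic)) sum(values * weights) / sum(weights)
    else statistic(values, weights)
  # ties at the threshold count into both tails, so a degenerate
  # distribution concentrated at the threshold gives p = 1, not the floor
  p <- 2 * min(mean(boots <= threshold), mean(boots >= threshold))
  p <- min(1, max(p, 2 / length(boots)))
  out <- list(estimate = est,
              ci = unname(quantile(boots, c(0.025, 0.975))),
              p = p, n_boot = length(boots), seed = seed,
              n_redrawn = n_redrawn)
  if (keep_samples) out$samples <- boots
  structure(out, class = "bootstrap_result")
}

#' @exportS3Method base::print
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: estimate %.4g, 95%% CI [%.4g, %.4g], p %s (n_boot %d)\n",
              x$estimate, x$ci[1], x$ci[2],
              if (x$p <= 2 / x$n_boot) paste0("< ", format(2 / x$n_boot))
              else format(x$p), x$n_boot))
  invisible(x)
}

#' False discovery rate correction
#'
#' Benjamini-Hochberg step-up adjusted values with enforced monotonicity.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
fdr_correct <- function(pvals) {
  .stop_if(any(pvals < 0 | pvals > 1 | is.na(pvals)),
           "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Median-absolute-deviation outlier mask
#'
#' Marks values within `k` unscaled median absolute deviations of the
#' median for inclusion. A zero MAD (more than half the values identical)
#' excludes nothing, with a warning.
#'
#' @param values Numeric vector (n >= 3).
#' @param k MAD multiplier (two-sided).
#' @param scaled If TRUE the MAD uses the 1.4826 normal-consistency factor.
#' @return Logical inclusion mask.
#' @export
mad_outlier_mask <- function(values, k = 5, scaled = FALSE) {
  .stop_if(length(values) < 3, "need at least three values")
  med <- median(values)
  m <- median(abs(values - med)) * if (scaled) 1.4826 else 1
  if (m == 0) {
    warning("MAD is zero; no outliers excluded", call. = FALSE)
    return(rep(TRUE, length(values)))
  }
  abs(values - med) <= k * m
}

#' Rayleigh test of circular non-uniformity
#'
#' Mean resultant length Rbar of the angles and the p-value of the Rayleigh
#' statistic Z = n * Rbar^2 under the small-sample-corrected approximation.
#'
#' @param angles Angles in radians (n >= 5).
#' @return List with `Rbar`, `z`, `p`, `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  .stop_if(n < 5, "need at least five angles")
  Rbar <- Mod(sum(exp(1i * angles))) / n
  z <- n * Rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(Rbar = Rbar, z = z, p = min(1, max(0, p)), n = n)
}

#' Fisher transform of a correlation
#'
#' atanh(r); errors for |r| >= 1.
#'
#' @param r Correlation in (-1, 1).
#' @return z value.
#' @export
fisher_z <- function(r) {
  .stop_if(any(abs(r) >= 1), "|r| must be < 1")
  atanh(r)
}
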