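# Adaptive-staircase behavioural simulation: a Bayesian one-parameter
# threshold staircase driving a 2AFC Weibull observer.

# Weibull psychometric function on a log-intensity axis.
.weibull_p <- function(x, threshold, slope, guess, lapse)
  guess + (1 - guess - lapse) * (1 - exp(-10^(slope * (x - threshold))))

#' Simulate a 2AFC observer under an adaptive staircase
#'
#' A Bayesian adaptive staircase holds a posterior over the observer's
#' threshold on a log-intensity lattice (Gaussian prior, Weibull
#' likelihood). Each trial is placed at the current posterior-mode
#' threshold estimate plus the fixed offset at which the assumed
#' psychometric function reaches `target_p`; the simulated observer
#' responds according to a Weibull psychometric with guess rate 0.5. With a
#' well-matched observer the staircase converges so that asymptotic
#' accuracy approximates `target_p`.
#'
#' A `true_threshold` of `Inf` yields an observer that ignores the stimulus
#' (flat psychometric at the guess rate).
#'
#' @param true_threshold Observer threshold on the log-intensity axis.
#' @param psychometric_slope Weibull slope (shared by staircase and
#'   observer).
#' @param n_trials Number of trials.
#' @param target_p Target proportion correct (0.5 < target_p < 1 - lapse).
#' @param guess Guess rate (0.5 for 2AFC).
#' @param lapse Lapse rate.
#' @param prior_mean,prior_sd Gaussian prior on the threshold.
#' @param lattice Log-intensity lattice for the posterior.
#' @param seed Seed; the simulation is deterministic given the seed.
#' @return List of class `staircase_sim`: `trials` data.frame (trial,
#'   intensity, p_correct, correct), `threshold_estimate` (posterior mean
#'   after the last trial), `threshold_mode`, `target_p`, `true_threshold`.
#' @export
simulate_staircase_observer <- function(true_threshold = 0.3,
                                        psychometric_slope = 3.5,
                                        n_trials = 1000,
                                        target_p = 0.83,
                                        guess = 0.5, lapse = 0.02,
                                        prior_mean = 0, prior_sd = 0.5,
                                        lattice = seq(-1.5, 1.5, by = 0.005),
                                        seed = 1L) {
  .stop_if(!(target_p > 0.5 && target_p < 1),
           "target_p must lie in (0.5, 1) for 2AFC")
  .stop_if(target_p >= 1 - lapse, "target_p must be below 1 - lapse")
  frac <- (target_p - guess) / (1 - guess - lapse)
  offset <- log10(-log(1 - frac)) / psychometric_slope
  logpost <- -(lattice - prior_mean)^2 / (2 * prior_sd^2)
  intensity <- p_correct <- numeric(n_trials)
  correct <- logical(n_trials)
  .with_seed(seed, {
    for (i in seq_len(n_trials)) {
      t_hat <- lattice[which.max(logpost)]
      x <- t_hat + offset
      pc <- .weibull_p(x, true_threshold, psychometric_slope, guess, lapse)
      resp <- rbinom(1, 1, pc) == 1
      pl <- .weibull_p(x, lattice, psychometric_slope, guess, lapse)
      logpost <- logpost + if (resp) log(pl) else log(1 - pl)
      logpost <- logpost - max(logpost)
      intensity[i] <- x
      p_correct[i] <- pc
      correct[i] <- resp
    }
  })
  post <- exp(logpost)
  post <- post / sum(post)
  structure(
    list(trials = data.frame(trial = seq_len(n_trials),
                             intensity = intensity, p_correct = p_correct,
                             correct = correct),
         threshold_estimate = sum(lattice * post),
         threshold_mode = lattice[which.max(post)],
         target_p = target_p, true_threshold = true_threshold,
         psychometric_slope = psychometric_slope, guess = guess,
         lapse = lapse, seed = seed),
    class = "staircase_sim")
}

#' @exportS3Method base::print
print.staircase_sim <- function(x, ...) {
  n <- nrow(x$trials)
  late <- x$trials$correct[(n %/% 2 + 1):n]
  cat(sprintf(paste0("staircase_sim: %d trials, target %.0f%%, ",
                     "accuracy last half %.1f%%, threshold estimate %.3f\n"),
              n, 100 * x$target_p, 100 * mean(late), x$threshold_estimate))
  invisible(x)
}

#' Maximum-likelihood threshold from a staircase trial table
#'
#' One-parameter Weibull threshold fit (slope, guess and lapse fixed) by
#' direct likelihood maximization over an interval; used to validate the
#' staircase's own posterior estimate.
#'
#' @param trials data.frame with `intensity` and `correct` columns.
#' @param psychometric_slope,guess,lapse Fixed psychometric parameters.
#' @param interval Search interval for the threshold.
#' @return Threshold estimate.
#' @export
fit_staircase_threshold <- function(trials, psychometric_slope = 3.5,
                                    guess = 0.5, lapse = 0.02,
                                    interval = c(-1.5, 1.5)) {
  nll <- function(th) {
    p <- .weibull_p(trials$intensity, th, psychometric_slope, guess, lapse)
    -sum(ifelse(trials$correct, log(p), log(1 - p)))
  }
  optimize(nll, interval)$minimum
}
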