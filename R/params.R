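#' Model parameters for the equivalence network
#'
#' Bundles every tunable constant of the Hebbian learning rule and the trial
#' mechanics. The defaults are the parameter set used throughout the canonical
#' replications: learning rate `beta = 0.2` and coactivation threshold
#' `theta = 0.7`, a sigmoid activation gate at net input 0.85, sub-threshold
#' decay at one quarter of the learning rate, and test-phase learning at one
#' quarter of the training rate.
#'
#' @param beta Learning rate in (0, 1]. Scales every weight change; its sign is
#'   flipped by negative feedback on incorrect training responses.
#' @param theta Coactivation threshold in (0, 1). Coactivations (products of
#'   two unit activations) at or above `theta` select the strengthening branch
#'   of the update; lower coactivations produce a decay toward zero. Plays the
#'   role of an LTP induction threshold.
#' @param activation_gate Net-input cutoff for the sigmoid. A unit only becomes
#'   active through spreading when its net input strictly exceeds this value.
#' @param decay_multiplier Fraction of the effective learning rate used for
#'   sub-threshold weight decay, in (0, 1].
#' @param test_beta_fraction Multiplier on `beta` during test phases, in
#'   (0, 1]. Test trials deliver no feedback; weights still drift slightly.
#' @param weight_min,weight_max Bounds on connection values; weights are
#'   clipped into this interval after every update.
#' @param pair_eligibility Which unit pairs receive an update on a trial:
#'   `"both_active"` (default; both activations strictly positive) or
#'   `"one_active"` (at least one activation strictly positive, so every
#'   connection touching an active unit decays when its partner is silent).
#' @param propagation Spreading-activation depth: `"single_wave"` (default;
#'   one synchronous wave from the clamped units) or `"fixpoint"` (waves
#'   repeat, newly active units becoming sources, until activations are stable
#'   to 1e-9).
#' @param max_stage_repeats Cap on repetitions of a training stage whose
#'   mastery criterion keeps failing, before the run aborts with a
#'   non-convergence error.
#'
#' @return An object of class `eq_params` (a validated list).
#' @examples
#' p <- eq_params()
#' p$beta
#' eq_params(beta = 0.1, theta = 0.72)  # learning-disability variant
#' @export
eq_params <- function(beta = 0.2,
                      theta = 0.7,
                      activation_gate = 0.85,
                      decay_multiplier = 0.25,
                      test_beta_fraction = 0.25,
                      weight_min = -1,
                      weight_max = 1,
                      pair_eligibility = c("both_active", "one_active"),
                      propagation = c("single_wave", "fixpoint"),
                      max_stage_repeats = 100L) {
  pair_eligibility <- match.arg(pair_eligibility)
  propagation <- match.arg(propagation)
  stopifnot(
    is.numeric(beta), length(beta) == 1, beta >= 0, beta <= 1,
    is.numeric(theta), length(theta) == 1, theta > 0, theta < 1,
    is.numeric(activation_gate), length(activation_gate) == 1,
    is.numeric(decay_multiplier), decay_multiplier > 0, decay_multiplier <= 1,
    is.numeric(test_beta_fraction), test_beta_fraction > 0,
    test_beta_fraction <= 1,
    is.numeric(weight_min), is.numeric(weight_max),
    weight_min < 0, weight_max > 0,
    is.numeric(max_stage_repeats), max_stage_repeats >= 1
  )
  structure(
    list(
      beta = beta, theta = theta, activation_gate = activation_gate,
      decay_multiplier = decay_multiplier,
      test_beta_fraction = test_beta_fraction,
      weight_min = weight_min, weight_max = weight_max,
      pair_eligibility = pair_eligibility, propagation = propagation,
      max_stage_repeats = as.integer(max_stage_repeats)
    ),
    class = "eq_params"
  )
}

#' @export
print.eq_params <- function(x, ...) {
  cat("<eq_params>\n")
  cat(sprintf("  beta = %g, theta = %g, gate = %g\n",
              x$beta, x$theta, x$activation_gate))
  cat(sprintf("  decay = %g * beta, test beta = %g * beta\n",
              x$decay_multiplier, x$test_beta_fraction))
  cat(sprintf("  weights in [%g, %g]; eligibility = %s; propagation = %s\n",
              x$weight_min, x$weight_max, x$pair_eligibility, x$propagation))
  invisible(x)
}

#' Parameter presets
#'
#' `eq_params_typical()` returns the default parameter set (`beta = 0.2`,
#' `theta = 0.7`); `eq_params_ld()` returns the learning-disability variant
#' with a raised coactivation (LTP) threshold and a halved learning rate
#' (`beta = 0.1`, `theta = 0.72`), which preserves trained relations but
#' abolishes derived transitivity under interleaved training.
#'
#' @param ... Overrides passed on to [eq_params()].
#' @return An `eq_params` object.
#' @export
eq_params_typical <- function(...) eq_params(...)

#' @rdname eq_params_typical
#' @export
eq_params_ld <- function(...) eq_params(beta = 0.1, theta = 0.72, ...)
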