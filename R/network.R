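#' Create a naive equivalence network
#'
#' One localist unit per stimulus, fully interconnected by bidirectional
#' (symmetric) connections. All connection values start at 0, modelling no
#' prior experience; through training they can take any value between the
#' configured bounds (default -1 to 1). The connection weight between two
#' units is read as the relatedness (associative strength) of the two stimuli.
#'
#' @param unit_labels Character vector of distinct stimulus identifiers.
#' @return An object of class `eq_network`: a list with `labels`, the symmetric
#'   `weights` matrix (zero diagonal), and the per-trial `activations` vector.
#' @examples
#' net <- eq_network(c("A1", "B1", "C1"))
#' weights(net)
#' @export
eq_network <- function(unit_labels) {
  unit_labels <- as.character(unit_labels)
  stopifnot(length(unit_labels) >= 2, !anyDuplicated(unit_labels))
  n <- length(unit_labels)
  w <- matrix(0, n, n, dimnames = list(unit_labels, unit_labels))
  structure(
    list(labels = unit_labels,
         weights = w,
         activations = stats::setNames(numeric(n), unit_labels)),
    class = "eq_network"
  )
}

#' Accessors for network state
#'
#' @param object,net An `eq_network`.
#' @param ... Ignored.
#' @return `weights()` the symmetric weight matrix; `activations()` the
#'   current per-unit activation vector; `unit_labels()` the stimulus labels.
#' @export
weights.eq_network <- function(object, ...) {
  object$weights
}

#' @rdname weights.eq_network
#' @export
activations <- function(net) {
  stopifnot(inherits(net, "eq_network"))
  net$activations
}

#' @rdname weights.eq_network
#' @importFrom stats weights
#' @export
unit_labels <- function(net) {
  stopifnot(inherits(net, "eq_network"))
  net$labels
}

#' @export
print.eq_network <- function(x, ...) {
  cat(sprintf("<eq_network> %d units: %s\n", length(x$labels),
              paste(utils::head(x$labels, 8), collapse = ", ")))
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("  %d non-zero connections; weight range [%.3g, %.3g]\n",
              nz, min(x$weights), max(x$weights)))
  invisible(x)
}

.unit_index <- function(net, units) {
  idx <- match(units, net$labels)
  if (anyNA(idx)) {
    stop("unknown unit id(s): ", paste(units[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Gated sigmoid activation
#'
#' Output function for units reached by spreading activation: the logistic
#' sigmoid of the net input, gated to 0 unless the net input strictly exceeds
#' the activation gate (default 0.85). The gate means only units that receive
#' substantial summed input from the currently active units become active at
#' all; just above the gate the output is ~0.70, so any unit activated by
#' spreading carries an activation in (0.70, 1). Never applied to clamped
#' (externally presented) units, which sit at 1.
#'
#' @param net_input Numeric vector of net inputs.
#' @param params An [eq_params()] object.
#' @return Activations in `[0, 1)`, same length as `net_input`.
#' @examples
#' gated_sigmoid(c(0, 0.85, 1), eq_params())  # 0, 0 (gate is strict), 0.731
#' @export
gated_sigmoid <- function(net_input, params = eq_params()) {
  out <- numeric(length(net_input))
  open <- net_input > params$activation_gate
  out[open] <- 1 / (1 + exp(-net_input[open]))
  out
}

#' Net inputs from a set of source units
#'
#' Every unit outside the source set performs a weighted sum of the inputs it
#' receives from the sources (weight times source activation). Because the
#' sum runs over all sources, convergent input from several partially trained
#' connections can exceed the activation gate even when no single connection
#' could — the mechanism that lets remote transitive relations bootstrap.
#'
#' @param net An `eq_network` whose `activations` hold the source activations.
#' @param source_units Character vector of source unit ids.
#' @return Named numeric vector of net inputs for all non-source units.
#' @export
net_inputs <- function(net, source_units) {
  src <- .unit_index(net, source_units)
  x <- net$activations
  others <- setdiff(seq_along(net$labels), src)
  drop(crossprod(net$weights[src, others, drop = FALSE], x[src]))
}

#' Spreading activation
#'
#' Propagates activation from the clamped units (sample and chosen comparison,
#' both at activation 1) to the rest of the layer. Each free unit receives the
#' gated sigmoid of its summed input. Excluded units (losing comparisons held
#' at 0 by lateral inhibition) never receive activation. Under
#' `propagation = "single_wave"` exactly one synchronous wave is computed;
#' under `"fixpoint"` waves repeat with newly active units joining the source
#' set until no activation changes by more than 1e-9. Clamped and excluded
#' activations are never overwritten.
#'
#' @param net An `eq_network`.
#' @param clamped_units Units clamped at activation 1.
#' @param excluded_units Units held at 0 (default none).
#' @param params An [eq_params()] object.
#' @return The network with updated `activations`.
#' @export
spread_activation <- function(net, clamped_units, excluded_units = character(),
                              params = eq_params()) {
  ci <- .unit_index(net, clamped_units)
  ei <- if (length(excluded_units)) .unit_index(net, excluded_units) else integer()
  if (length(intersect(ci, ei))) {
    stop("clamped and excluded unit sets overlap", call. = FALSE)
  }
  n <- length(net$labels)
  x <- numeric(n)
  x[ci] <- 1
  free <- setdiff(seq_len(n), c(ci, ei))
  if (length(free)) {
    if (params$propagation == "single_wave") {
      net_in <- drop(crossprod(net$weights[ci, free, drop = FALSE], x[ci]))
      x[free] <- gated_sigmoid(net_in, params)
    } else {
      repeat {
        src <- which(x > 0)
        net_in <- drop(crossprod(net$weights[src, free, drop = FALSE], x[src]))
        new <- gated_sigmoid(net_in, params)
        if (max(abs(new - x[free])) <= 1e-9) {
          x[free] <- new
          break
        }
        x[free] <- new
      }
    }
  }
  net$activations <- stats::setNames(x, net$labels)
  net
}

#' One pairwise Hebbian update
#'
#' The supervised Hebbian rule with a coactivation threshold and self-adapting
#' modulation. Let `beta_eff` be `beta` during training and
#' `beta * test_beta_fraction` during tests. When the coactivation (product of
#' the two activations) reaches the threshold `theta`, the modulation term is
#' `lambda = coactivation - w` and the applied change is
#' `feedback_sign * beta_eff * lambda` — strengthening toward the coactivation
#' after correct responses, weakening after incorrect ones. Below threshold,
#' `lambda = -w` and the change is `decay_multiplier * beta_eff * lambda`, a
#' decay toward zero that is indifferent to feedback. Test phases carry no
#' feedback signal, so `feedback_sign` is forced to +1 there.
#'
#' @param w Current connection value.
#' @param coactivation Product of the two unit activations, in `[0, 1]`.
#' @param feedback_sign +1 (correct / no feedback) or -1 (incorrect).
#' @param phase `"train"` or `"test"`.
#' @param params An [eq_params()] object.
#' @return A list of class `eq_pair_update` with `coactivation`,
#'   `lambda_value`, and `delta_w`.
#' @examples
#' pair_update(0, 1, +1, "train", eq_params())$delta_w    # +0.2
#' pair_update(0.5, 0.6, +1, "train", eq_params())$delta_w # -0.025 (decay)
#' @export
pair_update <- function(w, coactivation, feedback_sign = 1,
                        phase = c("train", "test"), params = eq_params()) {
  phase <- match.arg(phase)
  stopifnot(coactivation >= 0, coactivation <= 1,
            feedback_sign %in% c(-1, 1))
  beta_eff <- params$beta * if (phase == "test") params$test_beta_fraction else 1
  if (phase == "test") feedback_sign <- 1
  if (coactivation >= params$theta) {
    lambda <- coactivation - w
    delta <- feedback_sign * beta_eff * lambda
  } else {
    lambda <- -w
    delta <- params$decay_multiplier * beta_eff * lambda
  }
  structure(list(coactivation = coactivation, lambda_value = lambda,
                 delta_w = delta),
            class = "eq_pair_update")
}

#' Apply the Hebbian update to every eligible pair
#'
#' Synchronous update: every pairwise change is computed from the pre-trial
#' weight matrix, then all changes are applied at once, clipped into the
#' weight bounds, with symmetry and the zero diagonal preserved. Eligibility
#' follows `params$pair_eligibility`: under `"both_active"` a pair is updated
#' only when both activations are strictly positive; under `"one_active"`
#' when at least one is, so connections from active to silent units decay.
#'
#' @param net An `eq_network` whose activations reflect a completed trial.
#' @param feedback_sign +1 or -1 (forced to +1 in test phase).
#' @param phase `"train"` or `"test"`.
#' @param params An [eq_params()] object.
#' @param record If `TRUE`, attach a data frame of per-pair updates
#'   (`unit_i`, `unit_j`, `coactivation`, `lambda_value`, `delta_w`) as the
#'   `"updates"` attribute of the result.
#' @return The network with updated weights.
#' @export
apply_updates <- function(net, feedback_sign = 1, phase = c("train", "test"),
                          params = eq_params(), record = FALSE) {
  phase <- match.arg(phase)
  x <- net$activations
  w <- net$weights
  beta_eff <- params$beta * if (phase == "test") params$test_beta_fraction else 1
  if (phase == "test") feedback_sign <- 1
  active <- x > 0
  elig <- if (params$pair_eligibility == "both_active") {
    outer(active, active, "&")
  } else {
    outer(active, active, "|")
  }
  diag(elig) <- FALSE
  coact <- tcrossprod(x)
  over <- coact >= params$theta
  lambda <- ifelse(over, coact - w, -w)
  delta <- ifelse(over, feedback_sign * beta_eff * lambda,
                  params$decay_multiplier * beta_eff * lambda)
  delta[!elig] <- 0
  w <- pmin(pmax(w + delta, params$weight_min), params$weight_max)
  diag(w) <- 0
  net$weights <- w
  if (record) {
    up <- which(elig & upper.tri(elig), arr.ind = TRUE)
    attr(net, "updates") <- data.frame(
      unit_i = net$labels[up[, 1]],
      unit_j = net$labels[up[, 2]],
      coactivation = coact[up],
      lambda_value = lambda[up],
      delta_w = delta[up],
      stringsAsFactors = FALSE
    )
  }
  net
}
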