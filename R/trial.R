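#' Specify one matching-to-sample trial
#'
#' @param sample Sample stimulus unit id.
#' @param comparisons Ordered character vector of comparison unit ids (distinct,
#'   not containing the sample).
#' @param correct The class-consistent comparison; must be in `comparisons`.
#' @param phase `"train"` (feedback delivered) or `"test"` (no feedback,
#'   reduced learning rate).
#' @param relation_label Free-form tag for logging (e.g. `"A1B1"`).
#' @return An object of class `eq_trial`.
#' @export
trial_spec <- function(sample, comparisons, correct,
                       phase = c("train", "test"), relation_label = "") {
  phase <- match.arg(phase)
  comparisons <- as.character(comparisons)
  stopifnot(
    length(sample) == 1, length(correct) == 1,
    length(comparisons) >= 1,
    !anyDuplicated(comparisons),
    !(sample %in% comparisons),
    correct %in% comparisons
  )
  structure(
    list(sample = as.character(sample), comparisons = comparisons,
         correct = as.character(correct), phase = phase,
         relation_label = relation_label),
    class = "eq_trial"
  )
}

#' Comparison selection with lateral inhibition
#'
#' Each comparison unit computes the raw (ungated) input it receives from the
#' sample unit alone, i.e. its connection weight to the sample. The most
#' active comparison wins, transforms its activation to 1 and becomes the
#' response unit; the losers are set to 0, simulating competition through
#' lateral inhibition. Exact ties — including the all-zero naive network —
#' are broken uniformly at random.
#'
#' @param net An `eq_network`.
#' @param sample Sample unit id.
#' @param comparisons Character vector of comparison unit ids.
#' @return The chosen unit id; the number of random draws consumed (0 or 1)
#'   is attached as attribute `"rng_draws"`.
#' @export
select_comparison <- function(net, sample, comparisons) {
  if (length(comparisons) == 0) stop("empty comparison list", call. = FALSE)
  si <- .unit_index(net, sample)
  ci <- .unit_index(net, comparisons)
  scores <- net$weights[si, ci]
  cand <- which(scores == max(scores))
  draws <- 0L
  pick <- if (length(cand) > 1L) {
    draws <- 1L
    cand[sample.int(length(cand), 1L)]
  } else {
    cand
  }
  structure(comparisons[pick], rng_draws = draws)
}

#' Run one matching-to-sample trial
#'
#' The trial sequence is: clear all activations; clamp the sample unit to 1;
#' let the comparison units compete on their raw input from the sample and
#' clamp the winner to 1 (losers to 0, excluded from spreading); propagate
#' activation to the remaining units; determine the feedback sign (+1 for a
#' correct choice, -1 for an incorrect one; always +1 with the reduced
#' learning rate during test phases); and apply the synchronous Hebbian update
#' to every eligible pair.
#'
#' @param net An `eq_network`.
#' @param trial An [trial_spec()] object.
#' @param params An [eq_params()] object.
#' @param record_updates If `TRUE`, keep the per-pair update records in the
#'   outcome (slower; for audits).
#' @return A list with elements `network` (updated state) and `outcome`, an
#'   `eq_outcome` list: `chosen`, `is_correct`, `active_units` (named
#'   activations of all units that were active), `updates` (data frame or
#'   `NULL`), `rng_draws`.
#' @examples
#' net <- eq_network(c("A1", "B1", "B2"))
#' tr <- trial_spec("A1", c("B1", "B2"), "B1")
#' set.seed(1)
#' res <- run_trial(net, tr)
#' res$outcome$chosen
#' @export
run_trial <- function(net, trial, params = eq_params(), record_updates = FALSE) {
  stopifnot(inherits(trial, "eq_trial"))
  net$activations[] <- 0
  chosen <- select_comparison(net, trial$sample, trial$comparisons)
  draws <- attr(chosen, "rng_draws")
  chosen <- as.character(chosen)
  losers <- setdiff(trial$comparisons, chosen)
  net <- spread_activation(net, clamped_units = c(trial$sample, chosen),
                           excluded_units = losers, params = params)
  is_correct <- chosen == trial$correct
  feedback <- if (trial$phase == "train" && !is_correct) -1 else 1
  net <- apply_updates(net, feedback_sign = feedback, phase = trial$phase,
                       params = params, record = record_updates)
  updates <- attr(net, "updates")
  attr(net, "updates") <- NULL
  outcome <- structure(
    list(chosen = chosen,
         is_correct = is_correct,
         active_units = net$activations[net$activations > 0],
         updates = updates,
         rng_draws = draws),
    class = "eq_outcome"
  )
  list(network = net, outcome = outcome)
}
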