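#' Specify one protocol stage
#'
#' A stage is a block template: how many trials of each relation a block
#' contains, whether the block is shuffled, which phase it runs in, its
#' mastery criterion, and (for criterion-free training stages) how many blocks
#' to run.
#'
#' @param name Stage label, used in logs and error messages.
#' @param trial_counts Named integer vector: relation key (class-specific like
#'   `"A1B1"`, or set-level like `"AB"` which is split as evenly as possible
#'   across classes with remainders assigned at random) to repetitions per
#'   block.
#' @param phase `"train"` or `"test"`.
#' @param criterion `NULL` for none, or a list/ string: `"19/20"` means at
#'   least 19 correct of the 20 block trials; `list(min_correct=, out_of=,
#'   consecutive=)` with `consecutive = TRUE` requires a run of at least
#'   `min_correct` consecutive correct responses within the block.
#' @param shuffle Randomize trial order within each block (re-shuffled for
#'   every repeated block).
#' @param n_blocks Number of blocks to run when there is no criterion
#'   (criterion stages repeat until mastery instead; test stages with no
#'   criterion run `n_blocks` blocks, default 1).
#' @return An object of class `eq_stage`.
#' @export
stage_spec <- function(name, trial_counts, phase = c("train", "test"),
                       criterion = NULL, shuffle = TRUE, n_blocks = 1L) {
  phase <- match.arg(phase)
  stopifnot(is.character(name), length(name) == 1,
            length(trial_counts) >= 1, !is.null(names(trial_counts)),
            all(nzchar(names(trial_counts))), all(trial_counts >= 1))
  criterion <- .as_criterion(criterion)
  if (!is.null(criterion) && !criterion$consecutive) {
    if (criterion$out_of != sum(trial_counts)) {
      stop("criterion out_of (", criterion$out_of,
           ") must equal the block size (", sum(trial_counts), ")",
           call. = FALSE)
    }
  }
  structure(
    list(name = name,
         trial_counts = stats::setNames(as.integer(trial_counts),
                                        names(trial_counts)),
         phase = phase, criterion = criterion,
         shuffle = isTRUE(shuffle), n_blocks = as.integer(n_blocks)),
    class = "eq_stage"
  )
}

.as_criterion <- function(criterion) {
  if (is.null(criterion)) return(NULL)
  if (is.character(criterion)) {
    parts <- as.integer(strsplit(criterion, "/", fixed = TRUE)[[1]])
    stopifnot(length(parts) == 2)
    criterion <- list(min_correct = parts[1], out_of = parts[2],
                      consecutive = FALSE)
  }
  stopifnot(is.list(criterion),
            all(c("min_correct", "out_of") %in% names(criterion)))
  list(min_correct = as.integer(criterion$min_correct),
       out_of = as.integer(criterion$out_of),
       consecutive = isTRUE(criterion$consecutive))
}

#' Assemble a full protocol
#'
#' @param name Protocol label.
#' @param structure An [class_structure()] object.
#' @param stages List of [stage_spec()] objects, run in order over one
#'   evolving network.
#' @param params An [eq_params()] object.
#' @param tracked_pairs List of 2-element character vectors of unit labels
#'   whose weights are snapshot after every block (the learning trajectory).
#' @param seed Default seed used by [run_protocol()] when none is given.
#' @return An object of class `eq_protocol`.
#' @export
protocol_spec <- function(name, structure, stages, params = eq_params(),
                          tracked_pairs = list(), seed = 1L) {
  stopifnot(inherits(structure, "eq_structure"),
            all(vapply(stages, inherits, TRUE, "eq_stage")),
            inherits(params, "eq_params"))
  units <- structure_units(structure)
  for (st in stages) {
    for (key in names(st$trial_counts)) {
      rel <- parse_relation(key)
      if (!all(c(rel$source, rel$target) %in% structure$roles)) {
        stop("stage '", st$name, "' references unknown roles in ", key,
             call. = FALSE)
      }
      if (!is.na(rel$class_index) && rel$class_index > structure$n_classes) {
        stop("stage '", st$name, "' references unknown class in ", key,
             call. = FALSE)
      }
    }
  }
  for (p in tracked_pairs) stopifnot(all(p %in% units))
  structure(
    list(name = name, structure = structure, stages = stages,
         params = params, tracked_pairs = tracked_pairs,
         seed = as.integer(seed)),
    class = "eq_protocol"
  )
}

#' @export
print.eq_protocol <- function(x, ...) {
  cat(sprintf("<eq_protocol> %s: %d stages, %d units\n", x$name,
              length(x$stages), length(structure_units(x$structure))))
  for (st in x$stages) {
    crit <- if (is.null(st$criterion)) {
      if (st$n_blocks > 1) paste0(st$n_blocks, " blocks") else "one block"
    } else {
      paste0(st$criterion$min_correct, "/", st$criterion$out_of,
             if (st$criterion$consecutive) " consecutive" else "")
    }
    cat(sprintf("  %-28s %5d trials/block [%s] %s\n", st$name,
                sum(st$trial_counts), st$phase, crit))
  }
  invisible(x)
}

#' Expand a stage into one block of trials
#'
#' Class-specific relation counts are repeated verbatim; set-level counts
#' (e.g. `AB = 8` in a 3-class structure) are split as evenly as possible
#' across classes, remaining trials going to classes drawn at random. The
#' block is then uniformly shuffled if the stage asks for it.
#'
#' @param stage An [stage_spec()].
#' @param structure An [class_structure()].
#' @return List of `eq_trial` objects.
#' @export
build_block <- function(stage, structure) {
  trials <- list()
  for (key in names(stage$trial_counts)) {
    n <- stage$trial_counts[[key]]
    rel <- parse_relation(key)
    if (!is.na(rel$class_index)) {
      tr <- build_comparisons(structure, c(rel$source, rel$target),
                              rel$class_index, phase = stage$phase)
      trials <- c(trials, rep(list(tr), n))
    } else {
      k <- structure$n_classes
      per <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) {
        lucky <- sample.int(k, extra)
        per[lucky] <- per[lucky] + 1L
      }
      for (cls in seq_len(k)) {
        if (per[cls] == 0) next
        tr <- build_comparisons(structure, c(rel$source, rel$target), cls,
                                phase = stage$phase)
        trials <- c(trials, rep(list(tr), per[cls]))
      }
    }
  }
  if (stage$shuffle && length(trials) > 1) {
    trials <- trials[sample.int(length(trials))]
  }
  trials
}

#' Evaluate a mastery criterion over one block
#'
#' @param correct Logical vector of per-trial correctness for one block.
#' @param criterion A criterion list (see [stage_spec()]); `NULL` always
#'   passes.
#' @return `TRUE` if the block meets the criterion.
#' @export
evaluate_criterion <- function(correct, criterion) {
  criterion <- .as_criterion(criterion)
  if (is.null(criterion)) return(TRUE)
  if (criterion$consecutive) {
    runs <- rle(correct)
    any(runs$values & runs$lengths >= criterion$min_correct)
  } else {
    sum(correct) >= criterion$min_correct
  }
}

#' Run one stage to mastery
#'
#' Builds and runs blocks until the stage criterion passes or the repeat cap
#' is reached. Weights persist across repeated blocks (criterion failures do
#' not roll anything back). Stages without a criterion run a fixed number of
#' blocks. A stage that cannot converge (e.g. with a zero learning rate the
#' network never beats chance) aborts with an error of class
#' `eq_nonconvergence` naming the stage.
#'
#' @param net An `eq_network`.
#' @param stage An [stage_spec()].
#' @param structure The protocol's [class_structure()].
#' @param params An [eq_params()] object.
#' @param record_updates Keep per-pair update records in the trial log.
#' @return List with `network` and `log`, the per-trial data frame for the
#'   block.
#' @keywords internal
run_stage_once <- function(net, stage, structure, params,
                           record_updates = FALSE) {
  block <- build_block(stage, structure)
  n <- length(block)
  chosen <- character(n)
  correct <- logical(n)
  draws <- integer(n)
  for (i in seq_len(n)) {
    res <- run_trial(net, block[[i]], params, record_updates = record_updates)
    net <- res$network
    chosen[i] <- res$outcome$chosen
    correct[i] <- res$outcome$is_correct
    draws[i] <- res$outcome$rng_draws
  }
  log <- data.frame(
    phase = stage$phase,
    sample = vapply(block, function(t) t$sample, ""),
    comparisons = vapply(block, function(t) paste(t$comparisons,
                                                  collapse = "|"), ""),
    chosen = chosen,
    correct = vapply(block, function(t) t$correct, ""),
    is_correct = correct,
    relation_label = vapply(block, function(t) t$relation_label, ""),
    rng_draws = draws,
    stringsAsFactors = FALSE
  )
  list(network = net, log = log)
}

#' Run a stage (with criterion repetition) inside a protocol
#' @inheritParams run_stage_once
#' @param snapshot Function taking the network, called after every block.
#' @return List with `network`, `trial_log`, `block_log`.
#' @export
run_stage <- function(net, stage, structure, params = eq_params(),
                      record_updates = FALSE, snapshot = NULL) {
  stopifnot(inherits(stage, "eq_stage"))
  trial_logs <- list()
  blocks <- list()
  fixed_blocks <- is.null(stage$criterion)
  target_blocks <- if (fixed_blocks) stage$n_blocks else NA_integer_
  b <- 0L
  repeat {
    b <- b + 1L
    res <- run_stage_once(net, stage, structure, params, record_updates)
    net <- res$network
    passed <- evaluate_criterion(res$log$is_correct, stage$criterion)
    res$log$stage <- stage$name
    res$log$block <- b
    trial_logs[[b]] <- res$log
    blocks[[b]] <- data.frame(stage = stage$name, block = b,
                              n_trials = nrow(res$log),
                              n_correct = sum(res$log$is_correct),
                              passed = passed, stringsAsFactors = FALSE)
    if (!is.null(snapshot)) snapshot(net)
    if (fixed_blocks) {
      if (b >= target_blocks) break
    } else if (passed) {
      break
    } else if (b >= params$max_stage_repeats) {
      cond <- structure(
        class = c("eq_nonconvergence", "error", "condition"),
        list(message = sprintf(
          "stage '%s' failed its criterion %d times (max_stage_repeats)",
          stage$name, b),
          call = NULL, stage = stage$name))
      stop(cond)
    }
  }
  list(network = net,
       trial_log = do.call(rbind, trial_logs),
       block_log = do.call(rbind, blocks))
}

#' Run a complete staged protocol
#'
#' Runs the protocol's stages in order over a single evolving network, fully
#' reproducibly: the master seed deterministically spawns one child seed per
#' stage, so all shuffles, remainder assignments and tie-break draws are fixed
#' by `seed` alone, and inserting a stage does not perturb the streams of
#' later stages. Tracked pair weights are snapshot after every block.
#'
#' @param protocol An [protocol_spec()] object.
#' @param seed Integer master seed (defaults to the protocol's own).
#' @param record_updates Keep per-pair update records (slow; audits only).
#' @return An object of class `eq_run`: `protocol_name`, `seed`,
#'   `final_network`, `trajectory` (matrix: blocks x tracked pairs),
#'   `trajectory_stage` (stage name per trajectory row), `stage_log`,
#'   `trial_log`, `structure`, `params`.
#' @examples
#' pr <- make_protocol("sim1")
#' run <- run_protocol(pr, seed = 1)
#' utils::tail(run$trajectory, 3)
#' @export
run_protocol <- function(protocol, seed = protocol$seed,
                         record_updates = FALSE) {
  stopifnot(inherits(protocol, "eq_protocol"))
  net <- eq_network(structure_units(protocol$structure))
  n_stages <- length(protocol$stages)
  set.seed(as.integer(seed))
  stage_seeds <- sample.int(.Machine$integer.max - 1L, max(n_stages, 1L))
  traj <- list()
  traj_stage <- character()
  pairs <- protocol$tracked_pairs
  snapshot <- if (length(pairs)) {
    function(net) {
      w <- vapply(pairs, function(p) net$weights[p[1], p[2]], 0)
      traj[[length(traj) + 1L]] <<- w
    }
  } else {
    NULL
  }
  trial_logs <- list()
  block_logs <- list()
  for (i in seq_len(n_stages)) {
    st <- protocol$stages[[i]]
    set.seed(stage_seeds[i])
    before <- length(traj)
    res <- run_stage(net, st, protocol$structure, protocol$params,
                     record_updates = record_updates, snapshot = snapshot)
    net <- res$network
    trial_logs[[i]] <- res$trial_log
    block_logs[[i]] <- res$block_log
    traj_stage <- c(traj_stage, rep(st$name, length(traj) - before))
  }
  trial_log <- do.call(rbind, trial_logs)
  if (!is.null(trial_log) && nrow(trial_log)) {
    trial_log$trial_index <- seq_len(nrow(trial_log))
    trial_log <- trial_log[, c("trial_index", "stage", "block", "phase",
                               "sample", "comparisons", "chosen", "correct",
                               "is_correct", "relation_label", "rng_draws")]
  }
  trajectory <- if (length(traj)) {
    m <- do.call(rbind, traj)
    colnames(m) <- vapply(pairs, paste, "", collapse = "")
    m
  } else {
    matrix(numeric(), 0, 0)
  }
  structure(
    list(protocol_name = protocol$name,
         seed = as.integer(seed),
         final_network = net,
         trajectory = trajectory,
         trajectory_stage = traj_stage,
         stage_log = do.call(rbind, block_logs),
         trial_log = trial_log,
         structure = protocol$structure,
         params = protocol$params),
    class = "eq_run"
  )
}

#' @export
print.eq_run <- function(x, ...) {
  cat(sprintf("<eq_run> %s (seed %d): %d trials over %d blocks\n",
              x$protocol_name, x$seed,
              if (is.null(x$trial_log)) 0L else nrow(x$trial_log),
              if (is.null(x$stage_log)) 0L else nrow(x$stage_log)))
  invisible(x)
}
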