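#' Relatedness of all within-class stimulus pairs, by relation category
#'
#' Reads the final weight matrix of a run as a relatedness table: every
#' unordered within-class pair is assigned its nodal distance on the trained
#' baseline graph (distance 0 = directly trained baseline pair; distance k =
#' k-node transitive pair). Because connections are bidirectional, a symmetry
#' or combined probe shares the weight of its baseline/transitive
#' counterpart; the table reports one row per unordered pair and carries the
#' distance so directional categories can be read off.
#'
#' @param result An `eq_run` from [run_protocol()].
#' @param structure The matching [class_structure()]; defaults to the run's.
#' @return An object of class `eq_relatedness`: a data frame with columns
#'   `class_index`, `pair`, `role_i`, `role_j`, `distance`, `category`
#'   (`"baseline"` or `"k-node"`), `weight`.
#' @examples
#' run <- run_protocol(make_protocol("sim1"), seed = 1)
#' relatedness_by_category(run)
#' @export
relatedness_by_category <- function(result, structure = result$structure) {
  stopifnot(inherits(result, "eq_run"), inherits(structure, "eq_structure"))
  w <- result$final_network$weights
  if (!all(structure_units(structure) %in% rownames(w))) {
    stop("structure does not match the run's network", call. = FALSE)
  }
  roles <- structure$roles
  rows <- list()
  for (cls in seq_len(structure$n_classes)) {
    for (i in seq_along(roles)[-length(roles)]) {
      for (j in seq.int(i + 1, length(roles))) {
        d <- nodal_distance(structure, roles[i], roles[j])
        ui <- paste0(roles[i], cls)
        uj <- paste0(roles[j], cls)
        rows[[length(rows) + 1L]] <- data.frame(
          class_index = cls,
          pair = paste0(ui, "-", uj),
          role_i = roles[i], role_j = roles[j],
          distance = d,
          category = if (d == 0) "baseline" else paste0(d, "-node"),
          weight = w[ui, uj],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eq_relatedness", class(out))
  out
}

#' Mean relatedness as a function of nodal distance
#'
#' Pools the relatedness table across classes and returns the mean weight at
#' each nodal distance, ascending from 0 (baseline). This is the model's
#' nodal-distance profile: under staged linear-series training it decreases
#' with distance.
#'
#' @param table An `eq_relatedness` table from [relatedness_by_category()].
#' @return Data frame with columns `distance`, `category`, `mean_weight`,
#'   `n_pairs`.
#' @export
nodal_profile <- function(table) {
  stopifnot(inherits(table, "eq_relatedness"))
  agg <- stats::aggregate(weight ~ distance + category, data = table, FUN = mean)
  cnt <- stats::aggregate(weight ~ distance, data = table, FUN = length)
  agg <- agg[order(agg$distance), ]
  data.frame(distance = agg$distance, category = agg$category,
             mean_weight = agg$weight,
             n_pairs = cnt$weight[match(agg$distance, cnt$distance)],
             row.names = NULL)
}

#' Epoch at which a tracked pair first exceeds a threshold
#'
#' Scans a run's per-block trajectory for the first block (1-based; for
#' epoch-structured protocols one block is one epoch) at which the tracked
#' pair's weight strictly exceeds `threshold`. Used to date the emergence of
#' a derived relation (default threshold 0: first departure from naivety).
#'
#' @param result An `eq_run` whose protocol tracked the pair.
#' @param pair Character vector of the two unit labels, or the collapsed
#'   column name (e.g. `"A1C1"`).
#' @param threshold Weight that must be strictly exceeded.
#' @return Integer epoch index, or `NA_integer_` if the pair never exceeds
#'   the threshold.
#' @export
emergence_epoch <- function(result, pair, threshold = 0) {
  stopifnot(inherits(result, "eq_run"))
  key <- paste(pair, collapse = "")
  if (!key %in% colnames(result$trajectory)) {
    stop("pair ", key, " was not tracked in this run", call. = FALSE)
  }
  hits <- which(result$trajectory[, key] > threshold)
  if (length(hits)) hits[1L] else NA_integer_
}

#' Percent correct, grouped by stage or relation category
#'
#' Summarizes the trial log. With `grouping = "stage"`, one row per stage;
#' with `"relation_category"`, trials are grouped by the behavioral category
#' of their relation (baseline, symmetry, transitivity, combined) as judged
#' against class membership, separately for training and test phases.
#'
#' @param result An `eq_run`.
#' @param grouping `"stage"` or `"relation_category"`.
#' @return Data frame with group columns, `n_trials`, `n_correct`,
#'   `pct_correct` (rounded to one decimal).
#' @export
accuracy_summary <- function(result,
                             grouping = c("stage", "relation_category")) {
  grouping <- match.arg(grouping)
  log <- result$trial_log
  stopifnot(!is.null(log), nrow(log) > 0)
  if (grouping == "stage") {
    groups <- list(stage = log$stage)
  } else {
    cats <- vapply(log$relation_label, function(lbl) {
      rel <- parse_relation(lbl)
      as.character(relation_category(result$structure, rel$source, rel$target))
    }, "", USE.NAMES = FALSE)
    groups <- list(phase = log$phase, category = cats)
  }
  agg_n <- stats::aggregate(log$is_correct, by = groups, FUN = length)
  agg_c <- stats::aggregate(log$is_correct, by = groups, FUN = sum)
  out <- agg_n
  names(out)[ncol(out)] <- "n_trials"
  out$n_correct <- agg_c$x
  out$pct_correct <- round(100 * out$n_correct / out$n_trials, 1)
  out
}

#' Run a packaged replication across seeds
#'
#' Runs [make_protocol()] for each seed and aggregates: the per-distance mean
#' relatedness profile (mean and sd over seeds), final weights of the tracked
#' pairs, and (when tracked) the emergence epoch of each tracked pair.
#'
#' @param study,variant Passed to [make_protocol()].
#' @param seeds Integer vector of seeds (default `1:20`).
#' @param params Optional [eq_params()] override.
#' @return A list of class `eq_replication`: `study`, `variant`, `seeds`,
#'   `profile` (data frame distance x mean/sd over seeds), `tracked`
#'   (matrix seeds x tracked pairs of final weights), `emergence` (matrix of
#'   first-positive epochs), `runs` (list of `eq_run`, in seed order).
#' @export
replicate_study <- function(study, variant = "default", seeds = 1:20,
                            params = NULL) {
  proto <- make_protocol(study, variant, params = params)
  runs <- lapply(seeds, function(s) run_protocol(proto, seed = s))
  profiles <- lapply(runs, function(r) nodal_profile(relatedness_by_category(r)))
  dists <- profiles[[1]]$distance
  prof_mat <- vapply(profiles, function(p) p$mean_weight, numeric(length(dists)))
  prof_mat <- matrix(prof_mat, nrow = length(dists))
  tracked_names <- colnames(runs[[1]]$trajectory)
  tracked <- t(vapply(runs, function(r) {
    utils::tail(r$trajectory, 1)[1, ]
  }, numeric(length(tracked_names))))
  emergence <- t(vapply(runs, function(r) {
    vapply(tracked_names, function(nm) {
      as.numeric(emergence_epoch(r, nm))
    }, 0)
  }, numeric(length(tracked_names))))
  structure(
    list(study = study, variant = variant, seeds = seeds,
         profile = data.frame(
           distance = dists,
           category = profiles[[1]]$category,
           mean_weight = rowMeans(prof_mat),
           sd_weight = apply(prof_mat, 1, stats::sd),
           n_pairs = profiles[[1]]$n_pairs
         ),
         tracked = tracked,
         emergence = emergence,
         runs = runs),
    class = "eq_replication"
  )
}

#' @export
print.eq_replication <- function(x, ...) {
  cat(sprintf("<eq_replication> %s/%s over %d seeds\n", x$study, x$variant,
              length(x$seeds)))
  print(x$profile, row.names = FALSE)
  invisible(x)
}
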