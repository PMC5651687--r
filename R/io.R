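#' Read and write weight matrices
#'
#' Weight matrices serialize as CSV (unit labels as header row and first
#' column, full symmetric matrix) or as JSON objects `{labels, matrix}`.
#' Round-trips are lossless to better than 1e-12 (values are written with
#' full precision).
#'
#' @param net An `eq_network`.
#' @param path Output file.
#' @return `write_*` invisibly return `path`; `read_*` return an
#'   `eq_network` with zeroed activations.
#' @export
write_weights_csv <- function(net, path) {
  stopifnot(inherits(net, "eq_network"))
  df <- as.data.frame(net$weights)
  df <- cbind(unit = net$labels, df)
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(labels, labels)
  net <- eq_network(labels)
  net$weights <- m
  net
}

#' @rdname write_weights_csv
#' @export
write_weights_json <- function(net, path) {
  stopifnot(inherits(net, "eq_network"))
  jsonlite::write_json(
    list(labels = net$labels, matrix = net$weights),
    path, auto_unbox = FALSE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- as.character(obj$labels)
  m <- matrix(as.numeric(obj$matrix), length(labels), length(labels),
              byrow = FALSE)
  # rowmajor export of a symmetric matrix is orientation-safe
  dimnames(m) <- list(labels, labels)
  net <- eq_network(labels)
  net$weights <- m
  net
}

#' Write a run's trial log as CSV
#'
#' Columns: trial_index, stage, block, phase, sample, comparisons (separated
#' by `|`), chosen, correct, is_correct, relation_label, rng_draws, seed.
#'
#' @param result An `eq_run`.
#' @param path Output file.
#' @export
write_trial_log_csv <- function(result, path) {
  stopifnot(inherits(result, "eq_run"))
  log <- result$trial_log
  log$seed <- result$seed
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a protocol to YAML
#'
#' The YAML document stores the class structure (classes, members, trained
#' relations), the parameter set, the stage list (with criteria in `"19/20"`
#' form plus a consecutive flag), tracked pairs and the default seed.
#' [read_protocol_yaml()] reconstructs an identical [protocol_spec()].
#'
#' @param protocol An `eq_protocol`.
#' @param path Output file.
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "eq_protocol"))
  st <- protocol$structure
  doc <- list(
    name = protocol$name,
    seed = protocol$seed,
    structure = list(
      n_classes = st$n_classes,
      n_members = st$n_members,
      roles = as.list(st$roles),
      trained_relations = lapply(st$trained_relations, paste, collapse = ""),
      n_comparisons = st$n_comparisons
    ),
    parameters = unclass(protocol$params),
    tracked_pairs = lapply(protocol$tracked_pairs, as.list),
    stages = lapply(protocol$stages, function(s) {
      out <- list(
        name = s$name,
        phase = s$phase,
        trial_counts = as.list(s$trial_counts),
        shuffle = s$shuffle,
        n_blocks = s$n_blocks
      )
      if (!is.null(s$criterion)) {
        out$criterion <- paste0(s$criterion$min_correct, "/",
                                s$criterion$out_of)
        out$consecutive <- s$criterion$consecutive
      }
      out
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  st <- class_structure(
    n_classes = doc$structure$n_classes,
    n_members = doc$structure$n_members,
    trained_relations = unlist(doc$structure$trained_relations),
    roles = unlist(doc$structure$roles),
    n_comparisons = doc$structure$n_comparisons
  )
  p <- doc$parameters
  params <- eq_params(
    beta = p$beta, theta = p$theta, activation_gate = p$activation_gate,
    decay_multiplier = p$decay_multiplier,
    test_beta_fraction = p$test_beta_fraction,
    weight_min = p$weight_min, weight_max = p$weight_max,
    pair_eligibility = p$pair_eligibility, propagation = p$propagation,
    max_stage_repeats = p$max_stage_repeats
  )
  stages <- lapply(doc$stages, function(s) {
    crit <- if (is.null(s$criterion)) {
      NULL
    } else {
      c(.as_criterion(s$criterion)[1:2],
        list(consecutive = isTRUE(s$consecutive)))
    }
    stage_spec(s$name, unlist(s$trial_counts), phase = s$phase,
               criterion = crit, shuffle = s$shuffle, n_blocks = s$n_blocks)
  })
  protocol_spec(doc$name, st, stages, params = params,
                tracked_pairs = lapply(doc$tracked_pairs,
                                       function(p) unlist(p)),
                seed = doc$seed)
}

#' Export a class structure as JSON
#'
#' @param structure An `eq_structure`.
#' @param path Output file.
#' @export
write_structure_json <- function(structure, path) {
  stopifnot(inherits(structure, "eq_structure"))
  jsonlite::write_json(
    list(classes = lapply(seq_len(structure$n_classes),
                          function(k) paste0(structure$roles, k)),
         roles = structure$roles,
         trained_edges = lapply(structure$trained_relations, identity),
         n_comparisons = structure$n_comparisons),
    path, auto_unbox = FALSE
  )
  invisible(path)
}
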