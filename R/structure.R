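#' Define a stimulus-class structure
#'
#' A structure holds `n_classes` parallel stimulus classes, each with one
#' member per role (roles `A`, `B`, `C`, ... by default, so member labels are
#' `A1`, `B2`, etc.), plus the baseline relation graph: the ordered role pairs
#' that are directly trained (e.g. `A->B`, `B->C` for linear series training).
#' Everything else about a protocol — comparison sets, nodal distances,
#' derived-relation categories — is computed from this object.
#'
#' @param n_classes Number of classes (>= 2, so distractor comparisons exist).
#' @param n_members Members per class (>= 2).
#' @param trained_relations List of 2-element character vectors of roles, or a
#'   character vector of 2-letter strings (e.g. `c("AB", "BC")`), giving the
#'   directed baseline relations.
#' @param roles Role names; default the first `n_members` capital letters.
#' @param n_comparisons Comparisons per trial; defaults to `n_classes`.
#' @return An object of class `eq_structure`.
#' @examples
#' class_structure(3, 7, c("AB", "BC", "CD", "DE", "EF", "FG"))
#' @export
class_structure <- function(n_classes, n_members, trained_relations,
                            roles = LETTERS[seq_len(n_members)],
                            n_comparisons = n_classes) {
  stopifnot(n_classes >= 2, n_members >= 2, length(roles) == n_members,
            !anyDuplicated(roles))
  trained <- .as_role_pairs(trained_relations)
  for (p in trained) {
    if (!all(p %in% roles)) {
      stop("trained relation uses unknown role: ", paste(p, collapse = ""),
           call. = FALSE)
    }
  }
  st <- structure(
    list(n_classes = as.integer(n_classes),
         n_members = as.integer(n_members),
         roles = roles,
         trained_relations = trained,
         n_comparisons = as.integer(n_comparisons)),
    class = "eq_structure"
  )
  g <- .role_graph(st)
  if (igraph::components(g)$no > 1) {
    stop("trained-relation graph does not connect every role; ",
         "derived relations would be undefined", call. = FALSE)
  }
  st
}

.as_role_pairs <- function(rel) {
  if (is.character(rel)) rel <- as.list(rel)
  lapply(rel, function(p) {
    if (is.character(p) && length(p) == 1) p <- strsplit(p, "")[[1]]
    stopifnot(length(p) == 2)
    as.character(p)
  })
}

.role_graph <- function(structure) {
  edges <- unlist(structure$trained_relations)
  igraph::graph_from_data_frame(
    d = matrix(edges, ncol = 2, byrow = TRUE),
    directed = FALSE,
    vertices = structure$roles
  )
}

#' @export
print.eq_structure <- function(x, ...) {
  cat(sprintf("<eq_structure> %d classes x %d members (roles %s)\n",
              x$n_classes, x$n_members, paste(x$roles, collapse = "")))
  cat("  trained:", paste(vapply(x$trained_relations, paste, "", collapse = ""),
                          collapse = ", "), "\n")
  invisible(x)
}

#' All stimulus labels of a structure
#'
#' @param structure An `eq_structure`.
#' @return Character vector `A1, B1, ..., A2, ...` (class-major order).
#' @export
structure_units <- function(structure) {
  stopifnot(inherits(structure, "eq_structure"))
  as.vector(vapply(seq_len(structure$n_classes),
                   function(k) paste0(structure$roles, k),
                   character(structure$n_members)))
}

#' Member label for a role within a class
#' @noRd
.member <- function(structure, role, class_index) paste0(role, class_index)

#' Build the trial fields for one relation and class
#'
#' The sample is the source-role member of the given class; the comparisons
#' are the target-role members of every class (the correct one plus the
#' same-role distractors from the other classes); the correct answer is the
#' target-role member of the sample's class.
#'
#' @param structure An `eq_structure`.
#' @param relation A role pair, e.g. `c("A", "B")` or `"AB"`.
#' @param class_index Class of the sample (1-based).
#' @param phase Trial phase for the resulting [trial_spec()].
#' @return An `eq_trial`.
#' @examples
#' st <- class_structure(3, 3, c("AB", "BC"))
#' build_comparisons(st, "AB", 1)  # sample A1, comparisons B1 B2 B3
#' @export
build_comparisons <- function(structure, relation, class_index,
                              phase = c("train", "test")) {
  phase <- match.arg(phase)
  stopifnot(inherits(structure, "eq_structure"))
  pair <- .as_role_pairs(list(relation))[[1]]
  if (!all(pair %in% structure$roles)) {
    stop("unknown role in relation: ", paste(pair, collapse = ""), call. = FALSE)
  }
  if (class_index < 1 || class_index > structure$n_classes) {
    stop("class_index out of range", call. = FALSE)
  }
  comps <- paste0(pair[2], seq_len(structure$n_classes))
  trial_spec(
    sample = .member(structure, pair[1], class_index),
    comparisons = comps,
    correct = .member(structure, pair[2], class_index),
    phase = phase,
    relation_label = paste0(pair[1], class_index, pair[2], class_index)
  )
}

#' Nodal distance between two roles
#'
#' The number of nodal stimuli separating two class members on the trained
#' baseline graph: the shortest undirected path length minus one. Directly
#' trained pairs have distance 0; in a linear series A-B-C-...,
#' `nodal_distance(st, "A", "C")` is 1 (one intervening node, B).
#'
#' @param structure An `eq_structure`.
#' @param role_i,role_j Role names.
#' @return Non-negative integer.
#' @export
nodal_distance <- function(structure, role_i, role_j) {
  stopifnot(inherits(structure, "eq_structure"),
            role_i %in% structure$roles, role_j %in% structure$roles)
  if (role_i == role_j) return(0L)
  d <- igraph::distances(.role_graph(structure), v = role_i, to = role_j)[1, 1]
  if (!is.finite(d)) stop("roles are disconnected in the trained graph",
                          call. = FALSE)
  as.integer(d) - 1L
}

#' Generate a training structure
#'
#' Convenience constructors for the two standard training topologies:
#' `linear_series` trains role1->role2, role2->role3, ...; `one_to_many`
#' (cluster training) trains role1->role2, role1->role3, ... from a single
#' node.
#'
#' @param topology `"linear_series"` or `"one_to_many"`.
#' @param n_classes Number of classes (>= 2).
#' @param n_members Members per class (>= 2).
#' @return An `eq_structure`.
#' @examples
#' generate_structure("linear_series", 3, 7)  # trains AB..FG
#' @export
generate_structure <- function(topology = c("linear_series", "one_to_many"),
                               n_classes, n_members) {
  topology <- match.arg(topology)
  stopifnot(n_classes >= 2, n_members >= 2)
  roles <- LETTERS[seq_len(n_members)]
  trained <- if (topology == "linear_series") {
    lapply(seq_len(n_members - 1), function(i) roles[c(i, i + 1)])
  } else {
    lapply(seq.int(2, n_members), function(i) roles[c(1, i)])
  }
  class_structure(n_classes, n_members, trained, roles = roles)
}

#' Parse a relation key
#'
#' Relation keys in stage specifications are either class-specific
#' (`"A1B1"`: role pair A->B in class 1) or set-level (`"AB"`: role pair
#' across all classes).
#'
#' @param key Relation string.
#' @return List with `source`, `target` (roles) and `class_index`
#'   (`NA` for set-level keys).
#' @export
parse_relation <- function(key) {
  m <- regmatches(key, regexec("^([A-Za-z])([0-9]*)([A-Za-z])([0-9]*)$", key))[[1]]
  if (length(m) == 0) stop("malformed relation key: ", key, call. = FALSE)
  cls <- NA_integer_
  if (nzchar(m[3])) {
    if (!nzchar(m[5]) || m[3] != m[5]) {
      stop("relation key must stay within one class: ", key, call. = FALSE)
    }
    cls <- as.integer(m[3])
  } else if (nzchar(m[5])) {
    stop("malformed relation key: ", key, call. = FALSE)
  }
  list(source = m[2], target = m[4], class_index = cls)
}

#' Categorize a directed relation
#'
#' Labels a directed role pair the way the equivalence literature does:
#' `baseline` for a trained relation, `symmetry` for the reverse of a trained
#' relation, `transitivity` for an untrained pair probed in the trained
#' direction (earlier role as sample), and `combined` (equivalence) for the
#' reverse. Nodal distance is attached for the last two.
#'
#' @param structure An `eq_structure`.
#' @param source,target Role names.
#' @return Character scalar with attribute `"distance"`.
#' @export
relation_category <- function(structure, source, target) {
  trained <- vapply(structure$trained_relations, paste, "", collapse = "")
  key <- paste0(source, target)
  rev_key <- paste0(target, source)
  d <- nodal_distance(structure, source, target)
  cat <- if (key %in% trained) {
    "baseline"
  } else if (rev_key %in% trained) {
    "symmetry"
  } else if (match(source, structure$roles) < match(target, structure$roles)) {
    "transitivity"
  } else {
    "combined"
  }
  structure(cat, distance = d)
}
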