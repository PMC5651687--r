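#' Canonical replication protocols
#'
#' Builds the staged protocol specification for each of the packaged
#' replications:
#'
#' * `"sim1"` — a single 3-member class (with same-role distractor units from
#'   two further classes) trained on A1B1 then B1C1, one trial each per epoch,
#'   for 30 epochs (60 trials, no mastery criterion). Tracks the A1B1, B1C1
#'   and derived A1C1 weights after every epoch.
#' * `"sidman1982"` — three 4-member classes (roles A-D), baseline relations
#'   AB, AC and DC introduced over staged mixed blocks with 19/20, 29/30 and
#'   finally 44/45 criteria, followed by one unreinforced test block holding
#'   every baseline relation plus the derived DB, BD, AD, BC, CB and CD
#'   relations once each.
#' * `"devany1986"` — two 3-member classes (roles A-C), one-to-many baseline
#'   (AB, AC), two-choice trials. Variants: `"typical"` (default parameters),
#'   `"learning_disability"` (theta 0.72, beta 0.1), and
#'   `"interference_avoidance"` (learning-disability parameters, but each AB
#'   relation is trained alone for 45 trials before 30 mixed AB/AC trials, the
#'   schedule under which derived transitivity survives the raised threshold).
#' * `"spencer1996"` — three 7-member classes in linear series (AB..FG),
#'   trained over six 48-trial stages with 90% criteria and per-relation
#'   maintenance counts, an unreinforced 18-trial baseline-maintenance stage
#'   at 90%, then a 126-trial test block covering all baseline, symmetry,
#'   transitivity and combined relations. Variant `"equal_trials"` replaces
#'   the staged schedule with 65 reinforced trials of each relation set,
#'   interleaved-shuffled, before the same test block.
#'
#' @param study One of `"sim1"`, `"sidman1982"`, `"devany1986"`,
#'   `"spencer1996"`.
#' @param variant Study-specific variant (see above); `"default"` maps to the
#'   study's standard schedule and parameters.
#' @param params Optional [eq_params()] override; by default each
#'   study/variant carries its published parameter set.
#' @return An [protocol_spec()] object.
#' @examples
#' make_protocol("devany1986", "learning_disability")$params$theta  # 0.72
#' @export
make_protocol <- function(study = c("sim1", "sidman1982", "devany1986",
                                    "spencer1996"),
                          variant = "default", params = NULL) {
  study <- match.arg(study)
  switch(study,
         sim1 = .protocol_sim1(variant, params),
         sidman1982 = .protocol_sidman(variant, params),
         devany1986 = .protocol_devany(variant, params),
         spencer1996 = .protocol_spencer(variant, params))
}

#' List packaged protocol fixtures
#'
#' @return Data frame of study/variant combinations understood by
#'   [make_protocol()], with the fixture file shipped under
#'   `system.file("protocols", package = "eqsim")`.
#' @export
list_protocols <- function() {
  data.frame(
    study = c("sim1", "sidman1982", "devany1986", "devany1986", "devany1986",
              "spencer1996", "spencer1996"),
    variant = c("default", "default", "typical", "learning_disability",
                "interference_avoidance", "default", "equal_trials"),
    fixture = c("sim1.yaml", "sidman1982.yaml", "devany1986-typical.yaml",
                "devany1986-learning_disability.yaml",
                "devany1986-interference_avoidance.yaml",
                "spencer1996.yaml", "spencer1996-equal_trials.yaml"),
    stringsAsFactors = FALSE
  )
}

.check_variant <- function(study, variant, allowed) {
  if (!variant %in% allowed) {
    stop("unknown variant '", variant, "' for study '", study, "' (use ",
         paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  variant
}

.protocol_sim1 <- function(variant, params) {
  .check_variant("sim1", variant, "default")
  st <- generate_structure("linear_series", n_classes = 3, n_members = 3)
  stages <- list(
    stage_spec("AB-BC training",
               c(A1B1 = 1, B1C1 = 1),
               phase = "train", criterion = NULL, shuffle = FALSE,
               n_blocks = 30L)
  )
  protocol_spec("sim1", st, stages,
                params = params %||% eq_params(),
                tracked_pairs = list(c("A1", "B1"), c("B1", "C1"),
                                     c("A1", "C1")))
}

.protocol_sidman <- function(variant, params) {
  .check_variant("sidman1982", variant, "default")
  st <- class_structure(3, 4, c("AB", "AC", "DC"))
  pairwise <- function(prefix, a, b) {
    stage_spec(paste0(prefix, ": ", a, ", ", b),
               stats::setNames(c(10L, 10L), c(a, b)),
               phase = "train", criterion = "19/20")
  }
  trio <- function(prefix, rels, n_each, crit) {
    stage_spec(prefix,
               stats::setNames(rep(n_each, length(rels)), rels),
               phase = "train", criterion = crit)
  }
  ab <- c("A1B1", "A2B2", "A3B3")
  ac <- c("A1C1", "A2C2", "A3C3")
  dc <- c("D1C1", "D2C2", "D3C3")
  test_rels <- c(ab, ac, dc,
                 paste0("D", 1:3, "B", 1:3), paste0("B", 1:3, "D", 1:3),
                 paste0("A", 1:3, "D", 1:3), paste0("B", 1:3, "C", 1:3),
                 paste0("C", 1:3, "B", 1:3), paste0("C", 1:3, "D", 1:3))
  stages <- list(
    pairwise("AB", "A1B1", "A2B2"),
    pairwise("AB", "A1B1", "A3B3"),
    pairwise("AB", "A2B2", "A3B3"),
    trio("AB: all classes", ab, 10L, "29/30"),
    pairwise("AC", "A1C1", "A2C2"),
    pairwise("AC", "A1C1", "A3C3"),
    pairwise("AC", "A2C2", "A3C3"),
    trio("AC: all classes", ac, 10L, "29/30"),
    trio("AB and AC mixed", c(ab, ac), 5L, "29/30"),
    pairwise("DC", "D1C1", "D2C2"),
    pairwise("DC", "D1C1", "D3C3"),
    pairwise("DC", "D2C2", "D3C3"),
    trio("DC: all classes", dc, 10L, "29/30"),
    trio("AB, AC and DC mixed", c(ab, ac, dc), 5L, "44/45"),
    stage_spec("equivalence test",
               stats::setNames(rep(1L, length(test_rels)), test_rels),
               phase = "test", criterion = NULL)
  )
  protocol_spec("sidman1982", st, stages, params = params %||% eq_params(),
                tracked_pairs = list(c("A1", "B1"), c("B1", "D1"),
                                     c("B1", "C1"), c("A1", "D1")))
}

.protocol_devany <- function(variant, params) {
  variant <- if (identical(variant, "default")) "typical" else variant
  .check_variant("devany1986", variant,
                 c("typical", "learning_disability", "interference_avoidance"))
  st <- class_structure(2, 3, c("AB", "AC"))
  default_params <- switch(variant,
                           typical = eq_params(),
                           eq_params_ld())
  test_stage <- stage_spec(
    "transitivity test",
    c(B1C1 = 1, C1B1 = 1, B2C2 = 1, C2B2 = 1),
    phase = "test", criterion = NULL
  )
  if (variant == "interference_avoidance") {
    stages <- list(
      stage_spec("A1B1 alone", c(A1B1 = 45L), phase = "train",
                 criterion = NULL, shuffle = FALSE),
      stage_spec("A2B2 alone", c(A2B2 = 45L), phase = "train",
                 criterion = NULL, shuffle = FALSE),
      stage_spec("AB and AC mixed", c(AB = 15L, AC = 15L), phase = "train",
                 criterion = NULL),
      test_stage
    )
  } else {
    single <- function(rel) {
      stage_spec(rel, stats::setNames(10L, rel), phase = "train",
                 criterion = "9/10", shuffle = FALSE)
    }
    stages <- list(
      single("A1B1"),
      single("A2B2"),
      stage_spec("A1B1, A2B2", c(A1B1 = 5L, A2B2 = 5L), phase = "train",
                 criterion = "9/10"),
      single("A1C1"),
      single("A2C2"),
      stage_spec("A1C1, A2C2", c(A1C1 = 5L, A2C2 = 5L), phase = "train",
                 criterion = "9/10"),
      stage_spec("all relations mixed",
                 c(A1B1 = 2L, A2B2 = 2L, A1C1 = 2L, A2C2 = 2L),
                 phase = "train", criterion = "7/8"),
      stage_spec("maintenance without reinforcement",
                 c(A1B1 = 2L, A2B2 = 2L, A1C1 = 2L, A2C2 = 2L),
                 phase = "test", criterion = "8/8"),
      test_stage
    )
  }
  protocol_spec(paste0("devany1986-", variant), st, stages,
                params = params %||% default_params,
                tracked_pairs = list(c("A1", "B1"), c("A1", "C1"),
                                     c("B1", "C1"), c("B2", "C2")))
}

.spencer_test_stage <- function() {
  roles <- LETTERS[1:7]
  baseline <- paste0(roles[-7], roles[-1])
  symmetry <- paste0(roles[-1], roles[-7])
  transitivity <- character()
  combined <- character()
  for (i in 1:6) {
    for (j in (i + 1):7) {
      if (j - i >= 2) {
        transitivity <- c(transitivity, paste0(roles[i], roles[j]))
        combined <- c(combined, paste0(roles[j], roles[i]))
      }
    }
  }
  rels <- c(baseline, symmetry, transitivity, combined)
  per_class <- 3L  # one trial per relation per class -> 126 trials
  stage_spec("equivalence test",
             stats::setNames(rep(per_class, length(rels)), rels),
             phase = "test", criterion = NULL)
}

.protocol_spencer <- function(variant, params) {
  .check_variant("spencer1996", variant, c("default", "equal_trials"))
  st <- generate_structure("linear_series", n_classes = 3, n_members = 7)
  crit90 <- function(n) paste0(ceiling(0.9 * n), "/", n)
  if (variant == "equal_trials") {
    # 65 reinforced trials of each of the 18 class-specific baseline
    # relations, run as 65 shuffled passes so frequency stays equal
    # throughout; final weights are read directly after training.
    pats <- as.vector(vapply(seq_len(3), function(cl) {
      vapply(seq_len(6), function(i) {
        paste0(st$roles[i], cl, st$roles[i + 1], cl)
      }, "")
    }, character(6)))
    stages <- list(
      stage_spec("equal trials per relation",
                 stats::setNames(rep(1L, length(pats)), pats),
                 phase = "train", criterion = NULL, shuffle = TRUE,
                 n_blocks = 65L)
    )
  } else {
    counts <- list(
      `1. AB` = c(AB = 48L),
      `2. BC` = c(AB = 24L, BC = 24L),
      `3. CD` = c(AB = 12L, BC = 12L, CD = 24L),
      `4. DE` = c(AB = 8L, BC = 8L, CD = 8L, DE = 24L),
      `5. EF` = c(AB = 6L, BC = 6L, CD = 6L, DE = 6L, EF = 24L),
      `6. FG` = c(AB = 3L, BC = 3L, CD = 3L, DE = 6L, EF = 9L, FG = 24L)
    )
    stages <- lapply(names(counts), function(nm) {
      stage_spec(nm, counts[[nm]], phase = "train",
                 criterion = crit90(sum(counts[[nm]])))
    })
    maint <- c(AB = 3L, BC = 3L, CD = 3L, DE = 3L, EF = 3L, FG = 3L)
    stages <- c(stages, list(
      stage_spec("7. baseline maintenance (no reinforcement)", maint,
                 phase = "test", criterion = crit90(sum(maint))),
      .spencer_test_stage()
    ))
  }
  protocol_spec(paste0("spencer1996",
                       if (variant == "equal_trials") "-equal_trials" else ""),
                st, stages, params = params %||% eq_params(),
                tracked_pairs = list(c("A1", "B1"), c("A1", "C1"),
                                     c("A1", "D1"), c("A1", "G1")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
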