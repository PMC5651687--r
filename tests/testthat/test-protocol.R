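test_that("block construction expands counts and splits set-level keys", {
  st <- class_structure(3, 4, c("AB", "AC", "DC"))
  stage <- stage_spec("AB pair", c(A1B1 = 10, A2B2 = 10), criterion = "19/20")
  set.seed(1)
  block <- build_block(stage, st)
  expect_length(block, 20)
  labels <- vapply(block, function(t) t$relation_label, "")
  expect_equal(sort(unique(labels)), c("A1B1", "A2B2"))
  expect_equal(unname(table(labels)["A1B1"]), 10, ignore_attr = TRUE)

  # set-level key: even split with seeded remainder
  stage <- stage_spec("set", c(AB = 8), criterion = NULL)
  set.seed(1)
  counts <- table(vapply(build_block(stage, st),
                         function(t) t$relation_label, ""))
  expect_equal(sum(counts), 8)
  expect_true(all(counts %in% 2:3))
})

test_that("mastery criteria evaluate block totals and consecutive runs", {
  expect_true(evaluate_criterion(c(rep(TRUE, 19), FALSE), "19/20"))
  expect_false(evaluate_criterion(c(rep(TRUE, 18), FALSE, FALSE), "19/20"))
  expect_true(evaluate_criterion(rep(TRUE, 45), "44/45"))
  # literal consecutive-run reading: C C W C C C C C C C has a best run of 7
  runs <- c(TRUE, TRUE, FALSE, rep(TRUE, 7))
  expect_false(evaluate_criterion(
    runs, list(min_correct = 9, out_of = 10, consecutive = TRUE)))
  expect_true(evaluate_criterion(
    c(FALSE, rep(TRUE, 9)),
    list(min_correct = 9, out_of = 10, consecutive = TRUE)))
  expect_true(evaluate_criterion(logical(0), NULL))
})

test_that("stages repeat to mastery, keep weights, and cap repetitions", {
  st <- class_structure(2, 3, c("AB", "AC"))
  stage <- stage_spec("A1B1", c(A1B1 = 10), criterion = "9/10",
                      shuffle = FALSE)
  p <- eq_params()
  set.seed(3)
  res <- run_stage(eq_network(structure_units(st)), stage, st, p)
  expect_true(any(res$block_log$passed))
  expect_gt(res$network$weights["A1", "B1"], 0.5)
  # weights strictly increase across repeated blocks of solo training
  if (nrow(res$block_log) > 1) {
    expect_true(all(diff(res$block_log$n_correct) >= 0))
  }

  # a test stage with no criterion runs exactly once
  tstage <- stage_spec("probe", c(B1C1 = 2), phase = "test", criterion = NULL)
  set.seed(3)
  res <- run_stage(eq_network(structure_units(st)), tstage, st, p)
  expect_equal(nrow(res$block_log), 1L)

  # beta = 0: the network can never reach criterion; error names the stage
  p0 <- eq_params(beta = 0, max_stage_repeats = 12)
  set.seed(3)
  expect_error(
    run_stage(eq_network(structure_units(st)), stage, st, p0),
    class = "eq_nonconvergence"
  )
})

test_that("protocol runs are reproducible and stage-continuous", {
  proto <- make_protocol("devany1986", "typical")
  r1 <- run_protocol(proto, seed = 17)
  r2 <- run_protocol(proto, seed = 17)
  expect_identical(r1$final_network$weights, r2$final_network$weights)
  expect_identical(r1$trial_log, r2$trial_log)

  # weight state persists across stages: later stages start from trained state
  first_block <- r1$trial_log[r1$trial_log$stage == "A1C1", ]
  expect_true(mean(first_block$is_correct) > 0.5)

  # trajectory has one row per completed block
  expect_equal(nrow(r1$trajectory), nrow(r1$stage_log))
})

test_that("test stages change any weight by at most beta/4 per trial", {
  proto <- make_protocol("devany1986", "typical")
  run <- run_protocol(proto, seed = 4)
  cap <- proto$params$beta * proto$params$test_beta_fraction
  # rebuild the final test stage transitions trial by trial
  net <- run$final_network
  p <- proto$params
  set.seed(101)
  w0 <- net$weights
  res <- run_trial(net, trial_spec("B1", c("C1", "C2"), "C1", phase = "test"),
                   p)
  expect_lte(max(abs(res$network$weights - w0)), cap + 1e-12)
})

test_that("one vs three consecutive test blocks barely moves derived weights", {
  st <- class_structure(3, 4, c("AB", "AC", "DC"))
  base <- make_protocol("sidman1982")
  one <- run_protocol(base, seed = 8)
  test_stage <- base$stages[[length(base$stages)]]
  three <- protocol_spec("sidman-3tests", st,
                         c(base$stages, list(test_stage, test_stage)),
                         params = base$params,
                         tracked_pairs = base$tracked_pairs)
  r3 <- run_protocol(three, seed = 8)
  derived <- rbind(c("B1", "D1"), c("B2", "D2"), c("A1", "D1"),
                   c("B1", "C1"), c("C3", "D3"))
  for (i in seq_len(nrow(derived))) {
    d <- abs(one$final_network$weights[derived[i, 1], derived[i, 2]] -
             r3$final_network$weights[derived[i, 1], derived[i, 2]])
    expect_lt(d, 0.05)
  }
})

test_that("an empty stage list returns a naive final state", {
  st <- class_structure(2, 3, c("AB", "AC"))
  proto <- protocol_spec("empty", st, list())
  run <- run_protocol(proto, seed = 1)
  expect_true(all(run$final_network$weights == 0))
  expect_equal(nrow(run$trajectory), 0)
})
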