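test_that("comparison selection takes the argmax of raw sample weights", {
  net <- eq_network(c("A1", "B1", "B2", "B3"))
  net$weights["A1", "B1"] <- net$weights["B1", "A1"] <- 0.5
  expect_identical(as.character(select_comparison(net, "A1", c("B1", "B2", "B3"))),
                   "B1")
  expect_error(select_comparison(net, "A1", character()), "empty")
})

test_that("ties are broken uniformly and negative weights are avoided", {
  net <- eq_network(c("A1", "B1", "B2", "B3"))
  set.seed(11)
  picks <- replicate(6000, as.character(
    select_comparison(net, "A1", c("B1", "B2", "B3"))))
  freq <- table(picks) / length(picks)
  expect_true(all(abs(freq - 1 / 3) < 0.02))

  net$weights["A1", "B2"] <- net$weights["B2", "A1"] <- -0.2
  picks <- replicate(2000, as.character(
    select_comparison(net, "A1", c("B1", "B2", "B3"))))
  expect_false("B2" %in% picks)
  expect_true(all(abs(table(picks) / length(picks) - 0.5) < 0.05))
})

test_that("a trial runs clamp-select-spread-feedback-update in order", {
  p <- eq_params()
  # correct chance pick strengthens the sample-chosen pair to +beta
  net <- eq_network(c("A1", "B1", "B2", "B3"))
  set.seed(2)
  repeat {
    res <- run_trial(eq_network(c("A1", "B1", "B2", "B3")),
                     trial_spec("A1", c("B1", "B2", "B3"), "B1"), p)
    if (res$outcome$is_correct) break
  }
  expect_equal(res$network$weights["A1", "B1"], 0.2)

  # incorrect pick drives the chosen pair negative, correct pair untouched
  repeat {
    res <- run_trial(eq_network(c("A1", "B1", "B2", "B3")),
                     trial_spec("A1", c("B1", "B2", "B3"), "B1"), p)
    if (res$outcome$chosen == "B2") break
  }
  expect_equal(res$network$weights["A1", "B2"], -0.2)
  expect_equal(res$network$weights["A1", "B1"], 0)

  # test phase: beta/4, always-positive sign
  net <- eq_network(c("C1", "A1", "A2", "A3"))
  net$weights["C1", "A1"] <- net$weights["A1", "C1"] <- 0.9
  res <- run_trial(net, trial_spec("C1", c("A1", "A2", "A3"), "A1",
                                   phase = "test"), p)
  expect_identical(res$outcome$chosen, "A1")
  expect_equal(res$network$weights["C1", "A1"], 0.9 + 0.05 * (1 - 0.9),
               tolerance = 1e-12)
})

test_that("losing comparisons are excluded from spreading for the whole trial", {
  p <- eq_params()
  net <- eq_network(c("A1", "B1", "B2"))
  # B2 would be driven hard by the winner if it were allowed to spread
  net$weights["A1", "B1"] <- net$weights["B1", "A1"] <- 0.5
  net$weights["B1", "B2"] <- net$weights["B2", "B1"] <- 0.99
  res <- run_trial(net, trial_spec("A1", c("B1", "B2"), "B1"), p)
  expect_equal(res$outcome$active_units[["A1"]], 1)
  expect_false("B2" %in% names(res$outcome$active_units))
})

test_that("correct trials never weaken and wrong trials never strengthen the chosen pair", {
  p <- eq_params()
  net <- eq_network(c("A1", "B1", "B2"))
  set.seed(5)
  tr <- trial_spec("A1", c("B1", "B2"), "B1")
  for (i in 1:60) {
    before <- net$weights["A1", "B1"]
    res <- run_trial(net, tr, p)
    after <- res$network$weights["A1", res$outcome$chosen]
    prior <- net$weights["A1", res$outcome$chosen]
    if (res$outcome$is_correct) expect_gte(after, prior)
    else expect_lte(after, prior)
    net <- res$network
  }
})

test_that("a naive network responds at chance level", {
  p <- eq_params(beta = 0)  # frozen weights keep every trial naive
  net <- eq_network(c("A1", "B1", "B2", "B3"))
  tr <- trial_spec("A1", c("B1", "B2", "B3"), "B1")
  set.seed(123)
  correct <- replicate(1500, run_trial(net, tr, p)$outcome$is_correct)
  test <- stats::chisq.test(table(correct), p = c(2 / 3, 1 / 3))
  expect_gt(test$p.value, 0.001)
})

test_that("identical seeds give bitwise-identical outcome sequences", {
  p <- eq_params()
  run_once <- function(seed) {
    set.seed(seed)
    net <- eq_network(c("A1", "B1", "B2", "C1", "C2"))
    out <- character()
    for (i in 1:40) {
      tr <- if (i %% 2) trial_spec("A1", c("B1", "B2"), "B1")
            else trial_spec("B1", c("C1", "C2"), "C1")
      res <- run_trial(net, tr, p)
      net <- res$network
      out <- c(out, res$outcome$chosen)
    }
    list(choices = out, weights = net$weights)
  }
  a <- run_once(99)
  b <- run_once(99)
  expect_identical(a$choices, b$choices)
  expect_identical(a$weights, b$weights)
})
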