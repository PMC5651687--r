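test_that("gated sigmoid is zero at or below the gate and logistic above it", {
  p <- eq_params()
  expect_identical(gated_sigmoid(0, p), 0)
  expect_identical(gated_sigmoid(0.85, p), 0)  # gate is a strict inequality
  expect_equal(gated_sigmoid(1, p), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(gated_sigmoid(c(-2, 0.86, 5), p),
               c(0, 1 / (1 + exp(-0.86)), 1 / (1 + exp(-5))),
               tolerance = 1e-12)
})

test_that("net inputs sum weighted contributions over all source units", {
  net <- eq_network(c("A1", "B1", "C1"))
  expect_equal(unname(net_inputs(net, "A1")), c(0, 0))

  net$weights["A1", "B1"] <- net$weights["B1", "A1"] <- 0.9
  net$activations["A1"] <- 1
  expect_equal(net_inputs(net, "A1")[["B1"]], 0.9)

  net$weights["C1", "B1"] <- net$weights["B1", "C1"] <- 0.75
  net$weights["A1", "B1"] <- net$weights["B1", "A1"] <- 0.95
  net$activations["C1"] <- 1
  expect_equal(net_inputs(net, c("A1", "C1"))[["B1"]], 1.70)

  expect_error(net_inputs(net, "Z9"), "unknown unit")
})

test_that("spreading activates only units driven past the gate", {
  net <- eq_network(c("A1", "B1", "C1", "C2"))
  net <- spread_activation(net, c("A1", "B1"))
  expect_equal(unname(activations(net)),
               c(1, 1, 0, 0))

  net$weights["B1", "A1"] <- net$weights["A1", "B1"] <- 0.893
  net <- spread_activation(net, c("B1", "C1"))
  expect_equal(net$activations[["A1"]], 1 / (1 + exp(-0.893)),
               tolerance = 1e-12)
  expect_equal(net$activations[["C2"]], 0)

  net$weights["B1", "A1"] <- net$weights["A1", "B1"] <- 0.80
  net <- spread_activation(net, c("B1", "C1"))
  expect_equal(net$activations[["A1"]], 0)  # 0.80 does not exceed the gate
})

test_that("excluded units stay silent and cannot overlap the clamped set", {
  net <- eq_network(c("A1", "B1", "B2"))
  net$weights["A1", "B2"] <- net$weights["B2", "A1"] <- 0.95
  net <- spread_activation(net, "A1", excluded_units = "B2")
  expect_equal(net$activations[["B2"]], 0)
  expect_error(spread_activation(net, "A1", excluded_units = "A1"), "overlap")
})

test_that("fixpoint propagation iterates waves without touching clamped units", {
  p <- eq_params(propagation = "fixpoint")
  net <- eq_network(c("A", "B", "C"))
  net$weights["A", "B"] <- net$weights["B", "A"] <- 0.9
  net$weights["B", "C"] <- net$weights["C", "B"] <- 2  # forced for the test
  single <- spread_activation(net, "A", params = eq_params())
  expect_equal(single$activations[["C"]], 0)  # one wave cannot reach C

  net <- spread_activation(net, "A", params = p)
  # independent oracle: iterate the two-unit map directly
  sig <- function(z) ifelse(z > 0.85, 1 / (1 + exp(-z)), 0)
  xb <- xc <- 0
  repeat {
    xb2 <- sig(0.9 * 1 + 2 * xc)
    xc2 <- sig(2 * xb)
    if (max(abs(c(xb2 - xb, xc2 - xc))) <= 1e-9) break
    xb <- xb2; xc <- xc2
  }
  expect_equal(net$activations[["B"]], xb2, tolerance = 1e-6)
  expect_equal(net$activations[["C"]], xc2, tolerance = 1e-6)
  expect_equal(net$activations[["A"]], 1)
  expect_gt(net$activations[["B"]], single$activations[["B"]])
})

test_that("pair update follows the threshold-split self-adapting rule", {
  p <- eq_params()
  u <- pair_update(0, 1, +1, "train", p)
  expect_equal(u$lambda_value, 1)
  expect_equal(u$delta_w, 0.2)

  u <- pair_update(0.5, 0.6, +1, "train", p)  # below theta: decay branch
  expect_equal(u$lambda_value, -0.5)
  expect_equal(u$delta_w, -0.025)

  u <- pair_update(0, 1, -1, "train", p)  # incorrect response
  expect_equal(u$delta_w, -0.2)

  # decay is not flipped by negative feedback
  u <- pair_update(0.5, 0.6, -1, "train", p)
  expect_equal(u$delta_w, -0.025)

  # test phase: beta/4 and no feedback sign
  u <- pair_update(0.9, 1, -1, "test", p)
  expect_equal(u$delta_w, 0.05 * (1 - 0.9), tolerance = 1e-12)

  expect_error(pair_update(0, 1.2, 1, "train", p))
})

test_that("apply_updates touches exactly the eligible pairs, synchronously", {
  p <- eq_params()
  net <- eq_network(c("A1", "B1", "C1"))
  # nothing active: no change
  net2 <- apply_updates(net, 1, "train", p)
  expect_identical(net2$weights, net$weights)

  # single clamped pair
  net$activations[c("A1", "B1")] <- 1
  net2 <- apply_updates(net, 1, "train", p, record = TRUE)
  expect_equal(net2$weights["A1", "B1"], 0.2)
  expect_equal(net2$weights["A1", "C1"], 0)
  expect_equal(nrow(attr(net2, "updates")), 1L)

  # three active units: all three pairwise products updated from W(t)
  net$weights["A1", "B1"] <- net$weights["B1", "A1"] <- 0.5
  x <- 0.7095
  net$activations[] <- c(x, 1, 1)
  net2 <- apply_updates(net, 1, "train", p, record = TRUE)
  expect_equal(net2$weights["B1", "C1"], 0.2 * 1)          # lambda = 1 - 0
  expect_equal(net2$weights["A1", "B1"], 0.5 + 0.2 * (x - 0.5))
  expect_equal(net2$weights["A1", "C1"], 0.2 * x)
  expect_equal(nrow(attr(net2, "updates")), 3L)
  expect_symmetric_bounded(net2, p)
})

test_that("one_active eligibility decays connections of silent partners", {
  p <- eq_params(pair_eligibility = "one_active")
  net <- eq_network(c("A1", "B1", "C1"))
  net$weights["A1", "C1"] <- net$weights["C1", "A1"] <- 0.8
  net$activations[c("A1", "B1")] <- 1
  net2 <- apply_updates(net, 1, "train", p)
  # A1 active, C1 silent: coactivation 0 < theta, decay by 0.25 * beta * W
  expect_equal(net2$weights["A1", "C1"], 0.8 - 0.25 * 0.2 * 0.8)
  expect_equal(net2$weights["A1", "B1"], 0.2)
})

test_that("engine matches the solo-training closed form to 1e-12", {
  for (beta in c(0.05, 0.1, 0.2, 0.5, 0.9)) {
    p <- eq_params(beta = beta)
    net <- eq_network(c("S", "C"))
    tr <- trial_spec("S", "C", "C")
    w_prev <- 0
    for (t in 1:200) {
      net <- run_trial(net, tr, p)$network
      w <- net$weights["S", "C"]
      expect_equal(w, solo_weight(t, beta), tolerance = 1e-12)
      if (solo_weight(t, beta) < 1 - 1e-12) {
        expect_gt(w, w_prev)  # strictly increasing, bounded by 1
        expect_lt(w, 1)
      }
      w_prev <- w
    }
  }
  # the learning-disability further-simulation value: 0.99 after 45 trials
  expect_equal(round(solo_train(45, eq_params(beta = 0.1, theta = 0.72)), 2),
               0.99)
})

test_that("zero learning rate freezes all weights regardless of feedback", {
  p <- eq_params(beta = 0)
  net <- eq_network(c("A1", "B1", "B2"))
  set.seed(42)
  tr <- trial_spec("A1", c("B1", "B2"), "B1")
  for (i in 1:50) net <- run_trial(net, tr, p)$network
  expect_true(all(net$weights == 0))
  net2 <- apply_updates({
    net$activations[c("A1", "B1")] <- 1
    net
  }, -1, "train", p)
  expect_true(all(net2$weights == 0))
})

test_that("a pair receiving only sub-threshold events decays geometrically", {
  p <- eq_params()
  w <- 0.8
  ratio <- 1 - p$decay_multiplier * p$beta
  for (k in 1:60) {
    w <- w + pair_update(w, 0.3, 1, "train", p)$delta_w
    expect_equal(w, 0.8 * ratio^k, tolerance = 1e-12)
  }
  expect_lt(w, 0.05)
})

test_that("weights stay symmetric, bounded and zero-diagonal through training", {
  p <- eq_params()
  net <- eq_network(c("A1", "B1", "B2", "C1", "C2"))
  set.seed(7)
  trials <- list(
    trial_spec("A1", c("B1", "B2"), "B1"),
    trial_spec("B1", c("C1", "C2"), "C1"),
    trial_spec("C1", c("A1", "B2"), "A1", phase = "test")
  )
  for (i in 1:120) {
    net <- run_trial(net, trials[[(i %% 3) + 1]], p)$network
    expect_symmetric_bounded(net, p)
  }
})
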