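test_that("steady state matches hand-solved linear systems", {
  # chain A -> B with w(B,A) = 1, seed A: r = (1, 1)
  chain <- connectome(toy_edges(list("A", "B", 5)))
  r <- steady_state_activity(build_weight_matrix(chain), "A")
  expect_equal(unname(r[c("A", "B")]), c(1, 1))

  # two-cell cycle rescaled to 0.99, seed A:
  # r_A - 0.99 r_B = 1, r_B = 0.99 r_A  =>  r_A = 1/(1 - 0.99^2)
  wmr <- rescale_to_stability(build_weight_matrix(cycle_connectome()))
  r2 <- steady_state_activity(wmr, "A")
  expect_equal(unname(r2["A"]), 50.2513, tolerance = 1e-3)
  expect_equal(unname(r2["B"]), 49.7488, tolerance = 1e-3)

  # empty seed set: the zero response
  expect_true(all(steady_state_activity(wmr, character(0)) == 0))
})

test_that("steady state agrees with forward integration of the rate ODE", {
  skip_if_not_installed("deSolve")
  cn <- random_cyclic_connectome(n = 50, p = 0.12, seed = 11)
  wmr <- rescale_to_stability(build_weight_matrix(cn))
  seeds <- wmr$order[1:3]
  r_direct <- steady_state_activity(wmr, seeds)

  W <- as.matrix(wmr$W)
  s <- as.numeric(wmr$order %in% seeds)
  tau <- 1
  # the slowest mode relaxes with time constant tau / (1 - 0.99), so the
  # horizon must cover many multiples of 100 tau to reach 1e-4
  deriv <- function(t, r, parms) list((-r + W %*% r + s) / tau)
  sol <- deSolve::ode(y = numeric(length(s)), times = c(0, 2000 * tau),
                      func = deriv, parms = NULL)
  r_ode <- sol[nrow(sol), -1]
  denom <- pmax(abs(r_direct), 1e-12)
  expect_lt(max(abs(r_ode - r_direct) / denom), 1e-4)
})

test_that("adjusted influence applies the log-offset with a floor at zero", {
  expect_equal(adjusted_influence(exp(-24)), 0)
  expect_equal(adjusted_influence(exp(-10)), 14)
  expect_equal(adjusted_influence(0), 0)
  expect_equal(adjusted_influence(exp(-30)), 0)  # below the floor
  expect_equal(adjusted_influence(c(0, exp(-10), exp(2))), c(0, 14, 26))
  expect_error(adjusted_influence(-1), "nonnegative")
  # default offset is the documented constant
  expect_equal(formals(adjusted_influence)$offset, 24)
})

test_that("superposition: multi-seed response equals the sum of single-seed responses", {
  cn <- random_cyclic_connectome(n = 30, p = 0.15, seed = 3)
  wmr <- rescale_to_stability(build_weight_matrix(cn))
  seeds <- wmr$order[c(2, 5, 9)]
  r_multi <- steady_state_activity(wmr, seeds)
  r_sum <- Reduce(`+`, lapply(seeds, function(s) steady_state_activity(wmr, s)))
  expect_lt(max(abs(r_multi - r_sum)), 1e-9)
})

test_that("per-seed-average and simultaneous pooled influence agree by linearity", {
  cn <- random_cyclic_connectome(n = 30, p = 0.15, seed = 4)
  wmr <- rescale_to_stability(build_weight_matrix(cn))
  seeds <- wmr$order[1:4]
  targets <- wmr$order[10:20]
  a <- pooled_influence(wmr, seeds, targets, mode = "simultaneous")
  b <- pooled_influence(wmr, seeds, targets, mode = "per-seed-average")
  expect_equal(a$mean_activity, b$mean_activity, tolerance = 1e-9)
  expect_equal(a$adjusted, b$adjusted, tolerance = 1e-9)

  # doubling the seed vector doubles the pooled mean, adding log 2 on the
  # log scale (linearity of the steady state in the stimulation vector)
  expect_equal(adjusted_influence(2 * a$mean_activity),
               a$adjusted + log(2), tolerance = 1e-12)
  expect_error(pooled_influence(wmr, seeds, character(0)), "empty")
})

test_that("seed targets are excluded from pool means unless opted in", {
  cn <- random_cyclic_connectome(n = 20, p = 0.2, seed = 5)
  wmr <- rescale_to_stability(build_weight_matrix(cn))
  seeds <- wmr$order[1:2]
  targets <- wmr$order[1:10]  # overlaps the seeds
  res <- pooled_influence(wmr, seeds, targets)
  expect_setequal(res$excluded_seed_targets, seeds)
  expect_setequal(res$targets_used, setdiff(targets, seeds))
  res_in <- pooled_influence(wmr, seeds, targets, include_seed_targets = TRUE)
  expect_setequal(res_in$targets_used, targets)
  expect_gt(res_in$mean_activity, res$mean_activity)  # self-drive dominates

  # isolated cell as its own seed and target: positive self response
  iso <- connectome(toy_edges(list("X", "Y", 1)),
                    cells = tibble::tibble(id = c("X", "Y", "Z")))
  wmi <- build_weight_matrix(iso)
  expect_message(self <- pooled_influence(wmi, "Z", "Z"), "including seed")
  expect_gt(self$seed_activity[["Z"]], 0)
  # a target with no path from the seed floors at adjusted 0
  far <- pooled_influence(wmi, "Z", "X")
  expect_equal(far$adjusted, 0)
})

test_that("influence_matrix batches pooled influence and minmax-normalises rows", {
  cn <- random_cyclic_connectome(n = 30, p = 0.15, seed = 6)
  wmr <- rescale_to_stability(build_weight_matrix(cn))
  seeds <- list(g1 = wmr$order[1:3])
  targets <- list(h1 = wmr$order[10:15])
  m <- influence_matrix(wmr, seeds, targets)
  ref <- pooled_influence(wmr, seeds$g1, targets$h1)
  expect_equal(unname(m[1, 1]), ref$adjusted, tolerance = 1e-12)

  raw <- matrix(c(2, 4, 6), 1)
  expect_equal(circuitflow:::minmax_scale(raw[1, ]), c(0, 0.5, 1))
  expect_equal(circuitflow:::minmax_scale(c(3, 3, 3)), c(0, 0, 0))

  # overlapping seed/target groups are reported, not dropped
  m2 <- influence_matrix(wmr, list(g = wmr$order[1:3]),
                         list(h = wmr$order[2:5]))
  expect_named(attr(m2, "overlaps"), "g->h")
})

test_that("direct flags follow the edge list", {
  cn <- connectome(toy_edges(list("A", "B", 1), list("B", "C", 1)))
  wm <- build_weight_matrix(cn)
  flags <- direct_targets(wm, "A")
  expect_true(flags[["B"]])
  expect_false(flags[["C"]])
  expect_false(flags[["A"]])
})

test_that("no adjusted score is negative on any random network", {
  for (seed in 1:5) {
    cn <- random_cyclic_connectome(n = 25, p = 0.1, seed = seed)
    wmr <- rescale_to_stability(build_weight_matrix(cn))
    r <- steady_state_activity(wmr, wmr$order[1])
    expect_true(all(adjusted_influence(r) >= 0))
  }
})

test_that("body-part counting applies the high-influence cutoff", {
  effectors <- tibble::tibble(
    id = c("legA", "wingB", "legC", "mysteryD"),
    body_part_effector = c("leg", "wing", "leg", NA)
  )
  scores <- tibble::tibble(
    seed = c("s1", "s1", "s1", "s1", "s2", "s2"),
    target = c("legA", "wingB", "legC", "mysteryD", "legA", "wingB"),
    adjusted = c(18, 17, 19.5, 30, 12, 11)
  )
  out <- count_influenced_body_parts(scores, effectors)
  expect_equal(out$n_body_parts[out$seed == "s1"], 1L)  # wing at 17 < 17.18
  expect_equal(out$combination[out$seed == "s1"], "leg")
  expect_equal(out$n_body_parts[out$seed == "s2"], 0L)
  expect_equal(out$combination[out$seed == "s2"], "")
  expect_equal(attr(out, "n_missing_body_part"), 1L)

  # two effectors of the same part count once; default cutoff is 17.18
  expect_equal(formals(count_influenced_body_parts)$cutoff, 17.18)
  multi <- count_influenced_body_parts(
    tibble::tibble(seed = "s", target = c("legA", "legC"), adjusted = c(20, 21)),
    effectors
  )
  expect_equal(multi$n_body_parts, 1L)
})
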