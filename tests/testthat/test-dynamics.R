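# Public-goods payoffs, exact joint chains, stationary analysis, traces and
# Monte-Carlo simulation.

test_that("the three-person payoff matrix is reproduced for any rho", {
  for (rho in seq(1.1, 2.9, length.out = 10)) {
    m <- payoff_model(3, rho)
    # columns: number of defectors among the two co-players
    expect_equal(payoff(0L, 0, m), rho)
    expect_equal(payoff(0L, 1, m), 2 * rho / 3)
    expect_equal(payoff(0L, 2, m), rho / 3)
    expect_equal(payoff(1L, 0, m), 1 + 2 * rho / 3)
    expect_equal(payoff(1L, 1, m), 1 + rho / 3)
    expect_equal(payoff(1L, 2, m), 1)      # full defection, rho-independent
  }
  expect_equal(payoff(0L, 1, payoff_model(3, 1.5)), 1.0)
  expect_error(payoff(1L, 3, payoff_model(3, 1.5)), "defector count")
  expect_error(payoff_model(3, 3.5), "rho")
})

test_that("payoff differences equal defection-indicator differences", {
  for (n in 2:3) {
    for (rho in seq(1.05, n - 0.05, length.out = 10)) {
      model <- payoff_model(n, rho)
      for (r in 0:(2^n - 1)) {
        acts <- as.integer(intToBits(r))[n:1]
        pays <- vapply(seq_len(n), function(i)
          payoff(acts[i], sum(acts[-i]), model), numeric(1))
        for (i in seq_len(n)) {
          for (j in seq_len(n)) {
            expect_equal(pays[j] - pays[i], acts[j] - acts[i])
          }
        }
      }
    }
  }
})

test_that("joint transition matrices are row-stochastic", {
  fixtures <- list(
    joint_system(list(builtin_strategy("TFT"), builtin_strategy("TFT")),
                 e = 0.01),
    joint_system(rep(list(builtin_strategy("TFT-ATFT")), 2), e = 1e-3),
    joint_system(rep(list(random_strategy(3, 2, 4)), 3), e = 0.05),
    joint_system(rep(list(fuss_automaton()), 3), e = 1e-3))
  for (sys in fixtures) {
    P <- transition_matrix(sys)
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  }
})

test_that("full cooperation is an error-free fixed point when prescribed", {
  for (nm in c("TFT", "TF2T", "WSLS", "GRIM", "ALLC", "AON2", "TFT-ATFT")) {
    s <- builtin_strategy(nm)
    sys <- joint_system(rep(list(s), 2), e = 0)
    tr <- trace_recovery(sys, list())
    expect_true(attr(tr, "recovered"))
    expect_identical(attr(tr, "recovery_round"), 1L)
  }
  # at e = 0 from full cooperation all mass stays put
  sys <- joint_system(rep(list(builtin_strategy("TFT-ATFT")), 2), e = 0)
  P <- transition_matrix(sys)
  expect_equal(P["cccc", "cccc"], 1)
})

test_that("a single error sends two TFT-ATFT players along the published path", {
  sys <- joint_system(rep(list(builtin_strategy("TFT-ATFT")), 2), e = 0)
  tr <- trace_recovery(sys, list(c(1, 1)))
  expect_identical(tr$state, c("cccc", "cdcc", "ddcd", "dcdd", "ccdc"))
  expect_true(attr(tr, "recovered"))
  expect_identical(attr(tr, "recovery_round"), 5L)
})

test_that("two TFT players at small error rates mix uniformly", {
  sys <- joint_system(rep(list(builtin_strategy("TFT")), 2), e = 1e-4)
  st <- stationary_distribution(sys)
  expect_lt(st$residual, 1e-10)
  expect_equal(unname(st$distribution), rep(0.25, 4), tolerance = 1e-3 / 0.25)
  # RANDOM-level payoffs: the four profiles are equally likely
  expect_equal(st$payoffs[1], st$payoffs[2], tolerance = 1e-6)
})

test_that("stationary analysis needs a positive error rate", {
  sys <- joint_system(rep(list(builtin_strategy("TFT")), 2), e = 0)
  expect_error(stationary_distribution(sys), "reducible")
})

test_that("two TFT-ATFT players concentrate on full cooperation", {
  sys <- joint_system(rep(list(builtin_strategy("TFT-ATFT")), 2), e = 1e-4)
  st <- stationary_distribution(sys)
  expect_gt(st$coop_mass, 0.998)
  # eleven states carry O(e) mass: the two four-step recovery excursions,
  # the mutual-defection trap and the alternating dccd/cddc exploitation
  # cycle (both entered at O(e^2) but left at O(e) rate)
  expect_equal(1 - st$coop_mass, 11e-4, tolerance = 0.01)
})

test_that("simulation is seed-reproducible and matches the exact chain", {
  sys <- joint_system(rep(list(builtin_strategy("TFT")), 2), e = 0.01,
                      rho = 1.5)
  s1 <- simulate_system(sys, 5000, seed = 11)
  s2 <- simulate_system(sys, 5000, seed = 11)
  expect_identical(s1$states, s2$states)
  expect_identical(s1$actions, s2$actions)
  rounds <- 2e5
  sim <- simulate_system(sys, rounds, seed = 3)
  st <- stationary_distribution(sys)
  # binomial standard error inflated by the chain's autocorrelation time:
  # recurrent-class dwell times are O(1/e) rounds, so the effective sample
  # size is about rounds * e
  p <- st$coop_action_freq
  se_eff <- sqrt(p * (1 - p) * (1 + 1 / sys$e) / rounds)
  expect_lt(abs(sim$coop_freq - p), 3 * se_eff)
  expect_equal(sim$mean_payoffs[1], st$payoffs[1], tolerance = 0.02)
})

test_that("error-free TFT-ATFT play from full cooperation stays cooperative", {
  sys <- joint_system(rep(list(builtin_strategy("TFT-ATFT")), 2), e = 0)
  sim <- simulate_system(sys, 1000, seed = 1)
  expect_identical(sim$coop_freq, 1)
})

test_that("incompatible player lists are rejected", {
  expect_error(joint_system(list(builtin_strategy("TFT"),
                                 builtin_strategy("TF2T")), e = 0),
               "common")
  expect_error(joint_system(list(builtin_strategy("TFT"),
                                 builtin_strategy("CTFT")), e = 0),
               "all history strategies or all")
  co_aut <- minimize(build_transition_graph(builtin_strategy("TFT")))
  expect_error(joint_system(list(co_aut, co_aut), e = 0), "full alphabet")
})
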