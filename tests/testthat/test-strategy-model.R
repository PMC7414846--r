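# History-profile coding, prescriptions and the built-in strategy library.

test_that("profile codes match the published binary labelling anchors", {
  expect_identical(encode_profile(history_profile(c("cd", "cc"))), 4L)
  expect_identical(encode_profile(history_profile(c("dd", "cc"))), 12L)
  expect_identical(encode_profile(history_profile(c("ccd", "ccd", "ccc"))), 72L)
  expect_identical(encode_profile(history_profile(c("cd", "cc", "cc"))), 16L)
  expect_identical(encode_profile(history_profile(c("ccc", "ccc", "ccc"))), 0L)
})

test_that("decode inverts encode over every code for the listed game sizes", {
  for (dims in list(c(2, 1), c(2, 2), c(2, 3), c(3, 2), c(3, 3))) {
    n <- dims[1]; m <- dims[2]
    for (code in 0:(2^(n * m) - 1)) {
      expect_identical(encode_profile(decode_profile(code, n, m)), code)
    }
  }
  expect_identical(profile_label(12, 2, 2), "ddcc")
  expect_identical(profile_label(16, 3, 2), "cdcccc")
})

test_that("out-of-range codes and malformed profiles are rejected", {
  expect_error(decode_profile(16, 2, 2), "must be an integer in")
  expect_error(decode_profile(-1, 2, 2), "must be an integer in")
  expect_error(history_profile(matrix(2L, 2, 2)), "must be 0")
  expect_error(history_strategy(2, 2, "cdcd"), "exactly")
})

test_that("prescribe reads the TFT-ATFT table of the published listing", {
  taa <- builtin_strategy("TFT-ATFT")
  # every row of the 16-entry listing, states (A_{t-2}A_{t-1}, B_{t-2}B_{t-1})
  rows <- list(
    list("cc", "cc", 0L), list("cc", "cd", 1L), list("cc", "dc", 0L),
    list("cc", "dd", 1L), list("cd", "cc", 1L), list("cd", "cd", 0L),
    list("cd", "dc", 0L), list("cd", "dd", 1L), list("dc", "cc", 0L),
    list("dc", "cd", 1L), list("dc", "dc", 0L), list("dc", "dd", 0L),
    list("dd", "cc", 1L), list("dd", "cd", 0L), list("dd", "dc", 0L),
    list("dd", "dd", 1L))
  for (r in rows) {
    expect_identical(prescribe(taa, history_profile(c(r[[1]], r[[2]]))),
                     r[[3]])
  }
  expect_error(prescribe(taa, history_profile(c("c", "d"))), "dimensions")
})

test_that("built-in tables are total, deterministic and match definitions", {
  for (nm in c("TFT", "ATFT", "WSLS", "GRIM", "ALLC", "ALLD", "TF2T",
               "AON2", "AON3", "TFT-ATFT")) {
    s <- builtin_strategy(nm)
    expect_length(s$actions, 2^(s$n * s$m))
    expect_true(all(s$actions %in% c(0L, 1L)))
  }
  expect_error(builtin_strategy("NOPE"), "unknown strategy")
  # TFT copies the co-player's last action
  tft <- builtin_strategy("TFT")
  for (code in 0:3) {
    expect_identical(prescribe(tft, code), code %% 2L)
  }
  # TF2T defects iff the co-player defected in both previous rounds
  tf2t <- builtin_strategy("TF2T")
  for (code in 0:15) {
    b <- code %% 4L
    expect_identical(prescribe(tf2t, code), as.integer(b == 3L))
  }
  # WSLS cooperates iff both last actions coincide
  wsls <- builtin_strategy("WSLS")
  for (code in 0:3) {
    expect_identical(prescribe(wsls, code),
                     as.integer(code %/% 2L != code %% 2L))
  }
  # AON2 cooperates iff both previous rounds were unanimous
  aon2 <- builtin_strategy("AON2")
  for (code in 0:15) {
    expect_identical(prescribe(aon2, code),
                     as.integer(code %/% 4L != code %% 4L))
  }
  # ALLD at any profile, including larger games
  alld <- builtin_strategy("ALLD", n = 3, m = 2)
  expect_true(all(alld$actions == 1L))
})

test_that("CTFT is a four-state standing automaton with the contrite rule", {
  ctft <- builtin_strategy("CTFT")
  expect_s3_class(ctft, "automaton")
  expect_identical(length(ctft$action), 4L)
  # defect only at good-self/bad-co-player standing ('01')
  expect_identical(ctft$action[ctft$state_names == "01"], 1L)
  expect_identical(sum(ctft$action), 1L)
  # prescribed defection at '01' keeps own standing good, while the
  # co-player's unjustified defection keeps theirs bad
  s01 <- which(ctft$state_names == "01")
  expect_identical(ctft$state_names[step_automaton(ctft, s01, c(1L, 1L))],
                   "01")
  # cooperation by both restores mutual good standing from any state
  for (s in 1:4) {
    expect_identical(ctft$state_names[step_automaton(ctft, s, c(0L, 0L))],
                     "00")
  }
})

test_that("CTFT recovers cooperation after a single error without retaliation", {
  ctft <- builtin_strategy("CTFT")
  sys <- joint_system(list(ctft, ctft), e = 0)
  tr <- trace_recovery(sys, list(c(1, 1)))
  expect_true(attr(tr, "recovered"))
  # contrition: the erring player cooperates while accepting one punishment
  expect_identical(tr$realized, c("dc", "cd"))
})

test_that("co-player permutation is an involution fixing symmetric tables", {
  s <- random_strategy(3, 2, seed = 11)
  expect_identical(permute_coplayers(s, c(1, 2))$actions, s$actions)
  swapped <- permute_coplayers(s, c(2, 1))
  expect_identical(permute_coplayers(swapped, c(2, 1))$actions, s$actions)
  # entry at a profile equals the original entry at the co-player-swapped
  # profile, so the focal player's bits of every code are preserved
  for (code in 0:63) {
    a <- code %/% 16L; b <- (code %% 16L) %/% 4L; cc <- code %% 4L
    expect_identical(swapped$actions[code + 1L],
                     s$actions[a * 16L + cc * 4L + b + 1L])
  }
  expect_error(permute_coplayers(s, c(1, 1)), "permutation")
  # a manifestly symmetric table is a fixed point: three-person all-or-none
  f <- vapply(0:63, function(code) {
    a <- code %/% 16L; b <- (code %% 16L) %/% 4L; cc <- code %% 4L
    as.integer(!(a == b && b == cc))
  }, integer(1))
  aon <- history_strategy(3, 2, f)
  expect_identical(permute_coplayers(aon, c(2, 1))$actions, aon$actions)
})

test_that("random strategies are seed-reproducible with balanced actions", {
  expect_identical(random_strategy(2, 2, 5)$actions,
                   random_strategy(2, 2, 5)$actions)
  expect_length(random_strategy(3, 3, 1)$actions, 512L)
  frac_d <- mean(vapply(1:1000, function(s)
    mean(random_strategy(2, 2, s)$actions), numeric(1)))
  expect_lt(abs(frac_d - 0.5), 0.05)
  # the caller's RNG state is untouched
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(random_strategy(2, 2, 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})
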