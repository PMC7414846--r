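# The synthetic three-person PS2 and FUSS automata: printed transitions,
# recovery paths and criteria classes.

test_that("three FUSS players reproduce the printed two-bit recovery paths", {
  sys <- joint_system(rep(list(fuss_automaton()), 3), e = 0)

  # same player (Bob) errs twice in a row
  tr5 <- trace_recovery(sys, list(c(1, 2), c(2, 2)))
  expect_identical(tr5$state, c("(0,0,0)", "(8,64,1)", "(76,64,67)"))
  expect_identical(tr5$realized, c("cdc", "ddd", "dcd"))
  expect_true(attr(tr5, "recovered"))

  # Bob errs, then Charlie errs at the next round
  tr6 <- trace_recovery(sys, list(c(1, 2), c(2, 3)))
  expect_identical(tr6$state,
                   c("(0,0,0)", "(8,64,1)", "(66,0,0)", "(64,1,8)"))
  expect_identical(tr6$realized, c("cdc", "dcc", "dcc", "cdd"))
  expect_true(attr(tr6, "recovered"))

  # Bob and Charlie err simultaneously
  tr7 <- trace_recovery(sys, list(c(1, 2), c(1, 3)))
  expect_identical(tr7$state,
                   c("(0,0,0)", "(9,72,65)", "(66,0,0)", "(64,1,8)"))
  expect_identical(tr7$realized, c("cdd", "dcc", "dcc", "cdd"))
  expect_true(attr(tr7, "recovered"))

  # a single error is absorbed in one punishment round
  tr1 <- trace_recovery(sys, list(c(1, 2)))
  expect_identical(tr1$state, c("(0,0,0)", "(8,64,1)"))
  expect_true(attr(tr1, "recovered"))
})

test_that("the FUSS fixture corrects every one- and two-bit error pattern", {
  rec <- verify_error_recovery(fuss_automaton(), 2)
  expect_true(rec$ok)
  expect_identical(rec$patterns, 15L)  # 3 single + 3 repeat + 6 ordered + 3 joint
})

test_that("the FUSS fixture satisfies all three criteria", {
  r <- classify(fuss_automaton())
  expect_identical(r$label, "successful")
  eff <- check_efficiency(fuss_automaton())
  # 1 - p(e) shrinks linearly: full efficiency, not the PS2 plateau
  expect_gt(eff$p[3], 0.99)
  expect_lt((1 - eff$p[3]) / (1 - eff$p[2]), 0.2)
})

test_that("FUSS transient apology states have no error-free incoming links", {
  fuss <- fuss_automaton()
  co <- autostrat:::coplayer_view(fuss)
  for (lab in c(72, 65)) {
    s <- which(fuss$labels == lab)
    expect_false(any(co$succ == s))   # reachable only by one's own error
    expect_identical(fuss$action[s], 0L)  # and prescribing cooperation there
  }
})

test_that("the PS2 fixture walks the printed despair path under a double error", {
  sys <- joint_system(rep(list(ps2_automaton()), 3), e = 0)
  tr <- trace_recovery(sys, list(c(1, 2), c(2, 2)))
  # the focal player moves full trust -> distrust -> despair -> distrust of
  # the *other* co-player: the memory-two architecture forgets who started
  states <- do.call(rbind, strsplit(gsub("[()]", "", tr$state), ","))
  expect_identical(states[1:4, 1], c("0", "4", "5", "1"))
  expect_identical(tr$realized[1:3], c("cdc", "ddd", "dcd"))
})

test_that("the PS2 fixture is partially successful with an intermediate limit", {
  r <- classify(ps2_automaton())
  expect_identical(r$label, "partially successful")
  expect_true(r$defensible)
  expect_true(r$distinguishable)
  eff <- check_efficiency(ps2_automaton())
  expect_false(eff$efficient)
  expect_true(eff$partially_efficient)
  expect_gt(eff$limit, 0.1)
  expect_lt(eff$limit, 0.9)
})

test_that("PS2 recovers from any single error but not from joint defection", {
  expect_true(verify_error_recovery(ps2_automaton(), 1)$ok)
  rec2 <- verify_error_recovery(ps2_automaton(), 2)
  expect_false(rec2$ok)
  # the uncovered patterns include two co-players erring at once
  sys <- joint_system(rep(list(ps2_automaton()), 3), e = 0)
  tr <- trace_recovery(sys, list(c(1, 2), c(1, 3)))
  expect_false(attr(tr, "recovered"))
  expect_identical(attr(tr, "final_state"), "(5,5,5)")
})

test_that("both fixtures expose the apology/provocation exploitation loop", {
  for (fix in list(fuss_automaton(), ps2_automaton())) {
    apology <- if (any(fix$labels == 64)) 64 else 16
    provoke <- if (any(fix$labels == 66)) 66 else 18
    sa <- which(fix$labels == apology)
    sp <- which(fix$labels == provoke)
    # apology under unanimous cooperation turns into provocation ...
    expect_identical(step_automaton(fix, sa, c(0L, 0L, 0L)), sp)
    # ... and the provoking defection against naive cooperators returns
    expect_identical(step_automaton(fix, sp, c(1L, 0L, 0L)), sa)
    # so the payoff gap against unconditional cooperators is order one
    gap <- check_distinguishability(fix)$gap
    expect_gt(gap, 0.2)
  }
})

test_that("fixture automata are symmetric under exchanging the co-players", {
  for (fix in list(fuss_automaton(), ps2_automaton())) {
    mirror_label <- function(lab) {
      if (any(fix$labels == 8)) {
        swap <- c(`8` = 1, `1` = 8, `76` = 67, `67` = 76, `72` = 65, `65` = 72)
      } else {
        swap <- c(`4` = 1, `1` = 4)
      }
      out <- swap[as.character(lab)]
      ifelse(is.na(out), lab, out)
    }
    for (s in seq_along(fix$labels)) {
      sm <- which(fix$labels == mirror_label(fix$labels[s]))
      expect_identical(fix$action[s], fix$action[sm])
      for (code in 0:7) {
        a <- code %/% 4L; x <- (code %% 4L) %/% 2L; y <- code %% 2L
        dst <- fix$labels[step_automaton(fix, s, c(a, x, y))]
        dst_m <- fix$labels[step_automaton(fix, sm, c(a, y, x))]
        expect_identical(unname(mirror_label(dst)), unname(dst_m))
      }
    }
  }
})
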