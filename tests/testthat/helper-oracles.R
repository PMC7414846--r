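# Independent oracles used by the test suite. These deliberately avoid the
# package's own graph machinery: defensibility is checked by exhaustive play
# against every memory-<=2 adversary, and minimality by pairwise state
# equivalence.

# Exhaustive-adversary defensibility oracle for a memory-one two-player
# strategy: plays the focal table against all 2^16 memory-two adversary
# tables from all 16 initial histories, follows each deterministic orbit
# into its cycle, and reports whether any adversary gains a positive
# cycle-averaged payoff advantage. Payoff differences reduce to
# [b = d] - [a = d] per round, independent of rho.
adversary_oracle_defensible <- function(focal_m1) {
  stopifnot(length(focal_m1) == 4)         # action at (a_last, b_last)
  n_adv <- 65536L
  adv <- rep(0:(n_adv - 1), times = 16L)
  start <- rep(0:15, each = n_adv)
  s <- start
  focal_at <- function(s) {
    af <- s %/% 4L; bf <- s %% 4L
    focal_m1[2L * (af %% 2L) + (bf %% 2L) + 1L]
  }
  adv_at <- function(adv, s) {
    sw <- (s %% 4L) * 4L + s %/% 4L        # adversary's viewpoint
    (adv %/% 2L^(15L - sw)) %% 2L          # table bit at profile code sw
  }
  step <- function(s, a, b) {
    ((s %/% 4L * 2L + a) %% 4L) * 4L + (s %% 4L * 2L + b) %% 4L
  }
  for (i in 1:16) {                         # burn-in: land inside the cycle
    a <- focal_at(s); b <- adv_at(adv, s)
    s <- step(s, a, b)
  }
  s0 <- s
  gain <- numeric(length(s))
  active <- rep(TRUE, length(s))
  for (i in 1:16) {
    a <- focal_at(s); b <- adv_at(adv, s)
    gain[active] <- gain[active] + (b - a)[active]
    s <- ifelse(active, step(s, a, b), s)
    active <- active & !(s == s0)
    if (!any(active)) break
  }
  all(gain <= 0)
}

# Pairwise bisimilarity of two states of one automaton (used by the
# minimality oracle): breadth-first search over state pairs.
states_equivalent <- function(aut, s1, s2) {
  k <- length(aut$action)
  seen <- matrix(FALSE, k, k)
  queue <- matrix(c(s1, s2), 1, 2)
  while (nrow(queue) > 0) {
    fresh <- !seen[queue]
    queue <- queue[fresh, , drop = FALSE]
    if (!nrow(queue)) break
    if (any(aut$action[queue[, 1]] != aut$action[queue[, 2]])) return(FALSE)
    seen[queue] <- TRUE
    queue <- unique(do.call(rbind, lapply(seq_len(ncol(aut$trans)), function(kk)
      cbind(aut$trans[queue[, 1], kk], aut$trans[queue[, 2], kk]))))
  }
  TRUE
}

# No pair of distinct states of a minimal automaton may be bisimilar.
has_mergeable_pair <- function(aut) {
  k <- length(aut$action)
  if (k < 2) return(FALSE)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      if (states_equivalent(aut, i, j)) return(TRUE)
    }
  }
  FALSE
}

# All simple cycles of a small co-player-input transition graph, by DFS;
# returns TRUE iff some cycle has positive summed weight for co-player j.
# Exhaustive and independent of the Bellman-Ford search.
exhaustive_positive_cycle <- function(succ, weight) {
  nn <- nrow(succ)
  found <- FALSE
  path_nodes <- integer(0)
  path_w <- 0
  visit <- function(v, root, depth) {
    if (found) return(invisible())
    for (k in seq_len(ncol(succ))) {
      w2 <- path_w + weight[v, k]
      nxt <- succ[v, k]
      if (nxt == root && w2 > 1e-9) { found <<- TRUE; return(invisible()) }
      if (nxt > root && !(nxt %in% path_nodes) && depth < nn) {
        path_nodes <<- c(path_nodes, nxt)
        old <- path_w; path_w <<- w2
        visit(nxt, root, depth + 1L)
        path_nodes <<- path_nodes[-length(path_nodes)]
        path_w <<- old
      }
    }
  }
  for (root in seq_len(nn)) {
    path_nodes <- root; path_w <- 0
    visit(root, root, 1L)
    if (found) return(TRUE)
  }
  FALSE
}

coplayer_graph_for_tests <- function(strategy) {
  g <- build_transition_graph(strategy, "coplayer")
  list(succ = g$succ, action = g$action)
}
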