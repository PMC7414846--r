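# Defensibility, efficiency, distinguishability -- the three criteria of a
# successful strategy -- plus the classifier and the error-recovery verifier.

# Co-player-alphabet view of a strategy or automaton: states, prescribed
# action per state, successor matrix (state x co-player tuple), and state
# labels. For a full-alphabet automaton the focal action is fixed to the
# prescription (the adversary controls only the co-players).
coplayer_view <- function(x) {
  if (inherits(x, "history_strategy")) {
    g <- build_transition_graph(x, "coplayer")
    list(n = x$n, action = g$action, succ = g$succ,
         labels = 0:(nrow(g$succ) - 1))
  } else if (inherits(x, "automaton")) {
    if (x$alphabet == "coplayer") {
      list(n = x$n, action = x$action, succ = x$trans, labels = x$labels)
    } else {
      k <- n_states(x)
      n_co <- 2^(x$n - 1L)
      succ <- matrix(0L, k, n_co)
      for (kk in 0:(n_co - 1)) {
        co_bits <- as.integer(intToBits(kk))[(x$n - 1L):1]
        for (s in seq_len(k)) {
          succ[s, kk + 1L] <- step_automaton(x, s, c(x$action[s], co_bits))
        }
      }
      list(n = x$n, action = x$action, succ = succ, labels = x$labels)
    }
  } else {
    stop("expected a history strategy or an automaton", call. = FALSE)
  }
}

# Longest-path relaxation (Bellman-Ford with max-plus) from a virtual source
# attached to every node; a positive cycle exists iff relaxation still
# improves after |V| rounds. Returns the cycle (node indices and input
# codes) when one exists.
positive_cycle <- function(succ, weight) {
  nn <- nrow(succ); n_in <- ncol(succ)
  dist <- rep(0, nn)
  parent <- rep(NA_integer_, nn); parent_in <- rep(NA_integer_, nn)
  improved_node <- NA_integer_
  for (it in seq_len(nn + 1L)) {
    changed <- FALSE
    for (kk in seq_len(n_in)) {
      cand <- dist + weight[, kk]
      dst <- succ[, kk]
      better <- cand > dist[dst] + 1e-12
      if (any(better)) {
        changed <- TRUE
        src <- which(better)
        # resolve duplicate destinations: keep the best candidate
        ord <- order(cand[src])
        for (u in src[ord]) {
          v <- dst[u]
          if (cand[u] > dist[v] + 1e-12) {
            dist[v] <- cand[u]; parent[v] <- u; parent_in[v] <- kk
            improved_node <- v
          }
        }
      }
    }
    if (!changed) return(NULL)
  }
  # walk back |V| steps to land inside the positive cycle, then extract it
  v <- improved_node
  for (i in seq_len(nn)) v <- parent[v]
  cyc_nodes <- integer(0); cyc_in <- integer(0)
  u <- v
  repeat {
    cyc_nodes <- c(parent[u], cyc_nodes)
    cyc_in <- c(parent_in[u], cyc_in)
    u <- parent[u]
    if (u == v) break
  }
  list(nodes = cyc_nodes, inputs = cyc_in)
}

#' Defensibility check by positive-cycle search
#'
#' A deterministic strategy is defensible iff no co-player can accumulate an
#' unbounded payoff advantage over the focal player. Because the public-goods
#' payoffs satisfy `payoff_j - payoff_focal = [a_j = d] - [a_focal = d]`
#' exactly, this holds iff, for each co-player index j, the co-player-input
#' transition graph (over all states, with adversarial inputs) has no cycle
#' whose summed weight `[a_j = d] - [a_focal = d]` is positive. The search is
#' a longest-path Bellman-Ford relaxation over the whole graph, so the
#' verdict covers adversarial initial histories as well.
#'
#' @param x a [history_strategy()] or [automaton()].
#' @return a list with `defensible` (logical) and, when `FALSE`, `witness`:
#'   a data.frame of the exploiting cycle (state labels, co-player input
#'   labels and per-round weight for the offending co-player).
#' @export
check_defensibility <- function(x) {
  v <- coplayer_view(x)
  n <- v$n
  n_co <- 2^(n - 1L)
  co_bits <- sapply(0:(n_co - 1), function(kk)
    as.integer(intToBits(kk))[(n - 1L):1])
  co_bits <- matrix(co_bits, nrow = n - 1L)   # rows = co-players, cols = input
  for (j in seq_len(n - 1L)) {
    w <- outer(-v$action, co_bits[j, ], "+")  # [x_j = d] - [a_focal = d]
    cyc <- positive_cycle(v$succ, w)
    if (!is.null(cyc)) {
      ins <- cyc$inputs
      wt <- w[cbind(cyc$nodes, ins)]
      witness <- data.frame(
        state = v$labels[cyc$nodes],
        input = vapply(ins - 1L, function(code) {
          bits <- as.integer(intToBits(code))[(n - 1L):1]
          paste(action_to_char(bits), collapse = "")
        }, character(1)),
        weight = wt)
      return(list(defensible = FALSE, coplayer = j, witness = witness))
    }
  }
  list(defensible = TRUE, witness = NULL)
}

# Full-cooperation stationary mass of n identical players at each error rate.
coop_mass_grid <- function(x, e_grid, rho) {
  n <- x$n
  vapply(e_grid, function(e) {
    sys <- joint_system(rep(list(x), n), e = e, rho = rho)
    stationary_distribution(sys)$coop_mass
  }, numeric(1))
}

#' Efficiency check on an error-rate grid
#'
#' Efficiency demands that a homogeneous group of the strategy reaches full
#' cooperation with probability one as the implementation error rate tends
#' to zero. The check computes the stationary mass `p(e)` on the
#' full-cooperation state for a decreasing grid of error rates and requires
#' `1 - p(e)` to shrink at least linearly in `e` (ratio test within a factor
#' of two between successive grid points). Partial efficiency means `p(e)`
#' converges to a limit strictly between 0 and 1 (e.g. TFT, with limit 1/4).
#'
#' @param x a [history_strategy()] or a full-alphabet [automaton()]; all
#'   `n` players adopt it.
#' @param e_grid decreasing positive error rates.
#' @param rho multiplication factor of the payoff model.
#' @return a list with `efficient`, `partially_efficient`, `limit` (the
#'   estimated limit of `p(e)`), `p` (the grid values) and `inconclusive`.
#' @export
check_efficiency <- function(x, e_grid = c(1e-2, 1e-3, 1e-4), rho = 1.5) {
  stopifnot(length(e_grid) >= 2, all(diff(e_grid) < 0), all(e_grid > 0))
  p <- coop_mass_grid(x, e_grid, rho)
  delta <- 1 - p
  g <- e_grid[-length(e_grid)] / e_grid[-1]          # grid shrink factors
  r <- ifelse(delta[-1] > 0, delta[-length(delta)] / delta[-1], Inf)
  efficient <- all(r >= g / 2)
  stable <- all(r < 2)                                # 1 - p stopped shrinking
  q <- p[length(p)]
  partially <- !efficient && stable && q > 0.01 && q < 0.99
  inconclusive <- !efficient && !stable && !(q <= 0.01)
  list(efficient = efficient, partially_efficient = partially,
       limit = q, p = p, e_grid = e_grid, inconclusive = inconclusive)
}

# Any player as a full-alphabet automaton (exact lift for history tables).
as_full_automaton <- function(x) {
  if (inherits(x, "automaton")) {
    if (x$alphabet != "full") {
      stop("need a full-alphabet automaton to play under errors", call. = FALSE)
    }
    x
  } else {
    minimize_full(x)
  }
}

allc_automaton <- function(n) {
  automaton(n = n, alphabet = "full", labels = 0, action = 0L,
            trans = matrix(1L, 1, 2^n), start = 1L, name = "ALLC")
}

#' Distinguishability check against unconditional cooperators
#'
#' Distinguishable means: when all co-players are unconditional cooperators
#' (ALLC), the focal strategy's long-run payoff exceeds theirs by a strictly
#' positive margin in the small-error limit. The payoff gap is computed from
#' the exact stationary distribution on a decreasing error-rate grid; it is
#' O(1) in `e` for distinguishable strategies and O(e) otherwise, so the
#' verdict requires a gap above 1e-3 at the smallest rate, non-decreasing as
#' `e` shrinks.
#'
#' @inheritParams check_efficiency
#' @return a list with `distinguishable`, `gap` (at the smallest error
#'   rate) and `gaps` (the grid values).
#' @export
check_distinguishability <- function(x, e_grid = c(1e-2, 1e-3, 1e-4),
                                     rho = 1.5) {
  n <- x$n
  players <- if (inherits(x, "history_strategy")) {
    allc <- history_strategy(n, x$m, rep(0L, 2^(n * x$m)), name = "ALLC")
    c(list(x), rep(list(allc), n - 1L))
  } else {
    c(list(as_full_automaton(x)), rep(list(allc_automaton(n)), n - 1L))
  }
  gaps <- vapply(e_grid, function(e) {
    st <- stationary_distribution(joint_system(players, e = e, rho = rho))
    st$payoffs[1] - mean(st$payoffs[-1])
  }, numeric(1))
  ok <- gaps[length(gaps)] > 1e-3 &&
    all(diff(gaps) >= -0.1 * abs(gaps[-1]) - 1e-4)
  list(distinguishable = ok, gap = gaps[length(gaps)], gaps = gaps,
       e_grid = e_grid)
}

#' Classify a strategy by the three success criteria
#'
#' Runs [check_defensibility()], [check_efficiency()] and
#' [check_distinguishability()] and assigns the label `"successful"` (all
#' three hold), `"partially successful"` (defensible, distinguishable and
#' partially efficient -- the PS2 class in the three-person memory-two
#' space), or `"not successful"`.
#'
#' @inheritParams check_efficiency
#' @return an object of class `criteria_report`.
#' @export
classify <- function(x, e_grid = c(1e-2, 1e-3, 1e-4), rho = 1.5) {
  def <- check_defensibility(x)
  eff <- check_efficiency(x, e_grid, rho)
  dis <- check_distinguishability(x, e_grid, rho)
  label <- if (def$defensible && eff$efficient && dis$distinguishable) {
    "successful"
  } else if (def$defensible && eff$partially_efficient &&
             dis$distinguishable) {
    "partially successful"
  } else {
    "not successful"
  }
  structure(list(defensible = def$defensible, witness = def$witness,
                 efficient = eff$efficient,
                 partially_efficient = eff$partially_efficient,
                 efficiency_limit = eff$limit,
                 inconclusive = eff$inconclusive,
                 distinguishable = dis$distinguishable,
                 payoff_gap = dis$gap,
                 label = label),
            class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  cat(sprintf("<criteria report> %s\n", x$label))
  cat(sprintf("  defensible:       %s\n", x$defensible))
  cat(sprintf("  efficient:        %s (p(e) -> %.4g%s)\n", x$efficient,
              x$efficiency_limit,
              if (x$partially_efficient) ", partially efficient" else ""))
  cat(sprintf("  distinguishable:  %s (payoff gap %.4g)\n",
              x$distinguishable, x$payoff_gap))
  invisible(x)
}

#' Verify deterministic recovery from one- and two-bit errors
#'
#' All players adopt the given strategy (or automaton); dynamics are
#' error-free except for injected implementation errors. A pattern with at
#' most `max_error_bits` errors is: a single error; the same player erring
#' twice in consecutive rounds; two different players erring in consecutive
#' rounds; or two players erring simultaneously. The verdict is `TRUE` iff
#' every pattern returns to full cooperation (the orbit is deterministic, so
#' it either returns before revisiting a joint state or never does).
#'
#' @param x a [history_strategy()] or full-alphabet [automaton()].
#' @param max_error_bits 1 or 2.
#' @param rho multiplication factor (payoff bookkeeping only).
#' @return a list with `ok` (logical), `patterns` (count tried) and
#'   `failures` (list of uncovered injection patterns).
#' @export
verify_error_recovery <- function(x, max_error_bits = 2, rho = 1.5) {
  stopifnot(max_error_bits %in% 1:2)
  n <- x$n
  sys <- joint_system(rep(list(if (inherits(x, "automaton"))
    as_full_automaton(x) else x), n), e = 0, rho = rho)
  patterns <- list()
  for (i in seq_len(n)) patterns[[length(patterns) + 1L]] <- cbind(1, i)
  if (max_error_bits >= 2) {
    for (i in seq_len(n)) {
      patterns[[length(patterns) + 1L]] <- rbind(c(1, i), c(2, i))
      for (j in seq_len(n)) {
        if (j != i) patterns[[length(patterns) + 1L]] <- rbind(c(1, i), c(2, j))
      }
      for (j in seq_len(n)) {
        if (j > i) patterns[[length(patterns) + 1L]] <- rbind(c(1, i), c(1, j))
      }
    }
  }
  failures <- list()
  for (pat in patterns) {
    tr <- trace_recovery(sys, pat)
    if (!isTRUE(attr(tr, "recovered"))) {
      failures[[length(failures) + 1L]] <- pat
    }
  }
  list(ok = length(failures) == 0, patterns = length(patterns),
       failures = failures)
}
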