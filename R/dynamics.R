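#' Linear public-goods payoff model
#'
#' The n-person public-goods payoff used throughout: each cooperator pays a
#' unit contribution, contributions are multiplied by `rho` and shared
#' equally, and a defector keeps the unit. With `n_c` cooperators among all
#' `n` players, an action `a` earns `[a = d] + rho * n_c / n`. The iterated
#' prisoner's dilemma is the `n = 2` instance. For any two players i, j the
#' identity `payoff_j - payoff_i = [a_j = d] - [a_i = d]` holds, which makes
#' all payoff comparisons independent of `rho`.
#'
#' @param n player count.
#' @param rho multiplication factor, `1 < rho < n`.
#' @return an object of class `payoff_model`.
#' @export
payoff_model <- function(n, rho) {
  if (!(rho > 1 && rho < n)) {
    stop(sprintf("rho must satisfy 1 < rho < n = %d", n), call. = FALSE)
  }
  structure(list(n = as.integer(n), rho = rho), class = "payoff_model")
}

#' Per-round payoff
#'
#' @param action the focal player's action (0 = c, 1 = d).
#' @param defecting_coplayers number of defectors among the `n - 1`
#'   co-players.
#' @param model a [payoff_model()].
#' @return the focal player's payoff for the round.
#' @examples
#' m <- payoff_model(3, 1.5)
#' payoff(1, 2, m)  # full defection: 1, independent of rho
#' payoff(0, 0, m)  # full cooperation: rho
#' @export
payoff <- function(action, defecting_coplayers, model) {
  stopifnot(inherits(model, "payoff_model"), action %in% c(0L, 1L))
  if (any(defecting_coplayers < 0 | defecting_coplayers > model$n - 1)) {
    stop("defector count must lie in [0, n-1]", call. = FALSE)
  }
  n_c <- model$n - defecting_coplayers - (action == 1L)
  (action == 1L) + model$rho * n_c / model$n
}

# Payoffs of all players for every realized action profile: matrix
# [2^n x n], row r+1 = action tuple code r (player 1 most significant).
profile_payoffs <- function(model) {
  n <- model$n
  out <- matrix(0, nrow = 2^n, ncol = n)
  for (r in 0:(2^n - 1)) {
    acts <- as.integer(intToBits(r))[n:1]
    for (i in seq_len(n)) {
      out[r + 1L, i] <- payoff(acts[i], sum(acts[-i]), model)
    }
  }
  out
}

#' Joint system of players under implementation error
#'
#' Bundles `N = n` players (all [history_strategy()] objects of a common
#' `(n, m)`, or all full-alphabet [automaton()] objects) with an error rate
#' `e`. Each round every player independently misimplements its prescribed
#' action with probability `e`; all players observe the realized actions.
#' Player `i` views the players in cyclic order `(i, i+1, ..., i-1)`.
#'
#' For history-strategy players the joint state is the shared history
#' profile (labelled from player 1's viewpoint); for automaton players it is
#' the tuple of internal states, restricted to the closure of the start
#' tuple under all realized action profiles.
#'
#' @param players a list of `n` strategies or full-alphabet automata.
#' @param e implementation error rate in `[0, 1/2)`.
#' @param rho multiplication factor of the payoff model.
#' @return an object of class `joint_system` with fields `states` (labels),
#'   `prescribed` (state x player action matrix), `succ` (state x
#'   realized-profile successor matrix), `start`, `e`, and `model`.
#' @export
joint_system <- function(players, e = 0, rho = 1.5) {
  n <- length(players)
  stopifnot(n >= 2, e >= 0, e < 0.5)
  model <- payoff_model(n, rho)
  kinds <- vapply(players, function(p) class(p)[1], character(1))
  if (all(kinds == "history_strategy")) {
    ns <- vapply(players, `[[`, integer(1), "n")
    ms <- vapply(players, `[[`, integer(1), "m")
    if (!all(ns == n) || length(unique(ms)) != 1) {
      stop("history-strategy players need common (n, m) with n players",
           call. = FALSE)
    }
    m <- ms[1]
    codes <- 0:(2^(n * m) - 1)
    fields <- profile_fields(codes, n, m)
    prescribed <- matrix(0L, length(codes), n)
    for (i in seq_len(n)) {
      rot <- c(i:n, seq_len(i - 1L))        # player i's cyclic viewpoint
      view <- fields_to_codes(fields[, rot, drop = FALSE], n, m)
      prescribed[, i] <- players[[i]]$actions[view + 1L]
    }
    succ <- matrix(0L, length(codes), 2^n)
    for (r in 0:(2^n - 1)) {
      acts <- as.integer(intToBits(r))[n:1]
      succ[, r + 1L] <- shift_profile(codes, n, m, acts) + 1L
    }
    labels <- vapply(codes, profile_label, character(1), n = n, m = m)
    start <- 1L
  } else if (all(kinds == "automaton")) {
    ok <- vapply(players, function(p) p$alphabet == "full" && p$n == n,
                 logical(1))
    if (!all(ok)) {
      stop("automaton players must all use the full alphabet of an n-player game",
           call. = FALSE)
    }
    # closure of the start tuple under every realized action profile
    key <- function(s) paste(s, collapse = ",")
    start_tuple <- vapply(players, `[[`, integer(1), "start")
    states <- list(start_tuple)
    index <- new.env(parent = emptyenv())
    assign(key(start_tuple), 1L, envir = index)
    succ_rows <- list()
    head <- 1L
    while (head <= length(states)) {
      s <- states[[head]]
      row <- integer(2^n)
      for (r in 0:(2^n - 1)) {
        acts <- as.integer(intToBits(r))[n:1]
        s2 <- integer(n)
        for (i in seq_len(n)) {
          rot <- c(i:n, seq_len(i - 1L))
          s2[i] <- step_automaton(players[[i]], s[i], acts[rot])
        }
        k2 <- key(s2)
        j <- index[[k2]]
        if (is.null(j)) {
          states[[length(states) + 1L]] <- s2
          j <- length(states)
          assign(k2, j, envir = index)
        }
        row[r + 1L] <- j
      }
      succ_rows[[head]] <- row
      head <- head + 1L
    }
    succ <- do.call(rbind, succ_rows)
    prescribed <- t(vapply(states, function(s) {
      vapply(seq_len(n), function(i) players[[i]]$action[s[i]], integer(1))
    }, integer(n)))
    labels <- vapply(states, function(s) {
      paste0("(", paste(vapply(seq_len(n), function(i) {
        lab <- players[[i]]$labels[s[i]]
        as.character(lab)
      }, character(1)), collapse = ","), ")")
    }, character(1))
    start <- 1L
  } else {
    stop("players must be all history strategies or all full-alphabet automata",
         call. = FALSE)
  }
  structure(list(n = n, players = players, e = e, model = model,
                 states = labels, prescribed = prescribed, succ = succ,
                 start = start),
            class = "joint_system")
}

#' @export
print.joint_system <- function(x, ...) {
  cat(sprintf("<joint system> %d players, e = %g, %d joint states\n",
              x$n, x$e, length(x$states)))
  invisible(x)
}

# Probability of each realized action profile (columns, tuple code order)
# given the prescribed actions in each state (rows).
realization_probs <- function(system) {
  n <- system$n; e <- system$e
  ns <- nrow(system$prescribed)
  probs <- matrix(1, ns, 2^n)
  for (r in 0:(2^n - 1)) {
    acts <- as.integer(intToBits(r))[n:1]
    flips <- rowSums(system$prescribed != matrix(acts, ns, n, byrow = TRUE))
    probs[, r + 1L] <- e^flips * (1 - e)^(n - flips)
  }
  probs
}

#' Exact transition matrix of the joint Markov chain
#'
#' @param system a [joint_system()].
#' @return a row-stochastic matrix over the joint states, with the state
#'   labels as dimnames.
#' @export
transition_matrix <- function(system) {
  stopifnot(inherits(system, "joint_system"))
  probs <- realization_probs(system)
  ns <- nrow(probs)
  P <- matrix(0, ns, ns, dimnames = list(system$states, system$states))
  for (r in seq_len(ncol(probs))) {
    idx <- cbind(seq_len(ns), system$succ[, r])
    P[idx] <- P[idx] + probs[, r]
  }
  P
}

#' Stationary distribution and long-run payoffs
#'
#' Solves the left eigenproblem `pi P = pi` (dense linear solve up to 4096
#' states, power iteration above) and reports the long-run expected payoff
#' of each player and the stationary mass on the full-cooperation state.
#'
#' @param system a [joint_system()] with `e > 0`, or a row-stochastic matrix
#'   (then `payoffs` and `coop_mass` require `system`).
#' @param tol residual tolerance on `max |pi P - pi|`.
#' @return a list with `distribution` (named), `payoffs` (per player),
#'   `coop_mass` (mass on the full-cooperation state) and `residual`.
#' @export
stationary_distribution <- function(system, tol = 1e-10) {
  if (inherits(system, "joint_system")) {
    if (system$e <= 0) {
      stop("the joint chain is reducible at e = 0; use e > 0 or trace_recovery()",
           call. = FALSE)
    }
    P <- transition_matrix(system)
  } else {
    P <- system
    system <- NULL
  }
  ns <- nrow(P)
  if (ns <= 4096) {
    A <- t(P) - diag(ns)
    A[ns, ] <- 1                       # replace one equation by normalization
    b <- c(rep(0, ns - 1), 1)
    pi_vec <- solve(A, b)
  } else {
    pi_vec <- rep(1 / ns, ns)
    for (it in 1:100000) {
      nxt <- as.vector(pi_vec %*% P)
      if (max(abs(nxt - pi_vec)) < tol / 10) { pi_vec <- nxt; break }
      pi_vec <- nxt
    }
  }
  pi_vec <- pmax(pi_vec, 0); pi_vec <- pi_vec / sum(pi_vec)
  residual <- max(abs(as.vector(pi_vec %*% P) - pi_vec))
  names(pi_vec) <- rownames(P)
  out <- list(distribution = pi_vec, residual = residual)
  if (!is.null(system)) {
    probs <- realization_probs(system)
    pay <- profile_payoffs(system$model)
    n <- system$n
    # player i's payoff must be read in player-1 frame: tuple codes are in
    # the global (player-1 first) frame already
    exp_state <- probs %*% pay          # state x player expected payoff
    out$payoffs <- as.vector(pi_vec %*% exp_state)
    out$coop_mass <- unname(pi_vec[system$start])
    out$coop_action_freq <- sum(pi_vec * probs[, 1])
  }
  out
}

#' Deterministic trace with injected errors
#'
#' Follows the error-free joint dynamics from full cooperation, flipping the
#' prescribed action of given players in given rounds, and reports the orbit
#' and whether (and when) full cooperation recurs after the last injection.
#'
#' @param system a [joint_system()] (its `e` is ignored; dynamics are
#'   deterministic apart from the injections).
#' @param injected_errors a list of `c(round, player)` pairs, or a two-column
#'   matrix; rounds count from 1.
#' @param max_rounds safety bound on the trace length (default: one full
#'   cycle of the joint state space).
#' @return a data.frame with columns `round`, `state` (label at the start of
#'   the round), `realized` (action string); attributes `recovered`
#'   (logical) and `recovery_round` (first round after the last injection at
#'   whose end the system is back at full cooperation).
#' @export
trace_recovery <- function(system, injected_errors = list(),
                           max_rounds = NULL) {
  stopifnot(inherits(system, "joint_system"))
  if (is.matrix(injected_errors)) {
    injected_errors <- lapply(seq_len(nrow(injected_errors)),
                              function(i) injected_errors[i, ])
  }
  err_round <- vapply(injected_errors, `[[`, numeric(1), 1)
  err_player <- vapply(injected_errors, `[[`, numeric(1), 2)
  last_err <- if (length(err_round)) max(err_round) else 0
  n <- system$n
  if (is.null(max_rounds)) max_rounds <- nrow(system$succ) + last_err + 1L
  s <- system$start
  rows <- list()
  recovered <- FALSE; recovery_round <- NA_integer_
  seen_after <- integer(0)
  for (t in seq_len(max_rounds)) {
    acts <- system$prescribed[s, ]
    flip <- err_player[err_round == t]
    acts[flip] <- 1L - acts[flip]
    rows[[t]] <- data.frame(round = t, state = system$states[s],
                            realized = paste(action_to_char(acts),
                                             collapse = ""))
    s <- system$succ[s, tuple_code(acts) + 1L]
    if (t >= last_err) {
      if (s == system$start) { recovered <- TRUE; recovery_round <- t; break }
      if (s %in% seen_after) break       # trapped in a non-cooperative cycle
      seen_after <- c(seen_after, s)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "recovered") <- recovered
  attr(out, "recovery_round") <- recovery_round
  attr(out, "final_state") <- system$states[s]
  out
}

#' Monte-Carlo simulation of the joint system
#'
#' @param system a [joint_system()].
#' @param rounds number of rounds (>= 1).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @return a list with `states` (visited state indices, length `rounds`),
#'   `actions` (rounds x n realized 0/1 matrix), `mean_payoffs` (per
#'   player) and `coop_freq` (fraction of rounds with full cooperation).
#' @export
simulate_system <- function(system, rounds, seed) {
  stopifnot(inherits(system, "joint_system"), rounds >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- system$n
  flips <- matrix(stats::runif(rounds * n) < system$e, rounds, n)
  pay <- profile_payoffs(system$model)
  s <- system$start
  states <- integer(rounds)
  acts_out <- matrix(0L, rounds, n)
  paysum <- numeric(n)
  for (t in seq_len(rounds)) {
    states[t] <- s
    acts <- system$prescribed[s, ]
    acts <- ifelse(flips[t, ], 1L - acts, acts)
    acts_out[t, ] <- acts
    code <- tuple_code(acts)
    paysum <- paysum + pay[code + 1L, ]
    s <- system$succ[s, code + 1L]
  }
  list(states = states, actions = acts_out,
       mean_payoffs = paysum / rounds,
       coop_freq = mean(rowSums(acts_out) == 0))
}
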