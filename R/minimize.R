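#' Naive transition graph of a history strategy
#'
#' Reinterprets a memory-m strategy as an automaton whose states are the
#' `2^(nm)` history profiles themselves. With the `"coplayer"` alphabet the
#' focal player's action is fixed by the table, so every node has `2^(n-1)`
#' outgoing links (one per co-player action tuple); error-caused transitions
#' are not represented. With the `"full"` alphabet the focal player's
#' realized action is part of the input, giving `2^n` links per node and
#' retaining the complete information of the action table.
#'
#' @param strategy a [history_strategy()].
#' @param alphabet `"coplayer"` (default) or `"full"`.
#' @return an object of class `transition_graph` with fields `n`, `m`,
#'   `alphabet`, `action` (prescribed action per node, by profile code) and
#'   `succ` (node x input matrix of 1-based successor indices).
#' @export
build_transition_graph <- function(strategy, alphabet = c("coplayer", "full")) {
  alphabet <- match.arg(alphabet)
  n <- strategy$n; m <- strategy$m
  codes <- 0:(2^(n * m) - 1)
  n_inputs <- if (alphabet == "full") 2^n else 2^(n - 1L)
  succ <- matrix(0L, nrow = length(codes), ncol = n_inputs)
  for (k in 0:(n_inputs - 1L)) {
    width <- if (alphabet == "full") n else n - 1L
    bits <- as.integer(intToBits(k))[width:1]
    acts <- if (alphabet == "full") {
      matrix(bits, nrow = length(codes), ncol = n, byrow = TRUE)
    } else {
      cbind(strategy$actions, matrix(bits, nrow = length(codes),
                                     ncol = n - 1L, byrow = TRUE))
    }
    succ[, k + 1L] <- shift_profile(codes, n, m, acts) + 1L
  }
  structure(list(n = n, m = m, alphabet = alphabet,
                 action = strategy$actions, succ = succ,
                 name = strategy$name),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition graph%s> n=%d m=%d, %s alphabet: %d nodes, out-degree %d\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n, x$m, x$alphabet, nrow(x$succ), ncol(x$succ)))
  invisible(x)
}

#' Minimize a transition graph into a canonical automaton
#'
#' Moore-style partition refinement: the initial partition splits the nodes
#' by prescribed action; each round simultaneously splits every block whose
#' members disagree, for some input, on the block their successor belongs
#' to; the fixed point is the Myhill–Nerode partition, independent of
#' processing order. Each resulting state is labelled by the minimum profile
#' code among its constituent nodes, and the start state is the block
#' containing profile code 0 (full cooperation).
#'
#' @param graph a [build_transition_graph()] result.
#' @param order optional permutation of the node indices, used only to
#'   exercise order independence: the refinement is run with nodes processed
#'   in this order and must (and does) return the same partition.
#' @return an [automaton()] whose `blocks` field lists the constituent
#'   profile codes of each state; the attribute `"refinement_rounds"` records
#'   the number of refinement rounds until the fixed point.
#' @export
minimize <- function(graph, order = NULL) {
  stopifnot(inherits(graph, "transition_graph"))
  nn <- nrow(graph$succ)
  idx <- if (is.null(order)) seq_len(nn) else as.integer(order)
  stopifnot(length(idx) == nn, !anyDuplicated(idx))
  # partition id per node, computed over the permuted node order so that a
  # different processing order exercises different block numberings
  part <- integer(nn)
  part[idx] <- match(graph$action[idx], unique(graph$action[idx]))
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    sig <- cbind(part, matrix(part[graph$succ], nrow = nn))
    key <- do.call(paste, c(as.data.frame(sig), sep = ","))
    new_part <- integer(nn)
    new_part[idx] <- match(key[idx], unique(key[idx]))
    if (identical(new_part, part)) break
    part <- new_part
    if (rounds > nn) stop("refinement failed to terminate") # unreachable
  }
  blocks <- unname(split(0:(nn - 1), part))
  labels <- vapply(blocks, min, numeric(1))
  ord <- order(labels)
  blocks <- blocks[ord]; labels <- labels[ord]
  state_of_node <- integer(nn)
  for (s in seq_along(blocks)) state_of_node[blocks[[s]] + 1L] <- s
  reps <- vapply(blocks, function(b) b[[1]] + 1L, numeric(1))
  trans <- matrix(state_of_node[graph$succ[reps, , drop = FALSE]],
                  nrow = length(blocks))
  aut <- automaton(n = graph$n, alphabet = graph$alphabet, labels = labels,
                   action = graph$action[reps], trans = trans,
                   start = state_of_node[1L], m = graph$m,
                   blocks = unname(blocks), name = graph$name)
  attr(aut, "refinement_rounds") <- rounds
  aut
}

#' Minimize with the full input alphabet
#'
#' Minimizes the transition graph that also carries the links caused by the
#' focal player's own erroneous actions. The result is behaviourally
#' equivalent to the original history-based representation (see
#' [reconstruct_table()]) and has at least as many states as the
#' `"coplayer"` minimization.
#'
#' @param strategy a [history_strategy()].
#' @return an [automaton()] with `"full"` alphabet.
#' @export
minimize_full <- function(strategy) {
  minimize(build_transition_graph(strategy, "full"))
}

#' Reconstruct the action table from a full-alphabet automaton
#'
#' Feeds every length-`m` word of joint actions into the automaton from
#' every state; if the automaton realizes a memory-m strategy, the
#' prescribed action after the word is independent of the start state and
#' defines the table entry at the word's profile code.
#'
#' @param aut an [automaton()] with `"full"` alphabet.
#' @param n,m dimensions of the table to reconstruct (default: the
#'   automaton's own).
#' @return a [history_strategy()]; errors if the automaton is not memory-m
#'   realizable.
#' @export
reconstruct_table <- function(aut, n = aut$n, m = aut$m) {
  stopifnot(inherits(aut, "automaton"))
  if (aut$alphabet != "full") {
    stop("table reconstruction needs a full-alphabet automaton", call. = FALSE)
  }
  if (is.null(m)) stop("memory length m must be supplied", call. = FALSE)
  k <- n_states(aut)
  nprof <- 2^(n * m)
  table <- integer(nprof)
  for (w in 0:(nprof - 1)) {
    prof <- decode_profile(w, n, m)
    states <- seq_len(k)
    for (t in seq_len(m)) {
      states <- aut$trans[cbind(states, tuple_code(prof$actions[, t]) + 1L)]
    }
    acts <- unique(aut$action[states])
    if (length(acts) != 1L) {
      stop(sprintf(
        "automaton is not memory-%d realizable: word %s leaves the action undetermined",
        m, profile_label(w, n, m)), call. = FALSE)
    }
    table[w + 1L] <- acts
  }
  history_strategy(n, m, table, name = aut$name)
}

#' Bisimulation equivalence of strategies and automata
#'
#' Product construction over reachable state pairs: two machines are
#' equivalent iff no reachable pair of states disagrees on the prescribed
#' action. A [history_strategy()] argument is lifted to its naive transition
#' graph in the automaton's alphabet. When the automaton carries its
#' `blocks` (i.e. came out of [minimize()]), the check is run from the pair
#' (profile code, its block) for every profile code, so equivalence is
#' start-state independent; otherwise it starts from the two start states.
#'
#' @param a a [history_strategy()] or [automaton()].
#' @param b an [automaton()].
#' @return `TRUE` or `FALSE`.
#' @export
are_equivalent <- function(a, b) {
  stopifnot(inherits(b, "automaton"))
  if (inherits(a, "history_strategy")) {
    if (a$n != b$n) stop("player counts differ", call. = FALSE)
    g <- build_transition_graph(a, b$alphabet)
    a_action <- g$action
    a_trans <- g$succ
    if (!is.null(b$blocks)) {
      node_state <- integer(nrow(a_trans))
      ok <- TRUE
      for (s in seq_along(b$blocks)) {
        bl <- b$blocks[[s]] + 1L
        bl <- bl[bl <= length(node_state)]
        node_state[bl] <- s
      }
      if (any(node_state == 0L)) {
        start_pairs <- cbind(1L, b$start)     # blocks do not cover: fall back
      } else {
        start_pairs <- cbind(seq_len(nrow(a_trans)), node_state)
      }
    } else {
      start_pairs <- cbind(1L, b$start)
    }
  } else {
    stopifnot(inherits(a, "automaton"))
    if (a$n != b$n) stop("player counts differ", call. = FALSE)
    if (a$alphabet != b$alphabet) {
      stop("alphabet mismatch between the two automata", call. = FALSE)
    }
    a_action <- a$action
    a_trans <- a$trans
    start_pairs <- cbind(a$start, b$start)
  }
  if (ncol(a_trans) != ncol(b$trans)) {
    stop("alphabet mismatch", call. = FALSE)
  }
  ka <- length(a_action)
  seen <- matrix(FALSE, nrow = ka, ncol = n_states(b))
  queue <- start_pairs
  while (nrow(queue) > 0) {
    seen_now <- seen[queue] # logical per row
    queue <- queue[!seen_now, , drop = FALSE]
    if (nrow(queue) == 0) break
    if (any(a_action[queue[, 1]] != b$action[queue[, 2]])) return(FALSE)
    seen[queue] <- TRUE
    nxt <- vector("list", ncol(a_trans))
    for (kk in seq_len(ncol(a_trans))) {
      nxt[[kk]] <- cbind(a_trans[queue[, 1], kk], b$trans[queue[, 2], kk])
    }
    queue <- unique(do.call(rbind, nxt))
  }
  TRUE
}
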