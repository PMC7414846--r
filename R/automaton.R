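#' Finite-state strategy automata
#'
#' An automaton represents a strategy by a finite set of internal states.
#' Each state prescribes an action, and an input-labelled transition function
#' moves between states. Two input alphabets occur:
#'
#' * `"coplayer"`: inputs are the co-players' realized action tuples
#'   (`2^(n-1)` symbols); the focal player is assumed to play the prescribed
#'   action. This is the alphabet of the minimized, error-free representation.
#' * `"full"`: inputs are all `n` players' realized actions, focal player
#'   first (`2^n` symbols), so transitions after the focal player's own
#'   erroneous action are also defined.
#'
#' Input symbols are ordered by the binary code of the action tuple (first
#' player of the tuple most significant, c = 0, d = 1), so input index `k`
#' (1-based) encodes tuple code `k - 1`.
#'
#' @param n player count of the game.
#' @param alphabet `"coplayer"` or `"full"`.
#' @param labels numeric state labels (for minimized automata, the minimum
#'   constituent profile code of each state).
#' @param action integer vector of 0/1, prescribed action per state.
#' @param trans integer matrix (`n_states` x `n_inputs`) of 1-based state
#'   indices: `trans[s, k]` is the successor of state `s` on input code
#'   `k - 1`.
#' @param start 1-based index of the start state.
#' @param m memory length of the generating strategy, if any.
#' @param blocks optional list of constituent profile codes per state (set
#'   by [minimize()]).
#' @param name optional label.
#' @param state_names optional display names for states.
#' @return an object of class `automaton`.
#' @export
automaton <- function(n, alphabet = c("coplayer", "full"), labels, action,
                      trans, start = 1L, m = NULL, blocks = NULL,
                      name = NULL, state_names = NULL) {
  alphabet <- match.arg(alphabet)
  n_inputs <- if (alphabet == "full") 2^n else 2^(n - 1L)
  trans <- as.matrix(trans)
  storage.mode(trans) <- "integer"
  action <- as.integer(action)
  k <- length(action)
  stopifnot(nrow(trans) == k, ncol(trans) == n_inputs,
            all(trans >= 1L & trans <= k), all(action %in% c(0L, 1L)),
            length(labels) == k, start >= 1L, start <= k)
  structure(list(n = as.integer(n), m = m, alphabet = alphabet,
                 labels = labels, action = action, trans = trans,
                 start = as.integer(start), blocks = blocks, name = name,
                 state_names = state_names),
            class = "automaton")
}

n_states <- function(a) length(a$action)

#' @export
print.automaton <- function(x, ...) {
  cat(sprintf("<automaton%s> n=%d, %s alphabet, %d state%s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n, x$alphabet, n_states(x), if (n_states(x) == 1) "" else "s"))
  nm <- if (is.null(x$state_names)) as.character(x$labels) else x$state_names
  cat(sprintf("  states: %s\n",
              paste(sprintf("%s(%s)", nm, action_to_char(x$action)),
                    collapse = " ")))
  invisible(x)
}

# Character labels of the input symbols ("cd", "cdc", ...).
input_labels <- function(a) {
  width <- if (a$alphabet == "full") a$n else a$n - 1L
  vapply(0:(2^width - 1), function(code) {
    bits <- as.integer(intToBits(code))[width:1]
    paste(action_to_char(bits), collapse = "")
  }, character(1))
}

# Tuple code of an action vector (first element most significant).
tuple_code <- function(acts) {
  if (is.null(dim(acts))) acts <- matrix(acts, nrow = 1L)
  w <- ncol(acts)
  as.integer(acts %*% 2^((w - 1):0))
}

#' Step an automaton
#'
#' @param a an [automaton()].
#' @param state 1-based current state index (vectorized).
#' @param acts realized actions: for a `"full"` automaton a length-`n` 0/1
#'   vector (focal first) or a matrix with one row per state; for a
#'   `"coplayer"` automaton the co-players' actions only.
#' @return the successor state index (vectorized).
#' @export
step_automaton <- function(a, state, acts) {
  k <- tuple_code(acts)
  if (length(k) == 1L) k <- rep(k, length(state))
  a$trans[cbind(state, k + 1L)]
}
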