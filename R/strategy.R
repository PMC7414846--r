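#' Deterministic memory-m strategies
#'
#' A history strategy is a total, deterministic map from every history
#' profile of the last `m` rounds of an `n`-player game to the focal player's
#' next action. It is stored as a length-`2^(nm)` action vector indexed by
#' profile code (see [encode_profile()]).
#'
#' @param n player count (>= 2).
#' @param m memory length (>= 1).
#' @param actions an integer vector of 0/1 of length `2^(nm)` (entry `i+1` =
#'   action at profile code `i`), or a single string of `c`/`d` characters of
#'   that length.
#' @param name optional label.
#' @return an object of class `history_strategy`.
#' @examples
#' tft <- history_strategy(2, 1, "cdcd", name = "TFT")
#' prescribe(tft, history_profile(c("c", "d")))
#' @export
history_strategy <- function(n, m, actions, name = NULL) {
  if (is.character(actions)) actions <- action_to_int(actions)
  actions <- as.integer(actions)
  if (length(actions) != 2^(n * m)) {
    stop(sprintf("action table must have exactly 2^(%d*%d) = %d entries, got %d",
                 n, m, 2^(n * m), length(actions)), call. = FALSE)
  }
  if (!all(actions %in% c(0L, 1L))) {
    stop("action table entries must be 0 (c) or 1 (d)", call. = FALSE)
  }
  structure(list(n = as.integer(n), m = as.integer(m), actions = actions,
                 name = name),
            class = "history_strategy")
}

#' @export
print.history_strategy <- function(x, ...) {
  cat(sprintf("<history strategy%s> n=%d m=%d, %d entries\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n, x$m, length(x$actions)))
  if (length(x$actions) <= 64) {
    cat(" ", paste(action_to_char(x$actions), collapse = ""), "\n")
  }
  invisible(x)
}

#' @export
format.history_strategy <- function(x, ...) {
  paste(action_to_char(x$actions), collapse = "")
}

#' Look up the prescribed action at a profile
#'
#' @param strategy a [history_strategy()].
#' @param profile a [history_profile()] with matching `n` and `m`, or a raw
#'   profile code.
#' @return the action code (0 = c, 1 = d).
#' @export
prescribe <- function(strategy, profile) {
  stopifnot(inherits(strategy, "history_strategy"))
  if (inherits(profile, "history_profile")) {
    if (profile$n != strategy$n || profile$m != strategy$m) {
      stop("profile dimensions do not match the strategy", call. = FALSE)
    }
    profile <- encode_profile(profile)
  }
  strategy$actions[[profile + 1L]]
}

#' Permute the co-players of a strategy
#'
#' Relabels the co-players of an `n`-player strategy: the returned table's
#' entry at a profile equals the original entry at the profile whose
#' co-player rows have been permuted by `perm`. A strategy is symmetric
#' under co-player exchange iff it is a fixed point of every such
#' permutation.
#'
#' @param strategy a [history_strategy()].
#' @param perm a permutation of `1:(n-1)` (co-player indices; the focal
#'   player is fixed).
#' @return a [history_strategy()].
#' @export
permute_coplayers <- function(strategy, perm) {
  n <- strategy$n; m <- strategy$m
  perm <- as.integer(perm)
  if (length(perm) != n - 1L || !setequal(perm, seq_len(n - 1L))) {
    stop("perm must be a permutation of 1:(n-1)", call. = FALSE)
  }
  codes <- 0:(2^(n * m) - 1)
  fields <- profile_fields(codes, n, m)
  permuted <- fields
  permuted[, 1L + seq_len(n - 1L)] <- fields[, 1L + perm, drop = FALSE]
  src <- fields_to_codes(permuted, n, m)
  history_strategy(n, m, strategy$actions[src + 1L], name = strategy$name)
}

#' Seeded random strategy generator
#'
#' Draws a uniform random deterministic strategy table. The caller's RNG
#' state is left untouched.
#'
#' @inheritParams history_strategy
#' @param seed integer seed; identical seeds give identical tables.
#' @return a [history_strategy()].
#' @export
random_strategy <- function(n, m, seed) {
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
  history_strategy(n, m, sample(c(0L, 1L), 2^(n * m), replace = TRUE),
                   name = sprintf("random-%d-%d-seed%d", n, m, seed))
}
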