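#' History profiles and their integer codes
#'
#' A history profile records the last `m` actions of each of `n` players.
#' Player 1 is the focal player; the remaining rows are the co-players in the
#' focal player's viewing order. Within each row, actions are ordered oldest
#' to newest. A profile is labelled by the integer whose binary expansion is
#' the concatenation of the focal player's actions (oldest first, most
#' significant) followed by each co-player's actions in turn, with c = 0 and
#' d = 1. For example the two-player memory-two profile with focal history
#' `cd` and co-player history `cc` has code `0b0100 = 4`.
#'
#' @param actions an `n` x `m` integer matrix of 0/1 (rows = players, row 1 =
#'   focal; columns = lags, oldest first), or a character vector of `n`
#'   strings of length `m` over `{"c","d"}`.
#' @return an object of class `history_profile` with fields `n`, `m` and
#'   `actions` (integer matrix).
#' @examples
#' p <- history_profile(c("cd", "cc"))
#' encode_profile(p)            # 4
#' decode_profile(12, n = 2, m = 2)
#' @seealso [encode_profile()], [decode_profile()]
#' @export
history_profile <- function(actions) {
  if (is.character(actions)) {
    actions <- do.call(rbind, lapply(actions, action_to_int))
  }
  actions <- as.matrix(actions)
  storage.mode(actions) <- "integer"
  if (nrow(actions) < 2L || ncol(actions) < 1L) {
    stop("a history profile needs n >= 2 players and m >= 1 rounds",
         call. = FALSE)
  }
  if (!all(actions %in% c(0L, 1L))) {
    stop("profile entries must be 0 (c) or 1 (d)", call. = FALSE)
  }
  structure(list(n = nrow(actions), m = ncol(actions), actions = actions),
            class = "history_profile")
}

#' @export
print.history_profile <- function(x, ...) {
  labs <- apply(x$actions, 1L, function(r) paste(action_to_char(r), collapse = ""))
  cat(sprintf("<history profile n=%d m=%d> %s (code %d)\n",
              x$n, x$m, paste(labs, collapse = " "), encode_profile(x)))
  invisible(x)
}

#' Encode a history profile as an integer
#'
#' @param profile a [history_profile()].
#' @return an integer in `[0, 2^(nm))`.
#' @export
encode_profile <- function(profile) {
  stopifnot(inherits(profile, "history_profile"))
  bits <- as.vector(t(profile$actions))   # focal row first, oldest first
  code <- sum(bits * 2^(rev(seq_along(bits)) - 1L))
  if (length(bits) <= 30) as.integer(code) else code
}

#' Decode an integer profile code
#'
#' Inverse of [encode_profile()].
#'
#' @param code an integer in `[0, 2^(nm))`.
#' @param n number of players (>= 2).
#' @param m memory length (>= 1).
#' @return a [history_profile()].
#' @export
decode_profile <- function(code, n, m) {
  nm <- n * m
  if (length(code) != 1L || code < 0 || code >= 2^nm || code != floor(code)) {
    stop(sprintf("code must be an integer in [0, %d)", 2^nm), call. = FALSE)
  }
  bits <- as.integer(intToBits(code))[nm:1]
  history_profile(matrix(bits, nrow = n, ncol = m, byrow = TRUE))
}

#' Format a profile code as an action string
#'
#' Renders a profile code as the `n` length-`m` action words of its players,
#' e.g. code 4 for (n=2, m=2) becomes `"cdcc"`.
#'
#' @inheritParams decode_profile
#' @param sep separator between the players' words.
#' @return a character scalar.
#' @export
profile_label <- function(code, n, m, sep = "") {
  p <- decode_profile(code, n, m)
  paste(apply(p$actions, 1L, function(r) paste(action_to_char(r), collapse = "")),
        collapse = sep)
}

# Per-player m-bit fields of a vector of profile codes; column i = player i.
profile_fields <- function(codes, n, m) {
  out <- matrix(0L, nrow = length(codes), ncol = n)
  for (i in seq_len(n)) {
    out[, i] <- as.integer((codes %/% 2^(m * (n - i))) %% 2^m)
  }
  out
}

fields_to_codes <- function(fields, n, m) {
  codes <- numeric(nrow(fields))
  for (i in seq_len(n)) {
    codes <- codes + fields[, i] * 2^(m * (n - i))
  }
  codes
}

# Successor profile codes: drop each player's oldest action, append the
# realized actions. `acts` is a length-n 0/1 vector (focal first) or a
# matrix with one row per code.
shift_profile <- function(codes, n, m, acts) {
  fields <- profile_fields(codes, n, m)
  if (is.null(dim(acts))) acts <- matrix(acts, nrow = length(codes),
                                         ncol = n, byrow = TRUE)
  new_fields <- (fields * 2L) %% 2^m + acts
  fields_to_codes(new_fields, n, m)
}
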