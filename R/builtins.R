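#' Built-in strategy library
#'
#' Returns a named strategy of the iterated prisoner's dilemma (two-player)
#' repertoire. All are deterministic [history_strategy()] tables except
#' `CTFT` (contrite tit-for-tat), whose standing bookkeeping has no finite
#' memory-m table and is returned as a 4-state full-alphabet [automaton()].
#'
#' * `TFT` copies the co-player's last action (memory one).
#' * `ATFT` inverts the co-player's last action (memory one).
#' * `WSLS` (win-stay-lose-shift) cooperates iff both players' last actions
#'   coincide (memory one).
#' * `GRIM` cooperates only after mutual cooperation (memory-one trigger).
#' * `ALLC` / `ALLD` cooperate / defect unconditionally.
#' * `TF2T` (tit-for-two-tats) defects iff the co-player defected in both of
#'   the two previous rounds (memory two).
#' * `AON2` / `AON3` ("all-or-none") cooperate iff in each of the previous
#'   2 / 3 rounds all players chose one common action.
#' * `TFT-ATFT` is the 16-entry memory-two hybrid that plays TFT while its
#'   own record is consistent with TFT and anti-TFT otherwise; it satisfies
#'   all three success criteria in the two-player game.
#' * `CTFT` tracks a good/bad standing for each player: cooperation always
#'   earns good standing, and a defection earns bad standing unless it was
#'   prescribed (own standing good, co-player's bad). It defects iff its own
#'   standing is good and the co-player's is bad.
#'
#' `GRIM` and `AON3` are conveniences from the broader repertoire of the
#' field, included for completeness.
#'
#' @param name one of `"TFT"`, `"ATFT"`, `"TF2T"`, `"WSLS"`, `"GRIM"`,
#'   `"ALLC"`, `"ALLD"`, `"AON2"`, `"AON3"`, `"TFT-ATFT"`, `"CTFT"`.
#' @param n,m dimensions for `ALLC`/`ALLD`, which exist for every game size;
#'   ignored for the other names.
#' @return a [history_strategy()], or an [automaton()] for `"CTFT"`.
#' @examples
#' builtin_strategy("TFT")
#' prescribe(builtin_strategy("TFT-ATFT"), history_profile(c("cc", "cd")))
#' @export
builtin_strategy <- function(name, n = 2, m = 1) {
  codes <- function(nn, mm) 0:(2^(nn * mm) - 1)
  switch(name,
    "TFT"  = history_strategy(2, 1, "cdcd", name = name),
    "ATFT" = history_strategy(2, 1, "dcdc", name = name),
    "WSLS" = history_strategy(2, 1, "cddc", name = name),
    "GRIM" = history_strategy(2, 1, "cddd", name = name),
    "ALLC" = history_strategy(n, m, rep(0L, 2^(n * m)), name = name),
    "ALLD" = history_strategy(n, m, rep(1L, 2^(n * m)), name = name),
    "TF2T" = {
      b <- profile_fields(codes(2, 2), 2, 2)[, 2]
      history_strategy(2, 2, as.integer(b == 3L), name = name)
    },
    "AON2" = {
      f <- profile_fields(codes(2, 2), 2, 2)
      history_strategy(2, 2, as.integer(f[, 1] != f[, 2]), name = name)
    },
    "AON3" = {
      f <- profile_fields(codes(2, 3), 2, 3)
      history_strategy(2, 3, as.integer(f[, 1] != f[, 2]), name = name)
    },
    "TFT-ATFT" = history_strategy(2, 2, "cdcddccdcdccdccd", name = name),
    "CTFT" = ctft_automaton(),
    stop(sprintf("unknown strategy name '%s'", name), call. = FALSE)
  )
}

# Contrite TFT as a standing automaton. State label bits = (own standing,
# co-player standing), good = 0, bad = 1; e.g. state "01" means the focal
# player holds herself in good and the co-player in bad standing.
ctft_automaton <- function() {
  labs <- c("00", "01", "10", "11")
  action <- c(0L, 1L, 0L, 0L)            # defect only at good-self/bad-co
  trans <- matrix(0L, 4, 4)
  for (s in 1:4) {
    own_good <- substr(labs[s], 1, 1) == "0"
    co_good  <- substr(labs[s], 2, 2) == "0"
    for (k in 0:3) {
      a <- k %/% 2L; b <- k %% 2L        # realized (focal, co-player)
      # cooperation restores good standing; defection is forgiven only when
      # prescribed, i.e. committed from good standing against bad standing
      new_own <- if (a == 0L) 0L else if (own_good && !co_good) 0L else 1L
      new_co  <- if (b == 0L) 0L else if (co_good && !own_good) 0L else 1L
      trans[s, k + 1L] <- match(paste0(new_own, new_co), labs)
    }
  }
  automaton(n = 2, alphabet = "full", labels = 0:3, action = action,
            trans = trans, start = 1L, name = "CTFT", state_names = labs)
}
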