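# Enumeration of deterministic strategy spaces with defensibility-based
# pruning. Desk scale: two-player memory <= 2 and three-player memory-one
# spaces; the full three-person memory-two scan (> 10^12 tables) is cluster
# work and out of scope here.

#' Prunability of a partial action table
#'
#' A partial table (some profile codes assigned, the rest undetermined) is
#' prunable iff the subgraph induced by the determined entries already
#' contains a positive payoff-advantage cycle for some co-player: the cycle
#' weight criterion is monotone, so no completion of a prunable table is
#' defensible.
#'
#' @param partial a list with `n`, `m` and `actions` (length `2^(nm)`
#'   integer vector of 0/1 with `NA` at undetermined codes).
#' @return `TRUE` if every completion is non-defensible.
#' @export
prune_partial <- function(partial) {
  n <- partial$n; m <- partial$m
  acts <- partial$actions
  stopifnot(length(acts) == 2^(n * m))
  det <- which(!is.na(acts))
  if (!length(det)) return(FALSE)
  codes <- 0:(2^(n * m) - 1)
  n_co <- 2^(n - 1L)
  succ <- matrix(1L, length(codes), n_co)
  w_base <- ifelse(is.na(acts), -Inf, -acts)   # -[a_focal = d]; -Inf cuts edges
  weight <- matrix(-Inf, length(codes), n_co)
  for (k in 0:(n_co - 1)) {
    bits <- as.integer(intToBits(k))[(n - 1L):1]
    a <- ifelse(is.na(acts), 0L, acts)
    s <- shift_profile(codes, n, m, cbind(a, matrix(bits, length(codes),
                                                    n - 1L, byrow = TRUE))) + 1L
    succ[, k + 1L] <- s
    # an edge is usable only if both endpoints are determined
    weight[, k + 1L] <- w_base + ifelse(is.na(acts[s]), -Inf, 0)
  }
  for (j in seq_len(n - 1L)) {
    co_d <- vapply(0:(n_co - 1), function(k)
      as.integer(intToBits(k))[(n - 1L):1][j], integer(1))
    wj <- weight + matrix(co_d, length(codes), n_co, byrow = TRUE)
    if (!is.null(positive_cycle(succ, wj))) return(TRUE)
  }
  FALSE
}

# Vectorized defensibility over many two-player tables at once (max-plus
# Bellman-Ford run in parallel across tables).
batch_defensible_2p <- function(tables, m) {
  nn <- 2^(2 * m)
  stopifnot(ncol(tables) == nn)
  codes <- 0:(nn - 1)
  af <- codes %/% 2^m; bf <- codes %% 2^m
  half <- 2^m
  # destination = s_base + half * T(node)
  s_base <- matrix(0L, nn, 2)
  for (b in 0:1) {
    s_base[, b + 1L] <- ((af * 2L) %% half) * half + (bf * 2L) %% half + b + 1L
  }
  nt <- nrow(tables)
  dist <- matrix(0, nt, nn)
  has_cycle <- rep(FALSE, nt)
  for (it in seq_len(nn + 1L)) {
    old <- dist
    for (u in seq_len(nn)) {
      Tu <- tables[, u]
      for (b in 0:1) {
        cand <- dist[, u] + b - Tu
        for (t in 0:1) {
          rows <- Tu == t
          if (!any(rows)) next
          v <- s_base[u, b + 1L] + half * t
          dist[rows, v] <- pmax(dist[rows, v], cand[rows])
        }
      }
    }
    if (it == nn + 1L) has_cycle <- rowSums(dist != old) > 0
  }
  !has_cycle
}

#' Enumerate deterministic strategies with criteria filters
#'
#' Scans the full space of `2^(2^(nm))` action tables (so only small `(n,m)`
#' are feasible), keeping the tables that pass all requested filters. With
#' `prune = TRUE` and the `"defensible"` filter, the scan is a depth-first
#' search over partial tables (profile codes assigned in ascending order)
#' with incremental positive-cycle pruning; pruned and unpruned scans return
#' identical survivor sets.
#'
#' @param n,m game dimensions; `2^(nm)` must be at most 16.
#' @param filters subset of `"defensible"`, `"distinguishable"`,
#'   `"partially_efficient"`, `"efficient"`.
#' @param prune use defensibility pruning during the scan.
#' @param e_grid,rho criteria parameters (see [check_efficiency()]).
#' @return a list with `count`, `tables` (character action strings, in
#'   ascending table order) and `verdicts` (a data.frame with one row per
#'   survivor: table string, per-filter verdicts, minimized state count).
#' @export
enumerate_strategies <- function(n, m, filters = character(), prune = TRUE,
                                 e_grid = c(1e-2, 1e-3, 1e-4), rho = NULL) {
  nn <- 2^(n * m)
  if (nn > 16) stop("strategy space too large for a desk-scale scan",
                    call. = FALSE)
  if (is.null(rho)) rho <- 1 + (n - 1) / 2
  known <- c("defensible", "distinguishable", "partially_efficient",
             "efficient")
  stopifnot(all(filters %in% known))

  if ("defensible" %in% filters && prune) {
    survivors <- defensible_dfs(n, m)
  } else {
    tabs <- all_tables(nn)
    if ("defensible" %in% filters) {
      keep <- if (n == 2) batch_defensible_2p(tabs, m) else
        vapply(seq_len(nrow(tabs)), function(i)
          check_defensibility(history_strategy(n, m, tabs[i, ]))$defensible,
          logical(1))
      survivors <- tabs[keep, , drop = FALSE]
    } else {
      survivors <- tabs
    }
  }
  # remaining filters need the stationary machinery, table by table
  rest <- setdiff(filters, "defensible")
  keep <- rep(TRUE, nrow(survivors))
  eff_cache <- vector("list", nrow(survivors))
  if (length(rest) && nrow(survivors)) {
    for (i in seq_len(nrow(survivors))) {
      s <- history_strategy(n, m, survivors[i, ])
      if (any(c("efficient", "partially_efficient") %in% rest)) {
        eff <- check_efficiency(s, e_grid, rho)
        eff_cache[[i]] <- eff
        if ("efficient" %in% rest && !eff$efficient) keep[i] <- FALSE
        if ("partially_efficient" %in% rest && !eff$partially_efficient)
          keep[i] <- FALSE
      }
      if (keep[i] && "distinguishable" %in% rest) {
        if (!check_distinguishability(s, e_grid, rho)$distinguishable)
          keep[i] <- FALSE
      }
    }
  }
  survivors <- survivors[keep, , drop = FALSE]
  tables <- apply(survivors, 1L, function(r)
    paste(action_to_char(r), collapse = ""))
  verdicts <- NULL
  if (nrow(survivors)) {
    states <- vapply(seq_len(nrow(survivors)), function(i) {
      s <- history_strategy(n, m, survivors[i, ])
      n_states(minimize(build_transition_graph(s)))
    }, numeric(1))
    verdicts <- data.frame(table = tables, states = states)
    for (f in filters) verdicts[[f]] <- TRUE
  }
  list(count = nrow(survivors), tables = tables, verdicts = verdicts)
}

all_tables <- function(nn) {
  nt <- 2^nn
  tabs <- matrix(0L, nt, nn)
  for (j in seq_len(nn)) {
    # table index runs 0..2^nn - 1; profile-0 action is the most significant
    tabs[, j] <- as.integer(((0:(nt - 1)) %/% 2^(nn - j)) %% 2L)
  }
  tabs
}

# Depth-first scan over partial tables with incremental positive-cycle
# pruning; returns the defensible tables in ascending table order.
defensible_dfs <- function(n, m) {
  nn <- 2^(n * m)
  acts <- rep(NA_integer_, nn)
  out <- list()
  recurse <- function(depth) {
    if (depth > nn) {
      out[[length(out) + 1L]] <<- acts
      return(invisible())
    }
    for (a in 0:1) {
      acts[depth] <<- a
      if (!prune_partial(list(n = n, m = m, actions = acts))) {
        recurse(depth + 1L)
      }
      acts[depth] <<- NA_integer_
    }
  }
  recurse(1L)
  if (!length(out)) return(matrix(0L, 0, nn))
  do.call(rbind, out)
}
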