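#' Read and write plain-text strategy files
#'
#' The `.str` format: line 1 holds `"<n> <m>"`, line 2 the `2^(nm)`-character
#' action string over `{c,d}` (character `i` = action at profile code
#' `i - 1`). Lines starting with `#` are comments; a `# name:` comment sets
#' the strategy name. Round-trips are byte-exact.
#'
#' @param path file path.
#' @return [read_strategy()] returns a [history_strategy()];
#'   [write_strategy()] returns `path` invisibly.
#' @export
read_strategy <- function(path) {
  lines <- readLines(path)
  name <- NULL
  is_comment <- grepl("^\\s*#", lines)
  for (cm in lines[is_comment]) {
    nm <- sub("^\\s*#\\s*name:\\s*", "", cm)
    if (nm != cm) name <- trimws(nm)
  }
  lines <- trimws(lines[!is_comment & nzchar(trimws(lines))])
  if (length(lines) < 2) {
    stop(sprintf("%s: expected a header line and a body line", path),
         call. = FALSE)
  }
  header <- suppressWarnings(as.integer(strsplit(lines[1], "\\s+")[[1]]))
  if (length(header) != 2 || anyNA(header)) {
    stop(sprintf("%s: header must be '<n> <m>'", path), call. = FALSE)
  }
  n <- header[1]; m <- header[2]
  body <- lines[2]
  if (nchar(body) != 2^(n * m)) {
    stop(sprintf("%s: body has %d characters, expected 2^(%d*%d) = %d",
                 path, nchar(body), n, m, 2^(n * m)), call. = FALSE)
  }
  chars <- strsplit(body, "")[[1]]
  bad <- which(!chars %in% c("c", "d"))
  if (length(bad)) {
    stop(sprintf("%s: invalid action character '%s' at body position %d",
                 path, chars[bad[1]], bad[1]), call. = FALSE)
  }
  history_strategy(n, m, body, name = name)
}

#' @rdname read_strategy
#' @param strategy a [history_strategy()].
#' @export
write_strategy <- function(strategy, path) {
  stopifnot(inherits(strategy, "history_strategy"))
  lines <- character(0)
  if (!is.null(strategy$name)) lines <- sprintf("# name: %s", strategy$name)
  lines <- c(lines, sprintf("%d %d", strategy$n, strategy$m),
             paste(action_to_char(strategy$actions), collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' Export an automaton as Graphviz DOT text
#'
#' One node per state, labelled by the canonical state label; fill colour
#' encodes the prescribed action (blue = cooperation, red = defection); edge
#' labels are the input action tuples.
#'
#' @param aut an [automaton()].
#' @param path optional file to write to.
#' @return the DOT text as a character vector (invisibly when `path` is
#'   given).
#' @export
export_dot <- function(aut, path = NULL) {
  stopifnot(inherits(aut, "automaton"))
  labs <- if (is.null(aut$state_names)) as.character(aut$labels) else
    aut$state_names
  ins <- input_labels(aut)
  lines <- c("digraph automaton {",
             "  rankdir=LR;",
             "  node [style=filled, fontcolor=white];")
  for (s in seq_len(n_states(aut))) {
    lines <- c(lines, sprintf(
      "  \"%s\" [fillcolor=%s];", labs[s],
      if (aut$action[s] == 0L) "blue" else "red"))
  }
  for (s in seq_len(n_states(aut))) {
    for (k in seq_along(ins)) {
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                                labs[s], labs[aut$trans[s, k]], ins[k]))
    }
  }
  lines <- c(lines, "}")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse DOT text produced by [export_dot()]
#'
#' Used to round-trip-check exports: recovers the node set, fill colours and
#' labelled edges.
#'
#' @param lines DOT text as a character vector.
#' @return a list with `nodes` (data.frame: label, color) and `edges`
#'   (data.frame: from, to, input).
#' @export
parse_dot <- function(lines) {
  node_re <- "^\\s*\"([^\"]+)\"\\s*\\[fillcolor=(\\w+)\\];$"
  edge_re <- "^\\s*\"([^\"]+)\"\\s*->\\s*\"([^\"]+)\"\\s*\\[label=\"([^\"]+)\"\\];$"
  nodes <- lines[grepl(node_re, lines)]
  edges <- lines[grepl(edge_re, lines)]
  list(
    nodes = data.frame(label = sub(node_re, "\\1", nodes),
                       color = sub(node_re, "\\2", nodes)),
    edges = data.frame(from = sub(edge_re, "\\1", edges),
                       to = sub(edge_re, "\\2", edges),
                       input = sub(edge_re, "\\3", edges)))
}
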