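#' Action coding
#'
#' Actions in the social-dilemma games handled by this package are binary:
#' cooperation (`"c"`, code 0) and defection (`"d"`, code 1). All internal
#' computation uses the integer codes; these helpers convert between the two
#' representations.
#'
#' @param x an integer vector of action codes (0/1) or a character vector over
#'   `{"c","d"}` (as a single string or as individual characters).
#' @return `action_to_char()` returns a character vector of `"c"`/`"d"`;
#'   `action_to_int()` returns an integer vector of 0/1.
#' @examples
#' action_to_char(c(0L, 1L, 0L))
#' action_to_int("cdc")
#' @export
action_to_char <- function(x) {
  stopifnot(all(x %in% c(0L, 1L)))
  c("c", "d")[x + 1L]
}

#' @rdname action_to_char
#' @export
action_to_int <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1L]]
  if (!all(x %in% c("c", "d"))) {
    stop("actions must be characters 'c' or 'd'", call. = FALSE)
  }
  as.integer(x == "d")
}
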