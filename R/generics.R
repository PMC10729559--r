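#' Turn a result object into a tidy tibble
#'
#' Broom-style generic: each method returns the object's main per-row
#' result (pairs, scores, rankings) as a tibble.
#'
#' @param x A result object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a result object
#'
#' Broom-style generic: each method returns a one-row tibble of headline
#' numbers.
#'
#' @param x A result object.
#' @param ... Passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")
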