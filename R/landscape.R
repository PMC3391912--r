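#' Generate a random tunneling landscape
#'
#' Every lattice cell receives an independent uniform value on \[0, 1\]
#' interpreted as the transition probability \code{P_trans}: the ease with
#' which an active termite cell can tunnel into that site. The landscape is
#' drawn once per simulation and never modified afterwards. Values come from
#' the current R random number stream.
#'
#' @param L Lattice side length (cells).
#' @return An \code{L x L} numeric matrix of class \code{landscape} with
#'   entries in \[0, 1\].
#' @export
#' @examples
#' set.seed(1)
#' land <- generate_landscape(50)
#' range(land)
generate_landscape <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1)
    stop("`L` must be a single integer >= 1", call. = FALSE)
  L <- as.integer(L)
  structure(matrix(runif(L * L), L, L), class = c("landscape", "matrix"))
}

.check_landscape <- function(land, L = NULL) {
  if (!is.matrix(land) || !is.numeric(land) || nrow(land) != ncol(land))
    stop("expected a square numeric landscape matrix", call. = FALSE)
  if (!is.null(L) && nrow(land) != L)
    stop("landscape size does not match grid size", call. = FALSE)
  invisible(land)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d, P_trans in [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}
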