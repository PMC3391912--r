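# Cell-state coding shared by every grid operation. Kept as plain integers so
# state/label layers can be written and re-read as text matrices.
.EMPTY <- 0L
.ACTIVE <- 1L
.INACTIVE <- 2L

#' Cell state codes
#'
#' Integer codes used in the \code{state} layer of a cell grid:
#' \code{empty = 0}, \code{active = 1} (a live tunneling front able to extend
#' the territory), \code{inactive = 2} (occupied but no longer growing).
#'
#' @return Named integer vector of length 3.
#' @export
#' @examples
#' cell_states()
cell_states <- function() {
  c(empty = .EMPTY, active = .ACTIVE, inactive = .INACTIVE)
}

# Moore-neighbour lookup tables are pure functions of L; cache per side length.
# Row i of the table holds the 8 linear indices of cell i's neighbours, NA for
# off-lattice positions (the lattice is non-periodic: borders have fewer
# neighbours, which never count as empty nor as inactive).
.nbr_cache <- new.env(parent = emptyenv())

.nbr_table <- function(L) {
  key <- as.character(L)
  if (!is.null(.nbr_cache[[key]])) return(.nbr_cache[[key]])
  off <- cbind(
    dr = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
    dc = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  )
  rows <- rep(seq_len(L), L)
  cols <- rep(seq_len(L), each = L)
  nb <- matrix(NA_integer_, L * L, 8L)
  for (j in seq_len(8L)) {
    r <- rows + off[j, "dr"]
    ch <- cols + off[j, "dc"]
    ok <- r >= 1L & r <= L & ch >= 1L & ch <= L
    v <- rep(NA_integer_, L * L)
    v[ok] <- (ch[ok] - 1L) * L + r[ok]
    nb[, j] <- v
  }
  .nbr_cache[[key]] <- nb
  nb
}

.coord_to_lin <- function(coord, L) (coord[2L] - 1L) * L + coord[1L]
.lin_to_coord <- function(lin, L) cbind(row = (lin - 1L) %% L + 1L,
                                        col = (lin - 1L) %/% L + 1L)

#' Create an empty cell grid
#'
#' @param L Lattice side length (cells).
#' @return An object of class \code{cell_grid}: a list with integer matrices
#'   \code{state} and \code{label} (both \code{L x L}), the side length
#'   \code{L}, and \code{seed_pos}, an \code{N x 2} matrix of founding-cell
#'   coordinates (zero rows until \code{\link{place_seeds}} is called).
#' @seealso \code{\link{place_seeds}}, \code{\link{summer_step}}
#' @export
#' @examples
#' g <- new_cell_grid(10)
#' table(g$state)
new_cell_grid <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1)
    stop("`L` must be a single integer >= 1", call. = FALSE)
  L <- as.integer(L)
  structure(
    list(
      L = L,
      state = matrix(.EMPTY, L, L),
      label = matrix(0L, L, L),
      seed_pos = matrix(integer(0), 0L, 2L,
                        dimnames = list(NULL, c("row", "col")))
    ),
    class = "cell_grid"
  )
}

.check_grid <- function(grid) {
  if (!inherits(grid, "cell_grid"))
    stop("expected a `cell_grid` object", call. = FALSE)
  invisible(grid)
}

#' Place territory seeds on an empty grid
#'
#' Introduces \code{N} founding pairs as active cells at distinct positions
#' sampled uniformly from the lattice, labelled \code{1..N}. Positions are
#' drawn from the current R random number stream.
#'
#' @param grid An all-empty \code{cell_grid}.
#' @param N Number of founding pairs (territory seeds), \code{1 <= N <= L^2}.
#' @return The grid with \code{N} active seed cells and \code{seed_pos} filled.
#' @export
#' @examples
#' set.seed(1)
#' g <- place_seeds(new_cell_grid(20), 5)
#' sum(g$state == cell_states()["active"])
place_seeds <- function(grid, N) {
  .check_grid(grid)
  L <- grid$L
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 || N > L^2)
    stop("`N` must be a single integer in [1, L^2]", call. = FALSE)
  if (any(grid$state != .EMPTY))
    stop("`place_seeds()` requires an all-empty grid", call. = FALSE)
  N <- as.integer(N)
  pos <- sample.int(L * L, N)
  grid$state[pos] <- .ACTIVE
  grid$label[pos] <- seq_len(N)
  grid$seed_pos <- .lin_to_coord(pos, L)
  grid
}

#' @export
print.cell_grid <- function(x, ...) {
  n_seed <- nrow(x$seed_pos)
  cat(sprintf("<cell_grid> %d x %d lattice, %d seed(s)\n", x$L, x$L, n_seed))
  cat(sprintf("  empty: %d  active: %d  inactive: %d\n",
              sum(x$state == .EMPTY), sum(x$state == .ACTIVE),
              sum(x$state == .INACTIVE)))
  invisible(x)
}

# Euclidean distance of territory member cells from their seed, on integer
# cell-centre coordinates.
.dist_from_seed <- function(lin, seed_rc, L) {
  rc <- .lin_to_coord(lin, L)
  sqrt((rc[, 1L] - seed_rc[1L])^2 + (rc[, 2L] - seed_rc[2L])^2)
}
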