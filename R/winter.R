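# Winter rules: the whole season is resolved in a single step (no cell-cell
# interaction while the colony is dormant). Each territory contracts towards
# its founding cell, then a few distal cells are reactivated to start the
# next summer's growth from the periphery.

#' Winter shrinkage of all territories
#'
#' Independently for each territory, removes cells in order of decreasing
#' Euclidean distance from the founding (seed) cell until exactly
#' \code{max(1, round(sigma/100 * size))} cells remain (half-up rounding;
#' distance ties broken uniformly at random). The seed cell, being nearest to
#' itself, always survives. All surviving cells are set inactive: growth must
#' be re-initiated by \code{\link{reactivate}}.
#'
#' @param grid A \code{cell_grid}.
#' @param sigma Percentage of each territory's cells retained, in (0, 100].
#'   This is the climate variable sigma: warmer winters mean milder
#'   contraction (field estimate for the Formosan subterranean termite is
#'   about 20).
#' @return The contracted grid (all termite cells inactive).
#' @export
winter_shrink <- function(grid, sigma) {
  .check_grid(grid)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) ||
      sigma <= 0 || sigma > 100)
    stop("`sigma` must be a single value in (0, 100]", call. = FALSE)
  L <- grid$L
  occ <- which(grid$state != .EMPTY)
  for (lb in seq_len(nrow(grid$seed_pos))) {
    mem <- occ[grid$label[occ] == lb]
    sz <- length(mem)
    if (sz == 0L) next
    keep <- max(1L, as.integer(floor(sigma / 100 * sz + 0.5)))
    if (keep < sz) {
      d <- .dist_from_seed(mem, grid$seed_pos[lb, ], L)
      o <- order(d, runif(sz))       # nearest first; random tie-break
      drop <- mem[o][(keep + 1L):sz]
      grid$state[drop] <- .EMPTY
      grid$label[drop] <- 0L
      mem <- mem[o][seq_len(keep)]
    }
    grid$state[mem] <- .INACTIVE
  }
  grid
}

#' Reactivate distal cells after winter shrinkage
#'
#' Per territory, samples \code{min(n_react, size)} member cells without
#' replacement with probability proportional to their Euclidean distance from
#' the seed cell and sets them active. The distal weighting reflects that new
#' tunnel growth starts at the colony's periphery. The seed itself carries
#' weight 0 and is only reactivated when needed to reach the requested count
#' (always, when it is the sole surviving cell).
#'
#' @param grid A \code{cell_grid} containing no active cells (the state after
#'   \code{\link{winter_shrink}}).
#' @param n_react Number of cells to reactivate per territory.
#' @return The grid with reactivated growth fronts.
#' @export
reactivate <- function(grid, n_react) {
  .check_grid(grid)
  if (!is.numeric(n_react) || length(n_react) != 1L || is.na(n_react) ||
      n_react < 1)
    stop("`n_react` must be a single integer >= 1", call. = FALSE)
  if (any(grid$state == .ACTIVE))
    stop("`reactivate()` expects a grid with no active cells", call. = FALSE)
  n_react <- as.integer(n_react)
  L <- grid$L
  occ <- which(grid$state != .EMPTY)
  for (lb in seq_len(nrow(grid$seed_pos))) {
    mem <- occ[grid$label[occ] == lb]
    sz <- length(mem)
    if (sz == 0L) next
    k <- min(n_react, sz)
    if (sz == 1L) {
      act <- mem
    } else {
      w <- .dist_from_seed(mem, grid$seed_pos[lb, ], L)
      pos <- which(w > 0)
      if (k >= length(pos)) {
        # take every positive-weight cell, then fill from weight-0 cells
        # (the seed) to honour the exact count
        zero <- setdiff(seq_len(sz), pos)
        act <- c(mem[pos], mem[zero][seq_len(k - length(pos))])
      } else {
        act <- mem[sample(pos, k, prob = w[pos])]
      }
    }
    grid$state[act] <- .ACTIVE
  }
  grid
}
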