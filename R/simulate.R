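#' Run one full seasonal simulation
#'
#' Draws a fresh landscape and seed placement, then cycles
#' summer growth (\code{T_summer} synchronous rounds), winter shrinkage (one
#' step) and distal reactivation, until the run is steady or \code{n_cycles}
#' cycles have elapsed. The census of territory sizes is taken at the end of
#' each summer; the run is declared steady when the relative change of the
#' total termite-cell count between consecutive post-summer censuses drops
#' below \code{steady_tol}. The returned grid is the post-summer state of the
#' last cycle, i.e. the fully grown seasonal pattern.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{territory_sim}: list with
#'   \code{final_grid} (a \code{cell_grid}), \code{landscape},
#'   \code{size_history} (a \code{cycles_run x N} integer matrix of
#'   post-summer territory sizes), \code{cycles_run}, \code{steady} (logical)
#'   and \code{config}.
#' @export
#' @examples
#' res <- run_simulation(sim_config(L = 40, N = 5, T_summer = 5, sigma = 30,
#'                                  n_cycles = 3, rng_seed = 1))
#' res$size_history
run_simulation <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  land <- generate_landscape(config$L)
  grid <- place_seeds(new_cell_grid(config$L), config$N)

  hist <- matrix(0L, 0L, config$N)
  steady <- FALSE
  cycles <- 0L
  prev_total <- NA_real_
  for (cyc in seq_len(config$n_cycles)) {
    grid <- run_summer(grid, land, config$T_summer)
    sizes <- territory_sizes(grid)
    hist <- rbind(hist, sizes)
    cycles <- cyc
    total <- sum(sizes)
    if (!is.na(prev_total) && prev_total > 0 &&
        abs(total - prev_total) / prev_total < config$steady_tol) {
      steady <- TRUE
    }
    prev_total <- total
    if (steady || cyc == config$n_cycles) break
    grid <- winter_shrink(grid, config$sigma)
    grid <- reactivate(grid, config$n_react)
  }
  rownames(hist) <- NULL

  structure(
    list(final_grid = grid, landscape = land, size_history = hist,
         cycles_run = cycles, steady = steady, config = config),
    class = "territory_sim"
  )
}

#' @export
print.territory_sim <- function(x, ...) {
  cat(sprintf("<territory_sim> %d cycle(s)%s, %d territories, %d termite cells\n",
              x$cycles_run, if (x$steady) " (steady)" else "",
              x$config$N, sum(x$final_grid$state != .EMPTY)))
  invisible(x)
}
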