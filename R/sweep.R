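# Factorial sweep over the (T, sigma, N) climate grid with independent
# replicates. Every replicate receives its own substream seed derived by a
# deterministic integer hash of (master seed, N, T, sigma, replicate), so
# results do not depend on execution order and single combinations can be
# recomputed in isolation.

# 32-bit-safe polynomial hash onto [1, 2^31 - 2]; sigma may be fractional so
# it enters scaled by 1000.
.substream_seed <- function(master, N, T, sigma, rep) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(master) %% m)
  for (v in c(N, T, round(sigma * 1000), rep)) {
    h <- (h * 69621 + as.numeric(v) + 1) %% m
  }
  as.integer(h) + 1L
}

#' Sweep specification
#'
#' The full factorial experiment: every combination of \code{T_values},
#' \code{sigma_values} and \code{N_values} is simulated
#' \code{n_replicates} times; replicate size vectors are aggregated into a
#' rank-size distribution whose two-segment slope is fitted per combination.
#'
#' @param T_values Summer durations (default \code{seq(10, 50, by = 5)}).
#' @param sigma_values Winter retention percentages (default
#'   \code{seq(10, 50, by = 5)}).
#' @param N_values Founding-pair counts (default \code{c(30, 50, 70, 90)}).
#' @param n_replicates Independent runs per combination (default 50).
#' @param base_config \code{\link{sim_config}} supplying the remaining
#'   parameters (\code{L}, \code{n_react}, \code{n_cycles},
#'   \code{steady_tol}); its \code{N}, \code{T_summer}, \code{sigma} and
#'   \code{rng_seed} are overridden per combination.
#' @param rng_seed Master seed of the sweep (default 1).
#' @return A validated list of class \code{sweep_spec}.
#' @export
sweep_spec <- function(T_values = seq(10L, 50L, by = 5L),
                       sigma_values = seq(10L, 50L, by = 5L),
                       N_values = c(30L, 50L, 70L, 90L),
                       n_replicates = 50L,
                       base_config = sim_config(),
                       rng_seed = 1L) {
  if (length(T_values) == 0L || length(sigma_values) == 0L ||
      length(N_values) == 0L)
    stop("all value lists must be non-empty", call. = FALSE)
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  validate_sim_config(base_config)
  if (any(T_values < 0) || any(sigma_values <= 0) || any(sigma_values > 100) ||
      any(N_values < 1))
    stop("invalid sweep values", call. = FALSE)
  structure(
    list(T_values = as.integer(T_values),
         sigma_values = as.numeric(sigma_values),
         N_values = as.integer(N_values),
         n_replicates = as.integer(n_replicates),
         base_config = base_config,
         rng_seed = as.integer(rng_seed)),
    class = "sweep_spec"
  )
}

#' Run a parameter sweep
#'
#' For every (N, T, sigma) combination, runs \code{n_replicates} independent
#' simulations on substream seeds, builds the replicate-averaged rank-size
#' distribution and fits its two-segment semi-log slope. Rows are emitted in
#' deterministic (N, T, sigma) order.
#'
#' @param spec A \code{\link{sweep_spec}}.
#' @param mode \code{"averaged"} (default) fits the slope of the
#'   replicate-averaged distribution; \code{"per_replicate"} additionally
#'   reports the mean of per-replicate slope fits in column
#'   \code{m_front_mean_rep}.
#' @param verbose Print one progress line per combination.
#' @return Data frame of class \code{sweep_result} with columns \code{N},
#'   \code{T}, \code{sigma}, \code{n_replicates}, \code{breakpoint},
#'   \code{m_front}, \code{m_rear}, \code{mean_total_size}.
#' @export
run_sweep <- function(spec, mode = c("averaged", "per_replicate"),
                      verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  mode <- match.arg(mode)
  combos <- expand.grid(sigma = spec$sigma_values, T = spec$T_values,
                        N = spec$N_values, KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$N, combos$T, combos$sigma), , drop = FALSE]
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    N <- combos$N[i]; Tv <- combos$T[i]; sg <- combos$sigma[i]
    sizes <- vector("list", spec$n_replicates)
    m_rep <- numeric(spec$n_replicates)
    tot <- numeric(spec$n_replicates)
    for (r in seq_len(spec$n_replicates)) {
      cfg <- spec$base_config
      cfg$N <- N; cfg$T_summer <- Tv; cfg$sigma <- sg
      cfg$rng_seed <- .substream_seed(spec$rng_seed, N, Tv, sg, r)
      res <- run_simulation(validate_sim_config(cfg))
      sizes[[r]] <- territory_sizes(res$final_grid)
      tot[r] <- sum(sizes[[r]])
      if (mode == "per_replicate")
        m_rep[r] <- fit_two_segment_slope(
          sort(sizes[[r]], decreasing = TRUE))$m_front
    }
    fit <- fit_two_segment_slope(rank_size_distribution(sizes))
    row <- data.frame(N = N, T = Tv, sigma = sg,
                      n_replicates = spec$n_replicates,
                      breakpoint = fit$breakpoint, m_front = fit$m_front,
                      m_rear = fit$m_rear, mean_total_size = mean(tot))
    if (mode == "per_replicate") row$m_front_mean_rep <- mean(m_rep)
    rows[[i]] <- row
    if (verbose)
      message(sprintf("N=%d T=%d sigma=%g: m_front=%.4f", N, Tv, sg,
                      fit$m_front))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", class(out))
  out
}

#' Records for SOM training from a sweep result
#'
#' @param result A \code{\link{run_sweep}} result (single \code{N}).
#' @return Data frame with columns \code{T}, \code{sigma}, \code{m} ready for
#'   \code{\link{normalize_inputs}}.
#' @export
sweep_som_records <- function(result) {
  stopifnot(all(c("T", "sigma", "m_front") %in% names(result)))
  data.frame(T = result$T, sigma = result$sigma, m = result$m_front)
}
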