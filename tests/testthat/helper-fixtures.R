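# Fixture builders shared across the suite. All grids are built in code.

# constant-P landscape of side L
flat_landscape <- function(L, p = 1) {
  structure(matrix(p, L, L), class = c("landscape", "matrix"))
}

# grid with one active seed at (row, col), label 1
single_seed_grid <- function(L, row = ceiling(L / 2), col = ceiling(L / 2)) {
  g <- new_cell_grid(L)
  g$state[row, col] <- cell_states()[["active"]]
  g$label[row, col] <- 1L
  g$seed_pos <- cbind(row = row, col = col)
  g
}

# grid with explicit member cells for one or more territories;
# members: list of n x 2 coordinate matrices, first row = seed
multi_territory_grid <- function(L, members, state_code = "inactive") {
  g <- new_cell_grid(L)
  code <- cell_states()[[state_code]]
  seeds <- matrix(0L, length(members), 2L,
                  dimnames = list(NULL, c("row", "col")))
  for (lb in seq_along(members)) {
    m <- matrix(as.integer(members[[lb]]), ncol = 2L)
    lin <- (m[, 2L] - 1L) * L + m[, 1L]
    g$state[lin] <- code
    g$label[lin] <- lb
    seeds[lb, ] <- m[1L, ]
  }
  g$seed_pos <- seeds
  g
}

# grow one territory on a permissive landscape until it holds >= n_min cells
grow_single_territory <- function(L = 40, n_min = 100, seed = 1) {
  set.seed(seed)
  g <- single_seed_grid(L)
  land <- flat_landscape(L, 0.9)
  while (sum(g$state != 0L) < n_min) g <- summer_step(g, land)
  g
}

# exact two-segment log-linear rank-size curve
two_segment_sizes <- function(N = 30, b = 10, s1 = 0.2, s2 = 0.01,
                              a1 = 5, noise_sd = 0) {
  x <- seq_len(N)
  # drop the rear line below the front one at the breakpoint so that rank b
  # lies on the front line only, making the breakpoint unambiguous
  a2 <- a1 - s1 * b + s2 * b - 0.3
  ly <- ifelse(x <= b, a1 - s1 * x, a2 - s2 * x)
  exp(ly + stats::rnorm(N, 0, noise_sd))
}

# brute-force two-segment fit used as the independent oracle: plain lm()
# over every admissible breakpoint
oracle_two_segment <- function(y) {
  N <- length(y)
  ly <- log(y)
  x <- seq_len(N)
  best <- NULL
  for (b in 2:(N - 2)) {
    f <- stats::lm(ly[1:b] ~ x[1:b])
    r <- stats::lm(ly[(b + 1):N] ~ x[(b + 1):N])
    sse <- sum(stats::residuals(f)^2) + sum(stats::residuals(r)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(breakpoint = b, m_front = abs(unname(stats::coef(f)[2])),
                   sse = sse)
  }
  best
}
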