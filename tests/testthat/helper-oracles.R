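# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive results by the most naive route available
# (cell-by-cell scans, step-by-step R walks) so they share no code with the
# implementation they check.

# Brute-force nearest-seed assignment: plain loops, squared Euclidean
# distance on cell indices, lowest field_id wins ties.
brute_force_assign <- function(seeds, width, height) {
  out <- matrix(NA_integer_, height, width)
  for (y in 0:(height - 1)) {
    for (x in 0:(width - 1)) {
      d2 <- (x - seeds$x)^2 + (y - seeds$y)^2
      out[y + 1, x + 1] <- seeds$field_id[which.min(d2)]  # first min = lowest id
    }
  }
  out
}

# Build an hw_landscape directly from a field matrix (habitat derived) or
# from explicit field + habitat matrices.
make_landscape <- function(field, habitat = NULL, seeds = NULL) {
  if (is.null(habitat)) habitat <- classify_hedgerows(field)
  hedgewalk:::new_landscape(ncol(field), nrow(field), seeds, field, habitat)
}

# A landscape whose every cell is wild (single field fully converted to
# set-aside), handy for unconstrained-walk oracles.
uniform_wild_landscape <- function(width, height) {
  land <- make_landscape(matrix(0L, height, width))
  land$habitat[] <- 1L
  land
}

uniform_crop_landscape <- function(width, height) {
  make_landscape(matrix(0L, height, width))
}

# Step-by-step R walk that mirrors cpp_simulate_walk's RNG consumption
# exactly (one uniform for the initial heading when not supplied, one per
# timestep), built on the exported single-step functions.
r_reference_walk <- function(landscape, nest, params, T,
                             init_heading = NULL) {
  heading <- if (is.null(init_heading)) min(floor(4 * runif(1)), 3)
             else init_heading
  state <- list(x = nest[[1]], y = nest[[2]], heading = as.integer(heading))
  hab <- landscape$habitat
  max_d2 <- 0
  n_switch <- 0L
  n_wild <- 0L
  xs <- ys <- integer(T)
  for (t in seq_len(T)) {
    res <- step(state, landscape, params)
    state <- res$state
    if (res$switched) n_switch <- n_switch + 1L
    d2 <- (state$x - nest[[1]])^2 + (state$y - nest[[2]])^2
    if (d2 > max_d2) max_d2 <- d2
    if (hab[state$y + 1, state$x + 1] == 1L) n_wild <- n_wild + 1L
    xs[t] <- state$x; ys[t] <- state$y
  }
  list(max_distance = sqrt(max_d2), n_switches = n_switch,
       prop_wild = n_wild / T, x = xs, y = ys)
}

# Balanced repeated-measures table for trend-test checks: one observation
# per (run, level), with a run random effect and an optional linear level
# effect.
sim_table <- function(n_runs, levels, run_sd = 1, noise_sd = 1, effect = 0) {
  g <- expand.grid(env = seq_len(n_runs), level = levels)
  run_eff <- rnorm(n_runs, 0, run_sd)
  g$y <- run_eff[g$env] + effect * as.numeric(factor(g$level)) +
    rnorm(nrow(g), 0, noise_sd)
  g
}

# Brute-force hedge membership of one wild cell: field ids seen across the
# cell and its in-grid 3x3 neighbourhood must be exactly a pair that
# includes the cell's own field.
brute_force_hedge_key <- function(landscape, x, y) {
  fld <- landscape$field
  h <- nrow(fld); w <- ncol(fld)
  ids <- integer(0)
  for (dy in -1:1) for (dx in -1:1) {
    nx <- x + dx; ny <- y + dy
    if (nx >= 0 && nx < w && ny >= 0 && ny < h)
      ids <- c(ids, fld[ny + 1, nx + 1])
  }
  u <- sort(unique(ids))
  if (length(u) == 2) paste(u, collapse = "_") else ""
}
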