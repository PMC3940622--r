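#' @title Experiment protocols
#' @description
#' The experiment functions orchestrate replicate simulated environments.
#' Each environment is an independently generated landscape with its own
#' nest and its own randomly drawn nuisance movement parameters; the
#' variable under study is then swept over a fixed set of levels with one
#' walk per level, giving a repeated-measures design (environment =
#' random factor).  Defaults are the full study conditions: 1000
#' environments of 1000 x 1000 cells with 101-200 fields and 1000
#' timesteps per walk.  Pass smaller `n_env`/`width`/`height` for desk
#' runs; trends are preserved at reduced scale.
#'
#' The master `seed` expands into named substreams (one per environment,
#' then one per assay level and one per manipulation draw), so results
#' are byte-reproducible and adding levels never perturbs other levels.
#' @name experiments
NULL

MAX_SEED <- 2147483646L

# Draw one environment: landscape plus nest, redrawing (counted) if the
# landscape has no wild cell or fewer hedges than a schedule needs.
draw_environment <- function(width, height, n_fields_range,
                             min_hedges = 0L) {
  redraws <- 0L
  repeat {
    n_fields <- if (n_fields_range[1L] == n_fields_range[2L]) n_fields_range[1L]
                else sample(n_fields_range[1L]:n_fields_range[2L], 1L)
    land <- generate_landscape(width, height, n_fields)
    hedges <- NULL
    ok <- n_wild_cells(land) > 0L
    if (ok && min_hedges > 0L) {
      hedges <- enumerate_hedges(land)
      ok <- length(hedges) >= min_hedges
    }
    if (ok) {
      nest <- place_nest(land)
      return(list(landscape = land, nest = nest, n_fields = n_fields,
                  hedges = hedges, redraws = redraws))
    }
    redraws <- redraws + 1L
  }
}

new_results <- function(df, protocol, seed, redraws = 0L, nest_redraws = 0L) {
  structure(df, class = c("hw_results", "data.frame"),
            protocol = protocol, seed = seed, redraws = redraws,
            nest_redraws = nest_redraws)
}

#' @export
print.hw_results <- function(x, ...) {
  cat(sprintf("<hw_results> protocol %s: %d rows, %d environments\n",
              attr(x, "protocol"), nrow(x), length(unique(x$env))))
  NextMethod()
}

walk_row <- function(traj) {
  data.frame(max_distance = traj$max_distance,
             n_switches = traj$n_switches,
             prop_wild = traj$prop_wild,
             border_steps = traj$border_steps)
}

#' Model 1: effects of movement choice
#'
#' Sweeps the forward-move probability `p_F` over six levels per
#' environment.  Per environment the switching reduction `r` and the
#' side-bias constant `v` are each drawn once from U(0, 1) and reused at
#' every level; `p_S` and `p_B` follow from [base_probabilities()].
#'
#' @param n_env Number of replicate environments.
#' @param width,height Landscape dimensions in cells.
#' @param n_fields_range Integer range (min, max) from which each
#'   environment's field count is drawn.
#' @param T Timesteps per walk.
#' @param p_F_levels Systematic levels of `p_F`.
#' @param seed Master seed for the run (`NULL` continues the current RNG
#'   stream).
#' @return An `hw_results` data frame with one row per (environment,
#'   level): columns `env`, `p_F`, `max_distance`, `n_switches`,
#'   `prop_wild`, `border_steps`, and the environment's nuisance draws
#'   `r`, `v`, `n_fields`.
#' @examples
#' m1 <- run_model1(n_env = 4, width = 120, height = 120, seed = 1)
#' head(m1)
#' @export
run_model1 <- function(n_env = 1000, width = 1000, height = 1000,
                       n_fields_range = c(101, 200), T = 1000,
                       p_F_levels = seq(0.25, 0.875, by = 0.125),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  env_seeds <- sample.int(MAX_SEED, n_env)
  out <- vector("list", n_env)
  redraws <- 0L
  for (e in seq_len(n_env)) {
    set.seed(env_seeds[e])
    env <- draw_environment(width, height, n_fields_range)
    redraws <- redraws + env$redraws
    r <- stats::runif(1)
    v <- stats::runif(1)
    level_seeds <- sample.int(MAX_SEED, length(p_F_levels))
    rows <- lapply(seq_along(p_F_levels), function(i) {
      set.seed(level_seeds[i])
      pr <- movement_params(p_F_levels[i], v, r)
      cbind(data.frame(env = e, p_F = p_F_levels[i]),
            walk_row(simulate_walk(env$landscape, env$nest, pr, T)))
    })
    df <- do.call(rbind, rows)
    df$r <- r; df$v <- v; df$n_fields <- env$n_fields
    out[[e]] <- df
  }
  new_results(do.call(rbind, out), "M1", seed, redraws)
}

#' Model 2: effects of the habitat-switching reduction
#'
#' Sweeps the switching reduction over `r_levels` (geometric ladder
#' (2/3)^k, k = 0..13 by default, so the first level `r = 1` is the
#' habitat-neutral walk).  Per environment `p_F` is drawn from
#' U(0.25, 1) and `v` from U(0, 1), once, and reused at every level.
#'
#' @inheritParams run_model1
#' @param r_levels Systematic levels of `r`.
#' @return An `hw_results` data frame with one row per (environment,
#'   level); columns as in [run_model1()] but with `r` as the swept level
#'   and `p_F`, `v` as nuisance draws.
#' @export
run_model2 <- function(n_env = 1000, width = 1000, height = 1000,
                       n_fields_range = c(101, 200), T = 1000,
                       r_levels = (2 / 3)^(0:13), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  env_seeds <- sample.int(MAX_SEED, n_env)
  out <- vector("list", n_env)
  redraws <- 0L
  for (e in seq_len(n_env)) {
    set.seed(env_seeds[e])
    env <- draw_environment(width, height, n_fields_range)
    redraws <- redraws + env$redraws
    p_F <- stats::runif(1, 0.25, 1)
    v <- stats::runif(1)
    level_seeds <- sample.int(MAX_SEED, length(r_levels))
    rows <- lapply(seq_along(r_levels), function(i) {
      set.seed(level_seeds[i])
      pr <- movement_params(p_F, v, r_levels[i])
      cbind(data.frame(env = e, r = r_levels[i]),
            walk_row(simulate_walk(env$landscape, env$nest, pr, T)))
    })
    df <- do.call(rbind, rows)
    df$p_F <- p_F; df$v <- v; df$n_fields <- env$n_fields
    out[[e]] <- df
  }
  new_results(do.call(rbind, out), "M2", seed, redraws)
}

#' Models 3 and 3a: effects of adding set-aside fields
#'
#' Walks are assayed on cumulatively converted landscapes: at each point
#' of `setaside_points` the schedule's additional fields are converted to
#' wild set-aside and one walk is run from the environment's (fixed)
#' nest.  Per environment `p_F` ~ U(0.25, 1), `v` ~ U(0, 1) and `r` ~
#' U(0, 1) are drawn once.  `run_model3a()` is the specialist variant
#' with `r = 0` (the walker never leaves the wild habitat); following the
#' protocol it records only the maximum distance from the nest.
#'
#' @inheritParams run_model1
#' @param setaside_points Cumulative numbers of set-aside fields at which
#'   to assay movement (must start at 0 and increase).
#' @param r_fixed Optional fixed value for `r` replacing the per-
#'   environment draw (used by the specialist variant).
#' @return An `hw_results` data frame with one row per (environment,
#'   assay point); level column `n_setasides`.
#' @export
run_model3 <- function(n_env = 1000, width = 1000, height = 1000,
                       n_fields_range = c(101, 200), T = 1000,
                       setaside_points = seq(0, 50, by = 5),
                       r_fixed = NULL, seed = NULL) {
  check_schedule(setaside_points)
  if (max(setaside_points) >= n_fields_range[1L])
    stop("schedule error: schedule needs more fields than the minimum of ",
         "`n_fields_range` provides")
  if (!is.null(seed)) set.seed(seed)
  env_seeds <- sample.int(MAX_SEED, n_env)
  out <- vector("list", n_env)
  redraws <- 0L
  np <- length(setaside_points)
  for (e in seq_len(n_env)) {
    set.seed(env_seeds[e])
    env <- draw_environment(width, height, n_fields_range)
    redraws <- redraws + env$redraws
    p_F <- stats::runif(1, 0.25, 1)
    v <- stats::runif(1)
    r <- if (is.null(r_fixed)) stats::runif(1) else r_fixed
    pr <- movement_params(p_F, v, r)
    manip_seeds <- sample.int(MAX_SEED, np)
    level_seeds <- sample.int(MAX_SEED, np)
    land <- env$landscape
    converted <- integer(0)
    rows <- vector("list", np)
    for (i in seq_len(np)) {
      k_new <- setaside_points[i] - if (i == 1L) 0L else setaside_points[i - 1L]
      if (k_new > 0L) {
        set.seed(manip_seeds[i])
        res <- convert_setasides(land, k_new, converted)
        land <- res$landscape
        converted <- res$converted
      }
      set.seed(level_seeds[i])
      rows[[i]] <- cbind(data.frame(env = e, n_setasides = setaside_points[i]),
                         walk_row(simulate_walk(land, env$nest, pr, T)))
    }
    df <- do.call(rbind, rows)
    df$p_F <- p_F; df$v <- v; df$r <- r; df$n_fields <- env$n_fields
    out[[e]] <- df
  }
  proto <- if (!is.null(r_fixed) && r_fixed == 0) "M3a" else "M3"
  new_results(do.call(rbind, out), proto, seed, redraws)
}

#' @rdname run_model3
#' @export
run_model3a <- function(n_env = 1000, width = 1000, height = 1000,
                        n_fields_range = c(101, 200), T = 1000,
                        setaside_points = seq(0, 50, by = 5), seed = NULL) {
  res <- run_model3(n_env, width, height, n_fields_range, T,
                    setaside_points, r_fixed = 0, seed = seed)
  keep <- c("env", "n_setasides", "max_distance", "border_steps",
            "p_F", "v", "r", "n_fields")
  new_results(as.data.frame(res)[, keep], "M3a", seed, attr(res, "redraws"))
}

#' Models 4 and 4a: effects of removing hedgerows
#'
#' Hedges are enumerated once on the basal landscape ([enumerate_hedges()])
#' and removed cumulatively; at each point of `removal_points` one walk is
#' run.  Environments whose basal corridor network has fewer hedges than
#' the schedule needs are redrawn (counted in the `redraws` attribute).
#' If removal turns the nest cell into crop, a new nest is drawn from the
#' remaining wild cells for that and subsequent assay points (counted in
#' the `nest_redraws` attribute).  `run_model4a()` is the specialist
#' variant with `r = 0`, recording only the maximum distance.
#'
#' @inheritParams run_model3
#' @param removal_points Cumulative numbers of removed hedges at which to
#'   assay movement (must start at 0 and increase).
#' @return An `hw_results` data frame with one row per (environment,
#'   assay point); level column `n_hedges_removed`.
#' @export
run_model4 <- function(n_env = 1000, width = 1000, height = 1000,
                       n_fields_range = c(101, 200), T = 1000,
                       removal_points = seq(0, 40, by = 4),
                       r_fixed = NULL, seed = NULL) {
  check_schedule(removal_points)
  if (!is.null(seed)) set.seed(seed)
  env_seeds <- sample.int(MAX_SEED, n_env)
  out <- vector("list", n_env)
  redraws <- 0L
  nest_redraws <- 0L
  np <- length(removal_points)
  for (e in seq_len(n_env)) {
    set.seed(env_seeds[e])
    env <- draw_environment(width, height, n_fields_range,
                            min_hedges = max(removal_points))
    redraws <- redraws + env$redraws
    p_F <- stats::runif(1, 0.25, 1)
    v <- stats::runif(1)
    r <- if (is.null(r_fixed)) stats::runif(1) else r_fixed
    pr <- movement_params(p_F, v, r)
    manip_seeds <- sample.int(MAX_SEED, np)
    level_seeds <- sample.int(MAX_SEED, np)
    land <- env$landscape
    nest <- env$nest
    removed <- integer(0)
    rows <- vector("list", np)
    for (i in seq_len(np)) {
      k_new <- removal_points[i] - if (i == 1L) 0L else removal_points[i - 1L]
      if (k_new > 0L) {
        set.seed(manip_seeds[i])
        res <- remove_hedges(land, env$hedges, k_new, removed)
        land <- res$landscape
        removed <- res$removed
        if (land$habitat[nest[["y"]] + 1L, nest[["x"]] + 1L] == 0L) {
          nest <- place_nest(land)
          nest_redraws <- nest_redraws + 1L
        }
      }
      set.seed(level_seeds[i])
      rows[[i]] <- cbind(data.frame(env = e,
                                    n_hedges_removed = removal_points[i]),
                         walk_row(simulate_walk(land, nest, pr, T)))
    }
    df <- do.call(rbind, rows)
    df$p_F <- p_F; df$v <- v; df$r <- r; df$n_fields <- env$n_fields
    out[[e]] <- df
  }
  proto <- if (!is.null(r_fixed) && r_fixed == 0) "M4a" else "M4"
  new_results(do.call(rbind, out), proto, seed, redraws, nest_redraws)
}

#' @rdname run_model4
#' @export
run_model4a <- function(n_env = 1000, width = 1000, height = 1000,
                        n_fields_range = c(101, 200), T = 1000,
                        removal_points = seq(0, 40, by = 4), seed = NULL) {
  res <- run_model4(n_env, width, height, n_fields_range, T,
                    removal_points, r_fixed = 0, seed = seed)
  keep <- c("env", "n_hedges_removed", "max_distance", "border_steps",
            "p_F", "v", "r", "n_fields")
  new_results(as.data.frame(res)[, keep], "M4a", seed,
              attr(res, "redraws"), attr(res, "nest_redraws"))
}

check_schedule <- function(points) {
  if (length(points) < 1L || points[1L] != 0 ||
      any(diff(points) <= 0))
    stop("schedule points must start at 0 and be strictly increasing")
  invisible(TRUE)
}

#' Factorial sensitivity analysis
#'
#' Crosses one movement or landscape axis with a landscape-manipulation
#' schedule, replicated over `n_param_sets` randomised draws of the
#' remaining parameters, and summarises the three movement statistics per
#' grid point.
#'
#' Axes: `p_F` over 0.1-0.9 (with `v`, `r` random); `p_S` over 0-0.45
#' (with `p_F = (1 - 2 p_S) * U(0, 1)` and `r` random); `r` over 0-0.9
#' (with `p_F` ~ U(0.25, 1), `v` random); `n_fields` varies the seeded
#' field count, one landscape per axis value (with `p_F`, `v`, `r`
#' random).  Manipulation: `"set_aside"` (0, 5, ..., 50 fields) or
#' `"hedge_removal"` (0, 4, ..., 40 hedges), cumulative within each
#' parameter set.
#'
#' @inheritParams run_model1
#' @param axis One of `"p_F"`, `"p_S"`, `"r"`, `"n_fields"`.
#' @param manip `"set_aside"` or `"hedge_removal"`.
#' @param n_param_sets Number of randomised parameter sets.
#' @param axis_values Optional explicit axis levels overriding the
#'   defaults above.
#' @param manip_points Optional explicit manipulation schedule.
#' @param keep_raw If `TRUE`, attach the raw per-walk table as the
#'   `"raw"` attribute.
#' @return Data frame with one row per (axis value, manipulation level):
#'   mean and standard deviation of `max_distance`, `n_switches` and
#'   `prop_wild` over parameter sets, plus `n`.
#' @export
run_sensitivity <- function(axis = c("p_F", "p_S", "r", "n_fields"),
                            manip = c("set_aside", "hedge_removal"),
                            n_param_sets = 1000, width = 1000, height = 1000,
                            n_fields_range = c(101, 200), T = 1000,
                            axis_values = NULL, manip_points = NULL,
                            seed = NULL, keep_raw = FALSE) {
  axis <- match.arg(axis)
  manip <- match.arg(manip)
  if (is.null(axis_values))
    axis_values <- switch(axis,
                          p_F = seq(0.1, 0.9, by = 0.1),
                          p_S = seq(0, 0.45, by = 0.05),
                          r = seq(0, 0.9, by = 0.1),
                          n_fields = c(50, 100, 150, 200, 250))
  if (is.null(manip_points))
    manip_points <- if (manip == "set_aside") seq(0, 50, by = 5)
                    else seq(0, 40, by = 4)
  check_schedule(manip_points)
  if (!is.null(seed)) set.seed(seed)
  ps_seeds <- sample.int(MAX_SEED, n_param_sets)
  na <- length(axis_values); np <- length(manip_points)
  raw <- vector("list", n_param_sets)
  for (ps in seq_len(n_param_sets)) {
    set.seed(ps_seeds[ps])
    raw[[ps]] <- if (axis == "n_fields")
      sensitivity_nfields_set(ps, axis_values, manip, manip_points,
                              width, height, T)
    else
      sensitivity_movement_set(ps, axis, axis_values, manip, manip_points,
                               width, height, n_fields_range, T)
  }
  raw <- do.call(rbind, raw)
  agg <- stats::aggregate(
    raw[, c("max_distance", "n_switches", "prop_wild")],
    by = list(axis_value = raw$axis_value, manip_level = raw$manip_level),
    FUN = mean)
  names(agg)[3:5] <- paste0("mean_", names(agg)[3:5])
  sds <- stats::aggregate(
    raw[, c("max_distance", "n_switches", "prop_wild")],
    by = list(axis_value = raw$axis_value, manip_level = raw$manip_level),
    FUN = stats::sd)
  agg$sd_max_distance <- sds$max_distance
  agg$sd_n_switches <- sds$n_switches
  agg$sd_prop_wild <- sds$prop_wild
  agg$n <- n_param_sets
  agg <- agg[order(agg$axis_value, agg$manip_level), ]
  rownames(agg) <- NULL
  attr(agg, "axis") <- axis
  attr(agg, "manip") <- manip
  attr(agg, "seed") <- seed
  if (keep_raw) attr(agg, "raw") <- raw
  agg
}

# Draw the non-systematic movement parameters for one sensitivity
# parameter set and return the per-axis-value parameter objects.
sensitivity_params <- function(axis, axis_values) {
  switch(axis,
    p_F = {
      v <- stats::runif(1); r <- stats::runif(1)
      lapply(axis_values, function(pf) movement_params(pf, v, r))
    },
    p_S = {
      u <- stats::runif(1); r <- stats::runif(1)
      lapply(axis_values, function(ps) {
        pf <- (1 - 2 * ps) * u
        params_from_triple(pf, ps, 1 - pf - 2 * ps, r)
      })
    },
    r = {
      pf <- stats::runif(1, 0.25, 1); v <- stats::runif(1)
      lapply(axis_values, function(r) movement_params(pf, v, r))
    },
    n_fields = {
      pf <- stats::runif(1, 0.25, 1); v <- stats::runif(1)
      r <- stats::runif(1)
      rep(list(movement_params(pf, v, r)), length(axis_values))
    })
}

# Construct hw_params from an explicit probability triple (used where p_S
# is set directly rather than through the v-construction).
params_from_triple <- function(p_F, p_S, p_B, r) {
  if (p_F < 0 || p_S < 0 || p_B < -1e-12)
    stop("invalid probability triple")
  structure(list(p_F = p_F, p_S = p_S, p_B = max(p_B, 0), v = NA_real_,
                 r = r),
            class = "hw_params")
}

apply_manip <- function(manip, land, hedges, k_new, state) {
  if (manip == "set_aside") {
    res <- convert_setasides(land, k_new, state)
  } else {
    res <- remove_hedges(land, hedges, k_new, state)
  }
  list(landscape = res$landscape,
       state = if (manip == "set_aside") res$converted else res$removed)
}

sensitivity_movement_set <- function(ps, axis, axis_values, manip,
                                     manip_points, width, height,
                                     n_fields_range, T) {
  min_hedges <- if (manip == "hedge_removal") max(manip_points) else 0L
  env <- draw_environment(width, height, n_fields_range, min_hedges)
  par_list <- sensitivity_params(axis, axis_values)
  na <- length(axis_values); np <- length(manip_points)
  manip_seeds <- sample.int(MAX_SEED, np)
  walk_seeds <- matrix(sample.int(MAX_SEED, na * np), nrow = na)
  land <- env$landscape
  nest <- env$nest
  state <- integer(0)
  rows <- vector("list", na * np)
  for (i in seq_len(np)) {
    k_new <- manip_points[i] - if (i == 1L) 0L else manip_points[i - 1L]
    if (k_new > 0L) {
      set.seed(manip_seeds[i])
      res <- apply_manip(manip, land, env$hedges, k_new, state)
      land <- res$landscape
      state <- res$state
      if (land$habitat[nest[["y"]] + 1L, nest[["x"]] + 1L] == 0L)
        nest <- place_nest(land)
    }
    for (a in seq_len(na)) {
      set.seed(walk_seeds[a, i])
      rows[[(i - 1L) * na + a]] <- cbind(
        data.frame(param_set = ps, axis_value = axis_values[a],
                   manip_level = manip_points[i]),
        walk_row(simulate_walk(land, nest, par_list[[a]], T)))
    }
  }
  do.call(rbind, rows)
}

sensitivity_nfields_set <- function(ps, axis_values, manip, manip_points,
                                    width, height, T) {
  min_hedges <- if (manip == "hedge_removal") max(manip_points) else 0L
  par_list <- sensitivity_params("n_fields", axis_values)
  na <- length(axis_values); np <- length(manip_points)
  rows <- vector("list", na)
  for (a in seq_len(na)) {
    nf <- axis_values[a]
    if (manip == "set_aside" && max(manip_points) >= nf)
      stop("schedule error: set-aside schedule needs more fields than ",
           nf, " provides")
    env <- draw_environment(width, height, c(nf, nf), min_hedges)
    manip_seeds <- sample.int(MAX_SEED, np)
    walk_seeds <- sample.int(MAX_SEED, np)
    land <- env$landscape
    nest <- env$nest
    state <- integer(0)
    sub <- vector("list", np)
    for (i in seq_len(np)) {
      k_new <- manip_points[i] - if (i == 1L) 0L else manip_points[i - 1L]
      if (k_new > 0L) {
        set.seed(manip_seeds[i])
        res <- apply_manip(manip, land, env$hedges, k_new, state)
        land <- res$landscape
        state <- res$state
        if (land$habitat[nest[["y"]] + 1L, nest[["x"]] + 1L] == 0L)
          nest <- place_nest(land)
      }
      set.seed(walk_seeds[i])
      sub[[i]] <- cbind(
        data.frame(param_set = ps, axis_value = nf,
                   manip_level = manip_points[i]),
        walk_row(simulate_walk(land, nest, par_list[[a]], T)))
    }
    rows[[a]] <- do.call(rbind, sub)
  }
  do.call(rbind, rows)
}
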