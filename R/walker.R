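#' Base correlated-random-walk probabilities
#'
#' Computes the unadjusted step-direction probabilities of the correlated
#' random walk from the forward probability `p_F` and a shape constant
#' `v`:
#' \deqn{p_S = (1 - p_F)/3 + v (1 - p_F)/6, \quad p_B = 1 - p_F - 2 p_S.}
#' At `v = 0` the non-forward probability is split evenly over the three
#' remaining directions; at `v = 1` the backward probability vanishes and
#' all deviation goes sideways.
#'
#' @param p_F Probability of continuing forward, in (0, 1].
#' @param v Dimensionless constant in \[0, 1\] controlling how the
#'   non-forward probability is divided between sideways and backward
#'   moves.
#' @return Named numeric vector `c(p_F, p_S, p_B)` with
#'   `p_F + p_B + 2 p_S = 1`.
#' @examples
#' base_probabilities(0.25, 0)    # uniform over the four directions
#' base_probabilities(0.875, 0.4)
#' @export
base_probabilities <- function(p_F, v) {
  if (!is.numeric(p_F) || length(p_F) != 1L || is.na(p_F) ||
      p_F <= 0 || p_F > 1)
    stop("`p_F` must be a single number in (0, 1]")
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
    stop("`v` must be a single number in [0, 1]")
  p_S <- (1 - p_F) / 3 + v * (1 - p_F) / 6
  p_B <- 1 - p_F - 2 * p_S
  c(p_F = p_F, p_S = p_S, p_B = max(p_B, 0))
}

#' Movement parameter set
#'
#' Bundles the walker's direction probabilities with the habitat-switching
#' reduction `r`.  `r = 1` makes the walk habitat-neutral; `r = 0` forbids
#' moving into the other habitat type (a specialist confined to the
#' habitat it starts in).
#'
#' @inheritParams base_probabilities
#' @param r Switching reduction in \[0, 1\]: the preference for stepping
#'   into a cell of a different habitat is multiplied by `r`.
#' @return An object of class `hw_params`: list with `p_F`, `p_S`, `p_B`,
#'   `v`, `r`.
#' @export
movement_params <- function(p_F, v, r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
    stop("`r` must be a single number in [0, 1]")
  p <- base_probabilities(p_F, v)
  stopifnot(abs(p[["p_F"]] + p[["p_B"]] + 2 * p[["p_S"]] - 1) < 1e-12)
  structure(list(p_F = p[["p_F"]], p_S = p[["p_S"]], p_B = p[["p_B"]],
                 v = v, r = r),
            class = "hw_params")
}

#' @export
print.hw_params <- function(x, ...) {
  cat(sprintf("<hw_params> p_F=%.4g p_S=%.4g p_B=%.4g (v=%.4g), r=%.4g\n",
              x$p_F, x$p_S, x$p_B, x$v, x$r))
  invisible(x)
}

# Absolute directions are encoded 0=N, 1=E, 2=S, 3=W (N decreases y).
# Relative directions follow from the heading by clockwise rotation:
# forward = +0, right = +90, backward = +180, left = +270 degrees.
DIR_DELTA <- matrix(c(0L, -1L,   # N
                      1L,  0L,   # E
                      0L,  1L,   # S
                      -1L, 0L),  # W
                    ncol = 2, byrow = TRUE,
                    dimnames = list(c("N", "E", "S", "W"), c("dx", "dy")))

# heading offsets for relative order (F, B, L, R) in quarter turns clockwise
REL_OFFSET <- c(F = 0L, B = 2L, L = 3L, R = 1L)

#' Habitat context of the four neighbouring cells
#'
#' Looks up the habitat of the current cell and of the forward, backward,
#' left and right neighbours relative to the heading.  Neighbours beyond
#' the grid border are reported as `NA` (off-grid).
#'
#' @param landscape An `hw_landscape`.
#' @param x,y 0-based cell coordinates of the walker.
#' @param heading Absolute heading, one of 0 (N), 1 (E), 2 (S), 3 (W).
#' @return List with `c_current` and `c_F`, `c_B`, `c_L`, `c_R` (each 0,
#'   1 or `NA`).
#' @export
neighbour_context <- function(landscape, x, y, heading) {
  hab <- landscape$habitat
  w <- landscape$width; h <- landscape$height
  stopifnot(x >= 0, x < w, y >= 0, y < h, heading %in% 0:3)
  look <- function(off) {
    d <- (heading + off) %% 4L
    nx <- x + DIR_DELTA[d + 1L, "dx"]
    ny <- y + DIR_DELTA[d + 1L, "dy"]
    if (nx < 0 || nx >= w || ny < 0 || ny >= h) NA_integer_
    else hab[ny + 1L, nx + 1L]
  }
  list(c_current = hab[y + 1L, x + 1L],
       c_F = look(REL_OFFSET[["F"]]), c_B = look(REL_OFFSET[["B"]]),
       c_L = look(REL_OFFSET[["L"]]), c_R = look(REL_OFFSET[["R"]]))
}

#' Habitat-adjusted movement preferences
#'
#' Applies the switching reduction to the base probabilities: the
#' preference for direction i is \eqn{m_i = p_i} when the target cell has
#' the same habitat as the current cell and \eqn{m_i = r p_i} when it
#' differs.  Off-grid directions get preference 0.
#'
#' @param params An `hw_params`.
#' @param ctx A context as returned by [neighbour_context()].
#' @return Named numeric vector `c(m_F, m_B, m_L, m_R)`.
#' @export
adjusted_preferences <- function(params, ctx) {
  stopifnot(inherits(params, "hw_params"))
  p <- c(m_F = params$p_F, m_B = params$p_B, m_L = params$p_S,
         m_R = params$p_S)
  nb <- c(ctx$c_F, ctx$c_B, ctx$c_L, ctx$c_R)
  fac <- ifelse(is.na(nb), 0, ifelse(nb == ctx$c_current, 1, params$r))
  p * fac
}

#' Normalised step probabilities
#'
#' Converts preferences to probabilities, \eqn{a_i = m_i / \sum_j m_j}.
#' When every preference is zero (the walker is completely blocked) the
#' all-zero vector is returned as the stay-in-place sentinel: the walker
#' does not move that timestep.
#'
#' @param m Non-negative preference 4-vector (forward, backward, left,
#'   right).
#' @return Numeric 4-vector summing to 1, or all zeros for a blocked
#'   walker.
#' @export
step_probabilities <- function(m) {
  if (length(m) != 4L || any(is.na(m)) || any(m < 0))
    stop("`m` must be four non-negative preferences")
  s <- sum(m)
  if (s <= 0) return(stats::setNames(rep(0, 4), c("a_F", "a_B", "a_L", "a_R")))
  stats::setNames(as.numeric(m) / s, c("a_F", "a_B", "a_L", "a_R"))
}

#' Advance the walker by one timestep
#'
#' Samples one of the four relative directions with the adjusted,
#' normalised probabilities and updates position and heading.  Consumes
#' exactly one uniform draw from R's RNG stream per call, matching the
#' compiled bulk simulator step for step.
#'
#' @param state List with `x`, `y` (0-based) and `heading` (0-3).
#' @param landscape An `hw_landscape`.
#' @param params An `hw_params`.
#' @return List with the new `state`, and flags `moved` and `switched`
#'   (habitat of the new cell differs from the previous cell's).
#' @export
step <- function(state, landscape, params) {
  ctx <- neighbour_context(landscape, state$x, state$y, state$heading)
  m <- adjusted_preferences(params, ctx)
  a <- step_probabilities(m)
  u <- stats::runif(1)
  if (sum(a) <= 0)
    return(list(state = state, moved = FALSE, switched = FALSE))
  k <- findInterval(u * sum(m), cumsum(m)) + 1L
  k <- min(k, 4L)
  d <- (state$heading + REL_OFFSET[k]) %% 4L
  new <- list(x = state$x + DIR_DELTA[d + 1L, "dx"],
              y = state$y + DIR_DELTA[d + 1L, "dy"],
              heading = as.integer(d))
  hab <- landscape$habitat
  switched <- hab[new$y + 1L, new$x + 1L] != ctx$c_current
  list(state = new, moved = TRUE, switched = switched)
}

#' Simulate a foraging walk and summarise it
#'
#' Runs the habitat-biased correlated random walk for `T` timesteps from
#' the nest and returns the three per-trajectory summary statistics:
#' \describe{
#'   \item{max_distance}{maximum Euclidean distance (grid units, cell
#'     centre to cell centre) from the nest over the `T` post-move
#'     positions;}
#'   \item{n_switches}{number of habitat changes between consecutively
#'     occupied cells;}
#'   \item{prop_wild}{fraction of the `T` post-move positions on WILD
#'     cells (the nest cell at t = 0 is not counted).}
#' }
#' The initial heading is drawn uniformly from the four absolute
#' directions unless supplied.  Timesteps on which the walker is
#' completely blocked (all preferences zero) leave position and heading
#' unchanged but still count towards `prop_wild`.
#'
#' @param landscape An `hw_landscape`.
#' @param nest Integer vector `c(x, y)` (0-based), normally from
#'   [place_nest()].
#' @param params An `hw_params`.
#' @param T Number of timesteps (>= 1).
#' @param init_heading Optional fixed initial heading 0-3; `NULL` draws
#'   one at random.
#' @param keep_path If `TRUE`, attach the full trajectory as a data frame
#'   with columns `t`, `x`, `y`, `heading`, `habitat`, `switched`,
#'   `moved`.
#' @return An object of class `hw_trajectory`: list with the three
#'   statistics plus `border_steps` (timesteps spent on a border cell),
#'   `stay_steps`, `init_heading`, and optionally `path`.
#' @examples
#' set.seed(7)
#' land <- generate_landscape(101, 101, 30)
#' nest <- place_nest(land)
#' simulate_walk(land, nest, movement_params(0.5, 0.5, 0.5), T = 1000)
#' @export
simulate_walk <- function(landscape, nest, params, T = 1000,
                          init_heading = NULL, keep_path = FALSE) {
  stopifnot(inherits(landscape, "hw_landscape"), inherits(params, "hw_params"))
  nest <- as.integer(nest)
  if (length(nest) != 2L || any(is.na(nest)) ||
      nest[1L] < 0L || nest[1L] >= landscape$width ||
      nest[2L] < 0L || nest[2L] >= landscape$height)
    stop("`nest` must be a valid 0-based cell inside the grid")
  ih <- if (is.null(init_heading)) -1L else as.integer(init_heading)
  if (ih > 3L || (ih < 0L && ih != -1L)) stop("`init_heading` must be 0-3")
  res <- cpp_simulate_walk(landscape$habitat, nest[1L], nest[2L],
                           params$p_F, params$p_S, params$p_B, params$r,
                           as.integer(T), ih, isTRUE(keep_path))
  structure(res, class = "hw_trajectory")
}

#' @export
print.hw_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<hw_trajectory> max_distance=%.2f n_switches=%d ",
                     "prop_wild=%.3f (border_steps=%d)\n"),
              x$max_distance, x$n_switches, x$prop_wild, x$border_steps))
  invisible(x)
}
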