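#' Generate field seed points
#'
#' Draws `n_fields` distinct cells uniformly at random on a `width` x
#' `height` grid.  Each seed generates one agricultural field of the
#' Voronoi tessellation.
#'
#' Coordinates are 0-based throughout the package: `x` is the column,
#' `y` the row, with the origin at the top-left corner of the grid.
#' Randomness comes from R's global RNG stream, so wrap calls in
#' [set.seed()] for reproducibility.
#'
#' @param width,height Grid dimensions in cells (integers > 1).
#' @param n_fields Number of field seeds (integer >= 1, at most
#'   `width * height`).
#' @return A data frame with columns `field_id` (0-based, contiguous),
#'   `x` and `y`.
#' @examples
#' set.seed(1)
#' generate_seeds(100, 100, 5)
#' @export
generate_seeds <- function(width, height, n_fields) {
  check_grid_dims(width, height)
  n_fields <- as.integer(n_fields)
  if (length(n_fields) != 1L || is.na(n_fields) || n_fields < 1L)
    stop("`n_fields` must be a single integer >= 1")
  if (n_fields > width * height)
    stop("cannot place ", n_fields, " distinct seeds on a ",
         width, "x", height, " grid")
  idx <- sample.int(width * height, n_fields) - 1L
  data.frame(field_id = seq_len(n_fields) - 1L,
             x = idx %% width,
             y = idx %/% width)
}

#' Assign every cell to its nearest field seed
#'
#' Grid-based Voronoi tessellation: each cell joins the field whose seed is
#' closest by Euclidean distance between cell centres.  Ties are broken
#' deterministically in favour of the lowest `field_id`, so the assignment
#' does not depend on the order in which seeds are listed.
#'
#' @param seeds Data frame as returned by [generate_seeds()].
#' @param width,height Grid dimensions in cells.
#' @return An integer `height` x `width` matrix of 0-based field ids
#'   (rows index `y`, columns index `x`).
#' @export
assign_fields <- function(seeds, width, height) {
  check_grid_dims(width, height, min = 1L)
  if (is.null(seeds) || nrow(seeds) < 1L)
    stop("`seeds` must contain at least one field seed")
  if (!all(c("field_id", "x", "y") %in% names(seeds)))
    stop("`seeds` must have columns field_id, x, y")
  if (any(seeds$x < 0 | seeds$x >= width | seeds$y < 0 | seeds$y >= height))
    stop("seed coordinates fall outside the grid")
  ord <- order(seeds$field_id)
  if (!identical(as.integer(seeds$field_id[ord]),
                 seq_len(nrow(seeds)) - 1L))
    stop("field_ids must be unique and contiguous from 0")
  cpp_assign_fields(as.integer(seeds$x[ord]), as.integer(seeds$y[ord]),
                    width, height)
}

#' Classify hedgerow (wild) cells from a field map
#'
#' Field edges are wild land: cells lying on the boundary between two
#' fields.  Marking every cell with a differing neighbour would put wild
#' strips on both sides of each boundary (two cells thick); instead each
#' field-field interface contributes a single strip, laid on its lower
#' field-id side: a cell is WILD iff some neighbour in its 3 x 3
#' neighbourhood belongs to a field with a higher id.  The 8-cell
#' neighbourhood keeps the strip orthogonally connected where boundaries
#' run diagonally (a 4-neighbour scan leaves diagonal staircases as
#' isolated cells, which would strand habitat-confined walkers), so every
#' hedgerow cell shares an edge with another hedgerow cell.  Cells on the
#' outer grid border are classified from in-grid neighbours only; the
#' border itself is not automatically wild.
#'
#' @param field Integer matrix of field ids (rows = y, columns = x).
#' @return An integer matrix of the same shape with 1 = WILD (hedgerow)
#'   and 0 = CROP.
#' @export
classify_hedgerows <- function(field) {
  if (!is.matrix(field)) stop("`field` must be a matrix")
  h <- nrow(field); w <- ncol(field)
  wild <- matrix(FALSE, h, w)
  for (s in NEIGHBOURS8) {
    if (abs(s[1L]) >= h || abs(s[2L]) >= w) next
    rs <- max(1L, 1L + s[1L]):min(h, h + s[1L])
    cs <- max(1L, 1L + s[2L]):min(w, w + s[2L])
    tgt_r <- rs - s[1L]; tgt_c <- cs - s[2L]
    wild[tgt_r, tgt_c] <- wild[tgt_r, tgt_c] |
      (field[rs, cs, drop = FALSE] > field[tgt_r, tgt_c, drop = FALSE])
  }
  mode(wild) <- "integer"
  wild
}

NEIGHBOURS8 <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                    c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))

#' Generate a complete agricultural landscape
#'
#' Seeds the grid, tessellates it into fields, and classifies the
#' single-thickness hedgerow network.  This is the basal landscape of all
#' experiment protocols.
#'
#' @inheritParams generate_seeds
#' @return An object of class `hw_landscape`: a list with elements
#'   `width`, `height`, `seeds` (data frame), `field` (integer matrix of
#'   field ids) and `habitat` (integer matrix, 0 = CROP, 1 = WILD).
#' @examples
#' set.seed(42)
#' land <- generate_landscape(101, 101, 30)
#' land
#' @export
generate_landscape <- function(width, height, n_fields) {
  seeds <- generate_seeds(width, height, n_fields)
  field <- assign_fields(seeds, width, height)
  habitat <- classify_hedgerows(field)
  new_landscape(width, height, seeds, field, habitat)
}

new_landscape <- function(width, height, seeds, field, habitat) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 seeds = seeds, field = field, habitat = habitat),
            class = "hw_landscape")
}

#' @export
print.hw_landscape <- function(x, ...) {
  nf <- length(unique(as.vector(x$field)))
  cat(sprintf("<hw_landscape> %d x %d cells, %d fields, %d wild cells (%.1f%%)\n",
              x$width, x$height, nf, n_wild_cells(x),
              100 * wild_fraction(x)))
  invisible(x)
}

#' Place the pollinator's nest
#'
#' The nest sits in the wild corridor network (hedgerow cells): a
#' uniformly random WILD cell, which becomes the origin of every walk on
#' this landscape.
#'
#' @param landscape An `hw_landscape`.
#' @return Integer vector `c(x =, y =)` (0-based).
#' @export
place_nest <- function(landscape) {
  stopifnot(inherits(landscape, "hw_landscape"))
  wild <- which(landscape$habitat == 1L)
  if (length(wild) == 0L)
    stop("landscape has no wild cells to host a nest")
  cell <- if (length(wild) == 1L) wild else sample(wild, 1L)
  h <- landscape$height
  c(x = (cell - 1L) %/% h, y = (cell - 1L) %% h)
}

#' Fraction and count of wild cells
#'
#' @param landscape An `hw_landscape`.
#' @return `wild_fraction()` the proportion of cells classified WILD;
#'   `n_wild_cells()` their count.
#' @export
wild_fraction <- function(landscape) {
  mean(landscape$habitat == 1L)
}

#' @rdname wild_fraction
#' @export
n_wild_cells <- function(landscape) {
  sum(landscape$habitat == 1L)
}

#' Connectivity of the wild corridor network
#'
#' Counts orthogonally-connected components of the WILD cell set (flood
#' fill).  Generated landscapes are expected to have a single connected
#' hedgerow network in almost all cases; manipulated landscapes (after
#' hedge removal) may fragment.
#'
#' @param landscape An `hw_landscape`.
#' @return Integer: number of connected components (0 if no wild cells).
#' @export
wild_components <- function(landscape) {
  hab <- landscape$habitat
  h <- nrow(hab); w <- ncol(hab)
  lab <- matrix(0L, h, w)
  comp <- 0L
  for (start in which(hab == 1L & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    lab[start] <- comp
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cur - 1L) %% h + 1L
      cl <- (cur - 1L) %/% h + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        nr <- r + d[1L]; nc <- cl + d[2L]
        if (nr >= 1L && nr <= h && nc >= 1L && nc <= w) {
          idx <- (nc - 1L) * h + nr
          if (hab[idx] == 1L && lab[idx] == 0L) {
            lab[idx] <- comp
            stack <- c(stack, idx)
          }
        }
      }
    }
  }
  comp
}

check_grid_dims <- function(width, height, min = 2L) {
  if (length(width) != 1L || length(height) != 1L ||
      is.na(width) || is.na(height) ||
      width != as.integer(width) || height != as.integer(height) ||
      width < min || height < min)
    stop("`width` and `height` must be single integers >= ", min,
         if (min == 2L) " (grids must be larger than one cell)" else "")
  invisible(TRUE)
}
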