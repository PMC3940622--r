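#' Convert crop fields to wild set-aside
#'
#' Chooses `k_new` not-yet-converted fields uniformly at random and fills
#' every one of their cells with wild vegetation (habitat becomes WILD;
#' the field map itself is unchanged).  Conversion is cumulative: pass the
#' set returned by an earlier call to extend the same schedule.
#'
#' @param landscape An `hw_landscape`.
#' @param k_new Number of additional fields to convert.
#' @param already_converted Integer vector of field ids converted by
#'   earlier calls (default none).
#' @return List with elements `landscape` (modified) and `converted`
#'   (updated id set, including the new conversions).
#' @examples
#' set.seed(3)
#' land <- generate_landscape(101, 101, 30)
#' out <- convert_setasides(land, 5)
#' out <- convert_setasides(out$landscape, 5, out$converted)
#' length(out$converted)  # 10
#' @export
convert_setasides <- function(landscape, k_new, already_converted = integer(0)) {
  stopifnot(inherits(landscape, "hw_landscape"))
  k_new <- as.integer(k_new)
  if (is.na(k_new) || k_new < 0L) stop("`k_new` must be a non-negative integer")
  all_fields <- sort(unique(as.vector(landscape$field)))
  eligible <- setdiff(all_fields, already_converted)
  if (k_new > length(eligible))
    stop("schedule error: only ", length(eligible),
         " unconverted fields remain, cannot convert ", k_new)
  if (k_new == 0L)
    return(list(landscape = landscape, converted = already_converted))
  chosen <- if (length(eligible) == 1L) eligible else sample(eligible, k_new)
  landscape$habitat[landscape$field %in% chosen] <- 1L
  list(landscape = landscape,
       converted = sort(c(as.integer(already_converted), as.integer(chosen))))
}

#' Enumerate individual hedges of the corridor network
#'
#' A hedge is the strip of hedgerow cells separating one specific pair of
#' adjacent fields -- an edge of the landscape's corridor network.  A WILD
#' cell belongs to hedge (A, B) iff its own field id is A or B and the
#' field ids seen across itself and its in-grid 3 x 3 neighbourhood (the
#' same neighbourhood that defines the hedgerow classification) are
#' exactly \{A, B\}.  Junction cells touching three or more fields (the
#' network's nodes) belong to no hedge and are never removed.
#'
#' Enumeration is defined on the basal (unmanipulated) landscape; removal
#' state is tracked separately by [remove_hedges()].
#'
#' @param landscape A basal `hw_landscape`.
#' @return A list of hedges, each a list with `fields` (sorted pair of
#'   field ids) and `cells` (two-column matrix of 0-based x, y
#'   coordinates).
#' @export
enumerate_hedges <- function(landscape) {
  stopifnot(inherits(landscape, "hw_landscape"))
  fld <- landscape$field
  h <- nrow(fld); w <- ncol(fld)
  wild_idx <- which(landscape$habitat == 1L)
  if (length(wild_idx) == 0L) return(list())
  row <- (wild_idx - 1L) %% h + 1L
  col <- (wild_idx - 1L) %/% h + 1L
  self <- fld[wild_idx]
  nb <- function(dr, dc) {
    r <- row + dr; cl <- col + dc
    ok <- r >= 1L & r <= h & cl >= 1L & cl <= w
    out <- rep(NA_integer_, length(wild_idx))
    out[ok] <- fld[cbind(r[ok], cl[ok])]
    out
  }
  stack <- cbind(self, nb(-1L, 0L), nb(1L, 0L), nb(0L, -1L), nb(0L, 1L),
                 nb(-1L, -1L), nb(-1L, 1L), nb(1L, -1L), nb(1L, 1L))
  keys <- character(length(wild_idx))
  for (i in seq_along(wild_idx)) {
    ids <- unique(stack[i, !is.na(stack[i, ])])
    if (length(ids) == 2L)
      keys[i] <- paste(sort(ids), collapse = "_")
  }
  member <- keys != ""
  if (!any(member)) return(list())
  split_idx <- split(which(member), keys[member])
  hedges <- lapply(split_idx, function(ii) {
    pair <- as.integer(strsplit(keys[ii[1L]], "_", fixed = TRUE)[[1L]])
    list(fields = pair,
         cells = cbind(x = col[ii] - 1L, y = row[ii] - 1L))
  })
  names(hedges) <- NULL
  hedges
}

#' Remove hedges between adjacent fields
#'
#' Chooses `k_new` not-yet-removed hedges uniformly at random and turns
#' each member cell into CROP (habitat only; the field map is unchanged).
#' Removal is cumulative across calls via the `already_removed` index set.
#'
#' @param landscape An `hw_landscape` (basal or partially manipulated).
#' @param hedges Hedge list from [enumerate_hedges()] run on the basal
#'   landscape.
#' @param k_new Number of additional hedges to remove.
#' @param already_removed Integer vector of hedge indices removed by
#'   earlier calls.
#' @return List with `landscape` (modified) and `removed` (updated index
#'   set into `hedges`).
#' @export
remove_hedges <- function(landscape, hedges, k_new, already_removed = integer(0)) {
  stopifnot(inherits(landscape, "hw_landscape"))
  k_new <- as.integer(k_new)
  if (is.na(k_new) || k_new < 0L) stop("`k_new` must be a non-negative integer")
  remaining <- setdiff(seq_along(hedges), already_removed)
  if (k_new > length(remaining))
    stop("schedule error: only ", length(remaining),
         " unremoved hedges remain, cannot remove ", k_new)
  if (k_new == 0L)
    return(list(landscape = landscape, removed = already_removed))
  chosen <- if (length(remaining) == 1L) remaining else sample(remaining, k_new)
  for (i in chosen) {
    cells <- hedges[[i]]$cells
    landscape$habitat[cbind(cells[, "y"] + 1L, cells[, "x"] + 1L)] <- 0L
  }
  list(landscape = landscape,
       removed = sort(c(as.integer(already_removed), as.integer(chosen))))
}
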