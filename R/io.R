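#' Write and read landscapes as plain-text rasters
#'
#' A landscape is stored as two whitespace-separated integer grids, one
#' row of cells per line: `<path>.fields.txt` (field ids) and
#' `<path>.habitat.txt` (0 = CROP, 1 = WILD).  Each file starts with a
#' 3-line `#` header recording the dimensions, an optional note (e.g. a
#' manipulation schedule and assay point), and the coordinate convention
#' (0-based, x = column, y = row, origin top-left).  `write` followed by
#' `read` reproduces the grids exactly; seed points are not stored, so a
#' read-back landscape has `seeds = NULL`.
#'
#' @param landscape An `hw_landscape`.
#' @param path Base path; the two suffixes are appended.
#' @param note Free-text note stored in the header.
#' @return `write_landscape_raster()` invisibly returns the two file
#'   paths; `read_landscape_raster()` returns an `hw_landscape`.
#' @export
write_landscape_raster <- function(landscape, path, note = "") {
  stopifnot(inherits(landscape, "hw_landscape"))
  files <- paste0(path, c(".fields.txt", ".habitat.txt"))
  grids <- list(landscape$field, landscape$habitat)
  kinds <- c("field ids", "habitat (0=CROP 1=WILD)")
  for (i in 1:2) {
    con <- file(files[i], "w")
    writeLines(c(
      sprintf("# hedgewalk landscape raster: %s", kinds[i]),
      sprintf("# width=%d height=%d %s", landscape$width, landscape$height,
              note),
      "# 0-based coordinates, x=column, y=row, origin top-left; one grid row per line"),
      con)
    utils::write.table(grids[[i]], con, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(files)
}

#' @rdname write_landscape_raster
#' @export
read_landscape_raster <- function(path) {
  files <- paste0(path, c(".fields.txt", ".habitat.txt"))
  grids <- lapply(files, function(f) {
    if (!file.exists(f)) stop("missing raster file: ", f)
    hdr <- readLines(f, n = 3L)
    if (length(hdr) < 3L || !all(startsWith(hdr, "#")))
      stop("format error: expected a 3-line # header in ", f)
    dims <- regmatches(hdr[2L],
                       regexec("width=([0-9]+) height=([0-9]+)", hdr[2L]))[[1L]]
    if (length(dims) != 3L)
      stop("format error: header of ", f, " lacks width/height")
    w <- as.integer(dims[2L]); h <- as.integer(dims[3L])
    body <- utils::read.table(f, comment.char = "#")
    m <- as.matrix(body)
    if (any(m != floor(m)) || anyNA(m))
      stop("format error: non-integer cells in ", f)
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    if (nrow(m) != h || ncol(m) != w)
      stop("format error: header dimensions disagree with body in ", f)
    m
  })
  if (!identical(dim(grids[[1L]]), dim(grids[[2L]])))
    stop("format error: field and habitat grids have different dimensions")
  if (!all(grids[[2L]] %in% c(0L, 1L)))
    stop("format error: habitat values outside {0, 1}")
  new_landscape(ncol(grids[[1L]]), nrow(grids[[1L]]), NULL,
                grids[[1L]], grids[[2L]])
}

#' Export the habitat grid as a PGM image
#'
#' Writes the habitat map in the plain (P2) portable graymap format for
#' quick visual inspection: crop cells are white, wild cells black,
#' matching the usual sketch convention.
#'
#' @param landscape An `hw_landscape`.
#' @param path Output file path.
#' @export
write_pgm <- function(landscape, path) {
  stopifnot(inherits(landscape, "hw_landscape"))
  con <- file(path, "w")
  writeLines(c("P2",
               sprintf("%d %d", landscape$width, landscape$height), "1"),
             con)
  utils::write.table(1L - landscape$habitat, con,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Write and read results tables as CSV
#'
#' One header line, one row per walk; the protocol, master seed and
#' redraw counters are stored as leading `#` comment lines so that a
#' round trip preserves them.
#'
#' @param table An `hw_results` data frame.
#' @param path Output file path.
#' @return `write_results_csv()` invisibly returns `path`;
#'   `read_results_csv()` an `hw_results` data frame.
#' @export
write_results_csv <- function(table, path) {
  con <- file(path, "w")
  writeLines(sprintf("# protocol=%s seed=%s redraws=%d nest_redraws=%d",
                     attr(table, "protocol") %||% "NA",
                     format(attr(table, "seed") %||% NA),
                     attr(table, "redraws") %||% 0L,
                     attr(table, "nest_redraws") %||% 0L), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#")
  proto <- sub(".*protocol=([^ ]+).*", "\\1", hdr)
  seed <- suppressWarnings(as.integer(sub(".*seed=([^ ]+).*", "\\1", hdr)))
  new_results(df, proto, seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Box plots of a movement statistic across predictor levels
#'
#' Standard median/quartile/whisker box plots, one box per level of the
#' manipulated variable, in the layout used to display protocol results.
#'
#' @param table Results data frame.
#' @param response Column name of the statistic to plot.
#' @param predictor Column name of the manipulated variable.
#' @param path Optional file path; when given the figure is saved there
#'   (format from the extension).
#' @param width,height Device size in inches when saving.
#' @return The ggplot object, invisibly when saved.
#' @export
plot_boxplots <- function(table, response, predictor, path = NULL,
                          width = 6, height = 4) {
  df <- as.data.frame(table)
  if (nrow(df) == 0L) stop("empty results table")
  for (col in c(response, predictor))
    if (!col %in% names(df)) stop("column `", col, "` not found in table")
  df$.level <- factor(format(df[[predictor]], digits = 3),
                      levels = format(sort(unique(df[[predictor]])),
                                      digits = 3))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$.level,
                                        y = .data[[response]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = predictor, y = response) +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}
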