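# Marked point patterns: stroma pixel centres plus binary-marked tumor cells.

#' Construct a marked point pattern
#'
#' The spatial-statistics input: stroma pixel centres and tumor cell centres
#' with a binary marker (e.g. BrdU positive/negative) inside a rectangular
#' observation window.
#'
#' @param window Numeric `c(width_um, height_um)` of the observation window
#'   (half-open, origin at 0).
#' @param stroma Data frame with columns `x_um`, `y_um` of stroma pixel
#'   centres.
#' @param cells Data frame with columns `x_um`, `y_um`, `marker`; `marker`
#'   must be `"pos"` or `"neg"`.
#' @return An object of class `point_pattern`.
#' @export
point_pattern <- function(window, stroma, cells) {
  window <- as.numeric(window)
  if (length(window) != 2L || any(window <= 0))
    stop("`window` must be two positive extents (um)")
  stroma <- as.data.frame(stroma)
  cells <- as.data.frame(cells)
  if (nrow(stroma) && !all(c("x_um", "y_um") %in% names(stroma)))
    stop("`stroma` needs columns x_um, y_um")
  if (nrow(cells) && !all(c("x_um", "y_um", "marker") %in% names(cells)))
    stop("`cells` needs columns x_um, y_um, marker")
  inside <- function(df) {
    !nrow(df) || all(df$x_um >= 0 & df$x_um < window[1] &
                     df$y_um >= 0 & df$y_um < window[2])
  }
  if (!inside(stroma) || !inside(cells))
    stop("all coordinates must lie inside the window")
  if (nrow(cells) && !all(cells$marker %in% c("pos", "neg")))
    stop("`marker` must be \"pos\" or \"neg\"")
  structure(list(window = window, stroma = stroma, cells = cells),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf(
    "point_pattern: %.0f x %.0f um window, %d stroma pixels, %d cells (%d pos / %d neg)\n",
    x$window[1], x$window[2], nrow(x$stroma), nrow(x$cells),
    sum(x$cells$marker == "pos"), sum(x$cells$marker == "neg")))
  invisible(x)
}

#' Read or write a point-table CSV
#'
#' The on-disk exchange format for point patterns: columns
#' `x_um, y_um, type, marker` where `type` is `cell` or `stroma` and
#' `marker` is `pos`, `neg` or `NA` (stroma rows).
#'
#' @param path CSV path.
#' @param window Observation window `c(width, height)` in micrometres; for
#'   reading, defaults to the smallest window containing all points rounded
#'   up to whole micrometres.
#' @return `read_point_table()` returns a [point_pattern()];
#'   `write_point_table()` returns `path` invisibly.
#' @export
read_point_table <- function(path, window = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "type", "marker")
  if (!all(need %in% names(df)))
    stop("point table must have columns ", paste(need, collapse = ", "))
  if (is.null(window))
    window <- ceiling(c(max(df$x_um), max(df$y_um)) + 1e-9)
  st <- df[df$type == "stroma", c("x_um", "y_um")]
  ce <- df[df$type == "cell", c("x_um", "y_um", "marker")]
  point_pattern(window, st, ce)
}

#' @rdname read_point_table
#' @param pattern A [point_pattern()] to serialise.
#' @export
write_point_table <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  st <- pattern$stroma
  ce <- pattern$cells
  df <- rbind(
    if (nrow(st)) data.frame(x_um = st$x_um, y_um = st$y_um,
                             type = "stroma", marker = NA_character_),
    if (nrow(ce)) data.frame(x_um = ce$x_um, y_um = ce$y_um,
                             type = "cell", marker = as.character(ce$marker)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
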