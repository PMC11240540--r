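# Tissue geometry: lattice grids, label masks, stroma pixelation, niche maps.

#' Construct a tissue grid
#'
#' A tissue grid is the common substrate of the package: an integer lattice
#' whose sites are empty, occupied by a tumor cell, stroma, excluded
#' (micronecrotic), or inactivated stroma (see [STATE]). Each lattice cell is
#' a square of `cell_size` micrometres, the average tumor cell diameter.
#'
#' Lattice indices are 0-based in the physical convention: the centre of the
#' site in matrix row `i`, column `j` (1-based R indices) lies at
#' `((j - 0.5) * cell_size, (i - 0.5) * cell_size)` micrometres, with the
#' window being the half-open square `[0, ncol * cell_size)` by
#' `[0, nrow * cell_size)`.
#'
#' @param state Integer matrix of [STATE] codes (rows are y, columns are x).
#' @param cell_size Physical side of one lattice cell in micrometres.
#' @return An object of class `tissue_grid`: a list with elements `state`
#'   and `cell_size`.
#' @export
tissue_grid <- function(state, cell_size = 15) {
  if (!is.matrix(state)) stop("`state` must be a matrix")
  if (nrow(state) < 1L || ncol(state) < 1L) stop("grid must be at least 1x1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a positive scalar")
  storage.mode(state) <- "integer"
  bad <- setdiff(unique(as.vector(state)), unname(STATE))
  if (length(bad))
    stop("unknown state code(s): ", paste(bad, collapse = ", "))
  structure(list(state = state, cell_size = as.numeric(cell_size)),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  m <- stroma_metrics(x)
  cat(sprintf(
    "tissue_grid: %d x %d cells (%.0f x %.0f um at %.3g um/cell)\n",
    ncol(x$state), nrow(x$state),
    ncol(x$state) * x$cell_size, nrow(x$state) * x$cell_size, x$cell_size))
  cat(sprintf(
    "  tumor %d | stroma %d (%d inactive) | excluded %d | abundance %.3f, dispersal %.3f\n",
    sum(x$state == STATE[["tumor"]]),
    sum(x$state == STATE[["stroma"]] | x$state == STATE[["stroma_inactive"]]),
    sum(x$state == STATE[["stroma_inactive"]]),
    sum(x$state == STATE[["excluded"]]), m[["abundance"]], m[["dispersal"]]))
  invisible(x)
}

#' @export
dim.tissue_grid <- function(x) dim(x$state)

# sites that can hold a tumor cell
.tumor_capable <- function(state) {
  state == STATE[["empty"]] | state == STATE[["tumor"]]
}

.is_stroma <- function(state) {
  state == STATE[["stroma"]] | state == STATE[["stroma_inactive"]]
}

#' Load a segmented tissue mask
#'
#' Reads a label image (single-channel PNG or TIFF, palette
#' `0 = empty, 1 = tumor, 2 = stroma, 3 = excluded`) or a point-table CSV
#' (columns `x_um, y_um, type, marker` with `type` in `cell`/`stroma`) into a
#' [tissue_grid()]. Image pixel values stored on the unit scale are
#' multiplied by 255 before decoding, so masks written by [write_mask()]
#' round-trip exactly.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.csv` file.
#' @param cell_size Micrometres per lattice cell (and per mask pixel).
#' @param window For point tables only: physical window `c(width, height)`
#'   in micrometres; defaults to the smallest cell-aligned window containing
#'   all points.
#' @return A [tissue_grid()].
#' @export
load_mask <- function(path, cell_size = 15, window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (cell_size <= 0) stop("`cell_size` must be positive")
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(.grid_from_point_table(path, cell_size, window))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  codes <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  bad <- setdiff(unique(as.vector(codes)), unname(STATE[1:4]))
  if (length(bad))
    stop("unknown label code(s) in mask: ", paste(bad, collapse = ", "))
  tissue_grid(codes, cell_size = cell_size)
}

.grid_from_point_table <- function(path, cell_size, window) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "type")
  if (!all(need %in% names(df)))
    stop("point table must have columns x_um, y_um, type")
  if (!all(df$type %in% c("cell", "stroma")))
    stop("unknown `type` values in point table")
  if (is.null(window))
    window <- cell_size * ceiling(c(max(df$x_um), max(df$y_um)) / cell_size)
  nc <- as.integer(ceiling(window[1] / cell_size))
  nr <- as.integer(ceiling(window[2] / cell_size))
  state <- matrix(STATE[["empty"]], nr, nc)
  j <- pmin(nc, floor(df$x_um / cell_size) + 1L)
  i <- pmin(nr, floor(df$y_um / cell_size) + 1L)
  state[cbind(i[df$type == "stroma"], j[df$type == "stroma"])] <-
    STATE[["stroma"]]
  keep <- df$type == "cell"
  idx <- cbind(i[keep], j[keep])
  idx <- idx[state[idx] == STATE[["empty"]], , drop = FALSE]
  state[idx] <- STATE[["tumor"]]
  tissue_grid(state, cell_size = cell_size)
}

#' Write a tissue grid to a label mask
#'
#' Inverse of [load_mask()] for images. Inactive stroma (in-simulation code
#' 4) is written as plain stroma (code 2) since the on-disk palette is
#' `0..3`.
#'
#' @param grid A [tissue_grid()].
#' @param path Output path; format chosen by extension (`.png`, `.tif`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(grid, path) {
  stopifnot(inherits(grid, "tissue_grid"))
  codes <- grid$state
  codes[codes == STATE[["stroma_inactive"]]] <- STATE[["stroma"]]
  img <- codes / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported mask format: .", ext))
  invisible(path)
}

#' Pixelate a stroma raster into cell-sized tiles
#'
#' Converts a binary stroma raster at arbitrary resolution into the list of
#' stroma "pixels" used by the spatial statistics: the raster is tiled into
#' squares of `tile_um` (one average tumor cell diameter) and every tile
#' whose stroma coverage reaches `threshold` contributes its centre
#' coordinate. Tiles are laid from the raster origin; a tile partially
#' outside the raster is dropped.
#'
#' @param mask Logical or 0/1 matrix (rows are y), `TRUE`/1 = stroma.
#' @param px_size_um Micrometres per raster pixel. `tile_um` must be an
#'   integer multiple of it.
#' @param tile_um Tile side in micrometres (default 15).
#' @param threshold Minimum fraction of the tile area covered by stroma for
#'   the tile to count as a stroma pixel (default 0.5, unbiased rounding of
#'   a polygonal mask).
#' @return A data frame with columns `x_um`, `y_um` of tile centres.
#' @export
pixelate_stroma <- function(mask, px_size_um = 1, tile_um = 15,
                            threshold = 0.5) {
  if (!is.matrix(mask) || !length(mask)) stop("`mask` must be a non-empty matrix")
  if (tile_um <= 0 || px_size_um <= 0) stop("sizes must be positive")
  k <- tile_um / px_size_um
  if (abs(k - round(k)) > 1e-9)
    stop("`tile_um` must be an integer multiple of `px_size_um`")
  k <- as.integer(round(k))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  nty <- nrow(m) %/% k
  ntx <- ncol(m) %/% k
  if (nty < 1L || ntx < 1L) stop("tile larger than the raster window")
  m <- m[seq_len(nty * k), seq_len(ntx * k), drop = FALSE]
  # block means via two grouped row sums
  rows <- rowsum(m, rep(seq_len(nty), each = k))
  cov <- t(rowsum(t(rows), rep(seq_len(ntx), each = k))) / k^2
  hit <- which(cov >= threshold, arr.ind = TRUE)
  data.frame(x_um = (hit[, "col"] - 0.5) * tile_um,
             y_um = (hit[, "row"] - 0.5) * tile_um)
}

# shift a logical matrix by (dy, dx), padding with FALSE
.shift_logical <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  if (abs(dy) >= nr || abs(dx) >= nc) return(out)
  sr <- max(1L, 1L + dy):min(nr, nr + dy)
  sc <- max(1L, 1L + dx):min(nc, nc + dx)
  out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

#' Compute the peristromal niche map
#'
#' Marks every tumor-capable site lying within `distance_cells` lattice
#' cells of at least one active stroma site. Inactivated stroma generates no
#' niche; stroma and excluded sites themselves are never part of the niche.
#' With the default Chebyshev metric, "within 3 cells" is the 7x7 block
#' around each stroma site.
#'
#' @param grid A [tissue_grid()].
#' @param distance_cells Niche radius in lattice cells (>= 0).
#' @param metric `"chebyshev"` (default) or `"euclidean"` lattice distance.
#' @return An object of class `niche_map`: list with logical matrix
#'   `inside`, plus `distance_cells` and `metric`.
#' @export
compute_niche_map <- function(grid, distance_cells = 3,
                              metric = c("chebyshev", "euclidean")) {
  stopifnot(inherits(grid, "tissue_grid"))
  metric <- match.arg(metric)
  if (distance_cells < 0) stop("`distance_cells` must be non-negative")
  d <- as.integer(distance_cells)
  active <- grid$state == STATE[["stroma"]]
  acc <- matrix(FALSE, nrow(active), ncol(active))
  if (d > 0L && any(active)) {
    for (dy in -d:d) for (dx in -d:d) {
      if (dy == 0L && dx == 0L) next
      if (metric == "euclidean" && dy * dy + dx * dx > d * d) next
      acc <- acc | .shift_logical(active, dy, dx)
    }
  }
  acc[!.tumor_capable(grid$state)] <- FALSE
  structure(list(inside = acc, distance_cells = d, metric = metric),
            class = "niche_map")
}

#' Extract a simulation quadrant from a larger mask
#'
#' Cuts the axis-aligned square window starting at `origin_um` with side
#' `side_um` out of a larger grid, in the spirit of dividing a segmented
#' tumor cross-section into 1500 um x 1500 um quadrants that match the
#' simulation lattice (100 x 100 cells at 15 um).
#'
#' @param grid A [tissue_grid()].
#' @param origin_um Lower corner `c(x, y)` in micrometres; must be aligned
#'   to the lattice.
#' @param side_um Window side in micrometres (default 1500).
#' @return A [tissue_grid()] covering the requested window.
#' @export
extract_quadrant <- function(grid, origin_um = c(0, 0), side_um = 1500) {
  stopifnot(inherits(grid, "tissue_grid"))
  cs <- grid$cell_size
  o <- origin_um / cs
  n <- side_um / cs
  if (any(abs(o - round(o)) > 1e-9) || abs(n - round(n)) > 1e-9)
    stop("origin and side must align to the lattice")
  o <- as.integer(round(o)); n <- as.integer(round(n))
  if (any(o < 0L) || o[1] + n > ncol(grid$state) || o[2] + n > nrow(grid$state))
    stop("quadrant extends outside the source grid")
  tissue_grid(grid$state[o[2] + seq_len(n), o[1] + seq_len(n), drop = FALSE],
              cell_size = cs)
}

#' Stroma abundance and dispersal of a grid
#'
#' Abundance is the fraction of non-excluded lattice sites occupied by
#' stroma (active or inactivated). Dispersal is operationalised as the
#' boundary fraction of stroma: the fraction of stroma sites with at least
#' one non-stroma neighbour among their in-grid 8-neighbours, so many small
#' fragments score high and one compact blob scores low. An empty grid
#' returns `c(0, 0)`.
#'
#' @param grid A [tissue_grid()].
#' @return Named numeric vector `c(abundance, dispersal)`, both in `[0, 1]`.
#' @export
stroma_metrics <- function(grid) {
  stopifnot(inherits(grid, "tissue_grid"))
  st <- grid$state
  stroma <- .is_stroma(st)
  n_str <- sum(stroma)
  denom <- sum(st != STATE[["excluded"]])
  abundance <- if (denom > 0) n_str / denom else 0
  if (n_str == 0L) return(c(abundance = abundance, dispersal = 0))
  nonstroma <- !stroma
  boundary <- matrix(FALSE, nrow(st), ncol(st))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    boundary <- boundary | .shift_logical(nonstroma, dy, dx)
  }
  c(abundance = abundance, dispersal = sum(boundary & stroma) / n_str)
}
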