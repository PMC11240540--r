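# Synthetic tissue: stroma topologies with controlled abundance/dispersal,
# marker-labeled point patterns with peristromal enrichment, volume series.

# place n_seeds nuclei with a soft minimum separation (dart throwing with a
# bounded number of attempts, relaxing to uniform placement if packing
# fails); emulates the quasi-regular partitioning of tumor parenchyma by
# stromal septa
.place_seeds <- function(side, n_seeds, min_sep) {
  rows <- integer(0); cols <- integer(0)
  attempts <- 0L
  while (length(rows) < n_seeds && attempts < 200L * n_seeds) {
    attempts <- attempts + 1L
    r <- sample.int(side, 1L); c <- sample.int(side, 1L)
    if (!length(rows) ||
        min((rows - r)^2 + (cols - c)^2) >= min_sep^2) {
      rows <- c(rows, r); cols <- c(cols, c)
    }
  }
  while (length(rows) < n_seeds) {  # packing failed; fill uniformly
    rows <- c(rows, sample.int(side, 1L))
    cols <- c(cols, sample.int(side, 1L))
  }
  cbind(rows, cols)
}

# grow stroma from n_seeds nuclei to exactly `target_sites` sites by
# stochastic dilation (each stroma-adjacent free site converts with
# probability growth_p per iteration; the final iteration converts exactly
# as many sites as still needed)
.grow_stroma <- function(side, n_seeds, target_sites, growth_p, max_iter,
                         min_sep = 0) {
  state <- matrix(STATE[["empty"]], side, side)
  if (target_sites == 0L) return(state)
  n_seeds <- max(1L, min(n_seeds, target_sites))
  state[unique(.place_seeds(side, n_seeds, min_sep))] <- STATE[["stroma"]]
  for (it in seq_len(max_iter)) {
    n_now <- sum(state == STATE[["stroma"]])
    need <- target_sites - n_now
    if (need <= 0L) break
    stroma <- state == STATE[["stroma"]]
    adj <- matrix(FALSE, side, side)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      adj <- adj | .shift_logical(stroma, dy, dx)
    }
    cand <- which(adj & state == STATE[["empty"]])
    if (!length(cand))
      stop("stroma growth stalled before reaching the abundance target")
    chosen <- cand[runif(length(cand)) < growth_p]
    if (length(chosen) >= need)
      chosen <- if (need == length(chosen)) chosen else sample(chosen, need)
    state[chosen] <- STATE[["stroma"]]
  }
  if (sum(state == STATE[["stroma"]]) != target_sites)
    stop("stroma growth did not converge within max_iter iterations")
  state
}

#' Generate a synthetic stroma topology
#'
#' Places `n_seeds` random stroma nuclei on an initially empty lattice and
#' grows them by stochastic dilation until the requested abundance is met
#' exactly (the last iteration converts exactly the number of sites still
#' needed). Dispersal -- the boundary fraction of stroma measured by
#' [stroma_metrics()] -- is controlled by the number of fragments: many
#' small blobs give a high boundary fraction, few large blobs a low one.
#' When `dispersal` is supplied instead of `n_seeds`, the generator
#' bisects on the seed count and fails loudly (naming the achieved metrics)
#' if the target cannot be approached, since high abundance geometrically
#' caps the reachable dispersal.
#'
#' Seed nuclei are placed with a soft minimum separation (by default
#' `0.7 * side / sqrt(n_seeds)` cells), emulating the quasi-regular
#' partitioning of tumor parenchyma by stromal septa rather than a fully
#' Poisson scatter; set `seed_min_sep = 0` for uniform placement.
#'
#' @param abundance Target stroma abundance, a fraction of lattice sites.
#' @param dispersal Optional target dispersal (boundary fraction).
#' @param n_seeds Number of stroma nuclei (default 60, a finely dispersed
#'   septal topology); ignored when `dispersal` is given.
#' @param side Grid side in cells (default 100).
#' @param cell_size Micrometres per cell (default 15).
#' @param growth_p Per-iteration conversion probability of a stroma-adjacent
#'   free site (default 0.5; controls boundary roughness).
#' @param seed_min_sep Minimum seed separation in cells; `NULL` = auto.
#' @param tol_dispersal Acceptable |achieved - target| dispersal when a
#'   target is given (default 0.08).
#' @param max_iter Dilation iteration cap.
#' @return A [tissue_grid()] with attribute `"achieved"` holding the
#'   realised `c(abundance, dispersal)` and the seed count used.
#' @export
gen_stroma_topology <- function(abundance, dispersal = NULL, n_seeds = 60,
                                side = 100, cell_size = 15, growth_p = 0.5,
                                seed_min_sep = NULL,
                                tol_dispersal = 0.08, max_iter = 500) {
  if (abundance < 0 || abundance >= 1) stop("`abundance` must be in [0, 1)")
  target_sites <- as.integer(round(abundance * side * side))
  if (target_sites == 0L) {
    g <- tissue_grid(matrix(STATE[["empty"]], side, side), cell_size)
    attr(g, "achieved") <- list(abundance = 0, dispersal = 0, n_seeds = 0L)
    return(g)
  }
  sep_for <- function(k) {
    if (!is.null(seed_min_sep)) seed_min_sep else 0.7 * side / sqrt(k)
  }
  if (is.null(dispersal)) {
    state <- .grow_stroma(side, n_seeds, target_sites, growth_p, max_iter,
                          sep_for(n_seeds))
    g <- tissue_grid(state, cell_size)
    m <- stroma_metrics(g)
    attr(g, "achieved") <- list(abundance = m[["abundance"]],
                                dispersal = m[["dispersal"]],
                                n_seeds = n_seeds)
    return(g)
  }
  if (dispersal <= 0 || dispersal > 1) stop("`dispersal` must be in (0, 1]")
  # dispersal increases with fragment count: bisect on n_seeds
  lo <- 1L
  hi <- max(2L, target_sites %/% 2L)
  make <- function(k) {
    state <- .grow_stroma(side, k, target_sites, growth_p, max_iter,
                          sep_for(k))
    g <- tissue_grid(state, cell_size)
    list(grid = g, m = stroma_metrics(g))
  }
  best <- NULL
  for (it in 1:12) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    res <- make(mid)
    if (is.null(best) ||
        abs(res$m[["dispersal"]] - dispersal) <
        abs(best$m[["dispersal"]] - dispersal)) {
      best <- res
      best$n_seeds <- mid
    }
    if (abs(res$m[["dispersal"]] - dispersal) < 0.01) break
    if (res$m[["dispersal"]] < dispersal) lo <- mid else hi <- mid
    if (hi - lo <= 1L) break
  }
  if (abs(best$m[["dispersal"]] - dispersal) > tol_dispersal)
    stop(sprintf(
      paste0("infeasible topology spec: target abundance %.3f / dispersal ",
             "%.3f; best achieved abundance %.3f / dispersal %.3f"),
      abundance, dispersal, best$m[["abundance"]], best$m[["dispersal"]]))
  g <- best$grid
  attr(g, "achieved") <- list(abundance = best$m[["abundance"]],
                              dispersal = best$m[["dispersal"]],
                              n_seeds = best$n_seeds)
  g
}

#' Generate a marker-labeled point pattern with peristromal enrichment
#'
#' Emulates a segmented, marker-stained tissue section: tumor cells are
#' scattered uniformly over the tumor-capable sites of `grid` (at most one
#' per site, jittered uniformly within the site so distances are
#' continuous), and each receives a positive marker with probability
#' `base_positive` outside the peristromal protection halo and
#' `min(1, base_positive * enrichment)` inside it. The halo is evaluated at
#' the cell's actual (jittered) position: a cell is protected when its
#' distance to the nearest active stroma pixel centre is at most
#' `niche_width` cell diameters, by default in the euclidean metric, the
#' natural model for an isotropically diffusing paracrine factor (the
#' lattice simulator uses the discrete site-based niche of
#' [compute_niche_map()] instead). With `enrichment = 1` the labels carry
#' no spatial information (the baseline, CSR-like situation); larger
#' values emulate the therapy-induced proliferation bias toward the
#' stroma.
#'
#' @param grid A [tissue_grid()] carrying the stroma.
#' @param n_cells Number of tumor cells to place.
#' @param base_positive Marker-positive probability outside the niche.
#' @param enrichment Multiplicative enrichment of the positive probability
#'   inside the niche (>= 1; clipped at probability 1).
#' @param niche_width Halo radius in cell diameters (default 3).
#' @param metric `"euclidean"` (default) or `"chebyshev"` distance from
#'   cell position to stroma pixel centres.
#' @return A [point_pattern()] whose stroma points are the active stroma
#'   site centres; attribute `"truth"` records each cell's site, its
#'   distance to the nearest stroma pixel and its true halo membership for
#'   recovery tests.
#' @export
gen_labeled_pattern <- function(grid, n_cells = 5000, base_positive = 0.05,
                                enrichment = 5, niche_width = 3,
                                metric = c("euclidean", "chebyshev")) {
  stopifnot(inherits(grid, "tissue_grid"))
  metric <- match.arg(metric)
  if (base_positive < 0 || base_positive > 1)
    stop("`base_positive` must be in [0, 1]")
  if (enrichment < 0) stop("`enrichment` must be non-negative")
  cs <- grid$cell_size
  free <- which(.tumor_capable(grid$state))
  if (n_cells > length(free))
    stop("`n_cells` exceeds the number of tumor-capable sites")
  sites <- sample(free, n_cells)
  nr <- nrow(grid$state)
  row <- (sites - 1L) %% nr + 1L
  col <- (sites - 1L) %/% nr + 1L
  x <- (col - 1L) * cs + runif(n_cells, 0, cs)
  y <- (row - 1L) * cs + runif(n_cells, 0, cs)
  stroma_idx <- which(grid$state == STATE[["stroma"]])
  srow <- (stroma_idx - 1L) %% nr + 1L
  scol <- (stroma_idx - 1L) %/% nr + 1L
  sx <- (scol - 0.5) * cs
  sy <- (srow - 0.5) * cs
  dmin <- rep(Inf, n_cells)
  for (s in seq_along(sx)) {
    d <- if (metric == "euclidean")
      sqrt((sx[s] - x)^2 + (sy[s] - y)^2)
    else
      pmax(abs(sx[s] - x), abs(sy[s] - y))
    dmin <- pmin(dmin, d)
  }
  in_niche <- dmin <= niche_width * cs
  p_pos <- ifelse(in_niche, pmin(1, base_positive * enrichment),
                  base_positive)
  marker <- ifelse(runif(n_cells) < p_pos, "pos", "neg")
  pat <- point_pattern(cs * c(ncol(grid$state), nr),
                       data.frame(x_um = sx, y_um = sy),
                       data.frame(x_um = x, y_um = y, marker = marker))
  attr(pat, "truth") <- data.frame(site = sites, dist_um = dmin,
                                   in_niche = in_niche, p_pos = p_pos)
  pat
}

#' Generate a synthetic tumor volume series
#'
#' Exponential growth `V(t) = V0 exp(r t)` with optional multiplicative
#' log-normal measurement noise of coefficient of variation `noise_cv`
#' (zero-mean on the log scale, so the log-linear fit is unbiased).
#'
#' @param V0 Initial volume, mm^3 (> 0).
#' @param r Net growth rate per day (negative for decay).
#' @param times Measurement days (default weekly over four weeks).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0 = exact).
#' @return Data frame with columns `day`, `volume_mm3`.
#' @export
gen_volume_series <- function(V0 = 100, r = 0.192,
                              times = c(0, 7, 14, 21, 28), noise_cv = 0) {
  if (V0 <= 0) stop("`V0` must be positive")
  if (noise_cv < 0) stop("`noise_cv` must be non-negative")
  v <- V0 * exp(r * times)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    v <- v * exp(rnorm(length(times), 0, sdlog))
  }
  data.frame(day = times, volume_mm3 = v)
}
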