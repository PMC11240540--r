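# Shared fixtures, built once per test run and cached.

fixture <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      cache[[name]] <<- switch(name,
        # reference synthetic topologies (100 x 100 cells, 15 um/cell)
        topo10 = { set.seed(1101); gen_stroma_topology(0.10) },
        topo06_hi = { set.seed(1102); gen_stroma_topology(0.06, dispersal = 0.9) },
        topo06_lo = { set.seed(1103); gen_stroma_topology(0.06, dispersal = 0.7) },
        topo15 = { set.seed(1104); gen_stroma_topology(0.15) },
        # small, quick grid for ABM behaviour tests
        topo_small = { set.seed(1105); gen_stroma_topology(0.10, n_seeds = 15, side = 40) },
        stop("unknown fixture: ", name))
    }
    cache[[name]]
  }
})

# brute-force per-stroma-pixel RDF (independent of the package's binning):
# explicit double loop over annuli and points
rdf_oracle <- function(pattern, marker, w, r_max, normalization = "csr") {
  A <- floor(r_max / w)
  sx <- pattern$stroma$x_um; sy <- pattern$stroma$y_um
  cx <- pattern$cells$x_um;  cy <- pattern$cells$y_um
  is_m <- pattern$cells$marker == marker
  S <- length(sx); n <- length(cx); nm <- sum(is_m)
  per_pixel <- matrix(0, S, A)   # marker counts
  per_tot <- matrix(0, S, A)
  for (s in seq_len(S)) {
    d <- sqrt((sx[s] - cx)^2 + (sy[s] - cy)^2)
    for (a in seq_len(A)) {
      in_ann <- d > (a - 1) * w & d <= a * w
      per_tot[s, a] <- sum(in_ann)
      per_pixel[s, a] <- sum(in_ann & is_m)
    }
  }
  if (normalization == "csr") {
    ratio <- ifelse(per_tot > 0, per_pixel / per_tot, 0)
    colMeans(ratio) * n / nm
  } else if (normalization == "pooled") {
    tot <- colSums(per_tot)
    (colSums(per_pixel) / ifelse(tot > 0, tot, NA)) * n / nm
  } else {
    r_out <- w * seq_len(A)
    area <- pi * (r_out^2 - (r_out - w)^2)
    colSums(per_pixel) / (S * (nm / prod(pattern$window)) * area)
  }
}

# small random point pattern for oracle comparisons
random_pattern <- function(n_stroma, n_cells, window = c(300, 300),
                           p_pos = 0.4) {
  point_pattern(
    window,
    data.frame(x_um = runif(n_stroma, 0, window[1]),
               y_um = runif(n_stroma, 0, window[2])),
    data.frame(x_um = runif(n_cells, 0, window[1]),
               y_um = runif(n_cells, 0, window[2]),
               marker = ifelse(runif(n_cells) < p_pos, "pos", "neg")))
}

# uniform grid with a single tumor cell at the centre, everything else empty
single_cell_grid <- function(side = 5) {
  st <- matrix(STATE[["empty"]], side, side)
  mid <- (side + 1) %/% 2
  st[mid, mid] <- STATE[["tumor"]]
  tissue_grid(st)
}
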