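# In silico EMDR perturbation experiments: magnitude / distance / producer
# sweeps, residual-size quantification and exponential decay-rate impacts.

#' Normalized residual disease size
#'
#' The residual size of a completed run relative to the mean baseline
#' population ("% of control" scale as a fraction). The baseline occupancy
#' relative to carrying capacity (tumor-capable site count) is attached as
#' an attribute when a grid is supplied.
#'
#' @param run An `abm_run` from [run_abm()].
#' @param baseline_mean Baseline mean population used for normalisation
#'   (default: the run's own).
#' @param grid Optional [tissue_grid()] to report baseline occupancy
#'   against carrying capacity.
#' @return Normalized residual (final population / baseline mean).
#' @export
residual_size <- function(run, baseline_mean = run$baseline_mean,
                          grid = NULL) {
  stopifnot(inherits(run, "abm_run"))
  if (baseline_mean <= 0) stop("`baseline_mean` must be positive")
  out <- run$final_n / baseline_mean
  if (!is.null(grid)) {
    capacity <- sum(.tumor_capable(grid$state))
    attr(out, "baseline_occupancy") <- baseline_mean / capacity
  }
  out
}

# apply a perturbation level for one EMDR aspect
.apply_level <- function(params, aspect, level) {
  switch(aspect,
    magnitude = {
      params$p_div_therapy_niche <- params$p_div_therapy_out +
        level * (params$p_div_therapy_niche - params$p_div_therapy_out)
      params
    },
    distance = {
      params$niche_distance <- as.integer(round(level *
                                                params$niche_distance))
      params
    },
    producer = {
      params$producer_fraction <- level
      params
    },
    stop("unknown aspect: ", aspect))
}

#' Sweep one EMDR aspect and quantify residual disease
#'
#' Emulates a hypothetical EMDR-targeting intervention: for each level in
#' `[0, 1]` (1 = unperturbed EMDR, 0 = aspect fully removed) the aspect is
#' interpolated -- `magnitude` scales the niche division boost,
#' `distance` rounds `level * niche_distance` to whole cells, and
#' `producer` sets the fraction of EMDR-producing stroma (each replicate
#' inactivating its own random subset) -- and `n_reps` replicates are run.
#' Residuals are normalized to the mean baseline population at that level.
#'
#' @param grid A [tissue_grid()] with the stromal topology.
#' @param params Base [abm_params()] (full-EMDR therapy parameters).
#' @param aspect `"magnitude"`, `"distance"` or `"producer"`.
#' @param levels Perturbation levels, fractions of the full effect.
#' @param n_reps Replicates per level (default `params$n_reps`).
#' @param seed Master seed.
#' @return An object of class `sweep_result`: data frame `aspect, level,
#'   residual_mean, residual_sd, n_reps, extinct`, with the fitted decay
#'   rate (see [fit_decay()]) in attribute `"decay_rate"`.
#' @export
sweep_emdr <- function(grid, params = abm_params(),
                       aspect = c("magnitude", "distance", "producer"),
                       levels = c(0, 0.25, 0.5, 0.75, 1),
                       n_reps = params$n_reps, seed = NULL) {
  stopifnot(inherits(grid, "tissue_grid"))
  aspect <- match.arg(aspect)
  if (any(levels < 0 | levels > 1)) stop("`levels` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  levels <- sort(levels)
  rows <- lapply(levels, function(lv) {
    ens <- run_abm_reps(grid, .apply_level(params, aspect, lv), n_reps)
    base <- mean(ens$reps$baseline_mean)
    data.frame(aspect = aspect, level = lv,
               residual_mean = mean(ens$reps$final_n) / base,
               residual_sd = sd(ens$reps$final_n) / base,
               n_reps = n_reps, extinct = sum(ens$reps$extinct),
               baseline_mean = base)
  })
  out <- do.call(rbind, rows)
  k <- if (length(levels) >= 3)
    fit_decay(out$level, out$residual_mean,
              floor = 0.5 / mean(out$baseline_mean)) else NA_real_
  structure(out, class = c("sweep_result", "data.frame"), decay_rate = k)
}

#' Fit an exponential decay of residual size to perturbation strength
#'
#' Fits `R(x) = R0 * exp(-k x)` by least squares on the log scale, where
#' `x = 1 - level` is the reduction magnitude of the EMDR aspect. Larger
#' `k` means the residual disease collapses faster as the aspect is
#' targeted, i.e. a stronger impact of that aspect. Residuals below
#' `floor` (extinct conditions, whose log is undefined) are floored at
#' `floor` and flagged.
#'
#' @param levels Perturbation levels in `[0, 1]`.
#' @param residual_means Mean normalized residual per level (>= 0).
#' @param floor Positive floor applied before the log transform (on the
#'   same scale as `residual_means`); `NULL` demands all-positive input.
#' @return Decay rate `k` (per unit reduction), with attributes `R0` and
#'   `n_floored`.
#' @export
fit_decay <- function(levels, residual_means, floor = NULL) {
  if (length(levels) < 3) stop("need at least 3 levels")
  if (length(levels) != length(residual_means)) stop("length mismatch")
  if (any(residual_means < 0)) stop("residuals must be non-negative")
  y <- residual_means
  n_floored <- 0L
  if (!is.null(floor)) {
    n_floored <- sum(y < floor)
    y <- pmax(y, floor)
  }
  if (any(y <= 0)) stop("all residuals are zero below the floor; k undefined")
  x <- 1 - levels
  fit <- lm(log(y) ~ x)
  structure(-unname(coef(fit)[2]), R0 = exp(unname(coef(fit)[1])),
            n_floored = n_floored)
}

#' Compare EMDR perturbation impacts across stromal topologies
#'
#' Runs [sweep_emdr()] for every (topology, aspect) combination and
#' tabulates the fitted decay rates, the comparison used to rank which
#' EMDR aspect most strongly controls residual disease in which stromal
#' architecture.
#'
#' @param topologies Named list of [tissue_grid()] objects.
#' @param params Base [abm_params()].
#' @param aspects Aspects to sweep (default all three).
#' @param levels Perturbation levels.
#' @param n_reps Replicates per level.
#' @param seed Master seed.
#' @return Data frame `topology, aspect, decay_rate, abundance, dispersal`.
#' @export
compare_topologies <- function(topologies, params = abm_params(),
                               aspects = c("magnitude", "distance",
                                           "producer"),
                               levels = c(0, 0.25, 0.5, 0.75, 1),
                               n_reps = params$n_reps, seed = NULL) {
  if (length(topologies) < 2) stop("need at least two topologies")
  if (is.null(names(topologies)))
    names(topologies) <- paste0("topology_", seq_along(topologies))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (nm in names(topologies)) {
    m <- stroma_metrics(topologies[[nm]])
    for (a in aspects) {
      sw <- sweep_emdr(topologies[[nm]], params, a, levels, n_reps)
      rows[[length(rows) + 1L]] <- data.frame(
        topology = nm, aspect = a,
        decay_rate = as.numeric(attr(sw, "decay_rate")),
        abundance = m[["abundance"]], dispersal = m[["dispersal"]])
    }
  }
  do.call(rbind, rows)
}
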