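# Net growth, proliferation and death rates from volumetrics and BrdU.

#' Fit an exponential growth law to a volume series
#'
#' Tumor volume is taken as a proxy for population size under constant cell
#' density, `V(t) = V0 * exp(r t)`. The default fit is ordinary least
#' squares of `log(V)` on `t`, which is closed-form and exact on noiseless
#' series; `method = "nls"` refits the same model on the natural scale by
#' nonlinear least squares starting from the log-linear solution.
#'
#' @param times Days, strictly increasing, at least two points.
#' @param volumes Tumor volumes in mm^3, strictly positive.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return Net growth rate `r` per day (negative for decaying series), with
#'   attribute `V0` (fitted initial volume).
#' @export
fit_exponential <- function(times, volumes, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (length(times) < 2L || length(times) != length(volumes))
    stop("need at least two matched (time, volume) points")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("`times` must be finite and strictly increasing")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("`volumes` must be finite and positive")
  fit <- lm(log(volumes) ~ times)
  r <- unname(coef(fit)[2])
  v0 <- exp(unname(coef(fit)[1]))
  if (method == "nls") {
    nl <- try(stats::nls(volumes ~ v * exp(k * times),
                         start = list(v = v0, k = r)), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      r <- unname(coef(nl)[["k"]])
      v0 <- unname(coef(nl)[["v"]])
    }
  }
  structure(r, V0 = v0)
}

#' Per-animal exponential fits
#'
#' Fits each animal's volume series separately and reports the mean rate
#' alongside the per-animal estimates (matching per-tumor scatter plots);
#' `pooled = TRUE` instead fits one line through all points.
#'
#' @param df Data frame with columns `day`, `volume_mm3` and optionally
#'   `animal_id` (a single animal is assumed if absent).
#' @param pooled Fit all points jointly instead of per animal.
#' @return List with `per_animal` (data frame `animal_id`, `r`) and `r_mean`.
#' @export
fit_growth_rates <- function(df, pooled = FALSE) {
  if (!all(c("day", "volume_mm3") %in% names(df)))
    stop("`df` needs columns day, volume_mm3")
  if (is.null(df$animal_id)) df$animal_id <- "animal_1"
  if (pooled) {
    if (any(df$volume_mm3 <= 0)) stop("volumes must be positive")
    r <- unname(coef(lm(log(volume_mm3) ~ day, df))[2])
    return(list(per_animal = data.frame(animal_id = "pooled", r = r),
                r_mean = r))
  }
  per <- lapply(split(df, df$animal_id), function(a) {
    a <- a[order(a$day), ]
    as.numeric(fit_exponential(a$day, a$volume_mm3))
  })
  per_df <- data.frame(animal_id = names(per), r = unlist(per),
                       row.names = NULL)
  list(per_animal = per_df, r_mean = mean(per_df$r))
}

#' Proliferation rate from a BrdU labeling index
#'
#' A BrdU pulse marks cells in S phase; with an S-phase duration of
#' `s_phase_hours` (default 8 h), the per-day proliferation rate is the
#' labeling index scaled by `24 / s_phase_hours` (a factor of 3 at the
#' default).
#'
#' @param index BrdU positivity index, a fraction in `[0, 1]`.
#' @param s_phase_hours S-phase duration in hours (> 0).
#' @return Proliferation rate `p` per day.
#' @export
proliferation_from_brdu <- function(index, s_phase_hours = 8) {
  if (any(index < 0 | index > 1)) stop("`index` must be in [0, 1]")
  if (s_phase_hours <= 0) stop("`s_phase_hours` must be positive")
  index * 24 / s_phase_hours
}

#' Death rate from proliferation and net growth rates
#'
#' The net growth rate decomposes as growth minus loss, \eqn{r = p - d},
#' so the death rate is `d = p - r`: for a regressing tumor (negative `r`)
#' death exceeds proliferation.
#'
#' @param p Proliferation rate per day.
#' @param r Net growth rate per day.
#' @return Death rate `d` per day.
#' @export
death_rate <- function(p, r) p - r

#' Bundle rate estimates
#'
#' @param r Net growth rate per day.
#' @param p Proliferation rate per day (>= 0).
#' @param s_phase_hours S-phase duration used for `p`, hours.
#' @return A `rate_estimates` list with `r`, `p`, `d = p - r`, `s_phase_hours`.
#' @export
rate_estimates <- function(r, p, s_phase_hours = 8) {
  if (p < 0) stop("`p` must be non-negative")
  structure(list(r = r, p = p, d = death_rate(p, r),
                 s_phase_hours = s_phase_hours),
            class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf("rates per day: net growth r = %.3f, proliferation p = %.3f, death d = %.3f (S phase %g h)\n",
              x$r, x$p, x$d, x$s_phase_hours))
  invisible(x)
}
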