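# Enzyme-kinetics fitting: Michaelis-Menten nonlinear regression with Wald
# 95% confidence intervals, competitive-inhibition Ki, catalytic efficiency
# at the report precision, and activity-optimum ranges.

#' Construct a Michaelis-Menten fit object
#'
#' Normally produced by [fit_mm()]; the constructor is exported so printed
#' parameter tables can be wrapped for downstream arithmetic such as
#' [catalytic_efficiency()].
#'
#' @param km Michaelis constant (mM).
#' @param kcat turnover number (1/s).
#' @param ci95_km,ci95_kcat half-widths of the 95% confidence intervals.
#' @param residual_sd residual standard deviation of the fit.
#' @param n number of points fitted.
#' @return A list of class `mm_fit`; `efficiency` is always `kcat / km`.
#' @export
mm_fit <- function(km, kcat, ci95_km = NA_real_, ci95_kcat = NA_real_,
                   residual_sd = NA_real_, n = NA_integer_) {
  if (km <= 0 || kcat <= 0) stop("km and kcat must be > 0", call. = FALSE)
  structure(list(km = km, kcat = kcat, efficiency = kcat / km,
                 ci95_km = ci95_km, ci95_kcat = ci95_kcat,
                 residual_sd = residual_sd, n = n),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: K_M = %.4g +/- %.2g mM, k_cat = %.4g +/- %.2g 1/s, k_cat/K_M = %s 1/(s mM)\n",
              x$km, x$ci95_km, x$kcat, x$ci95_kcat,
              format(catalytic_efficiency(x))))
  invisible(x)
}

# Hanes-Woolf linearization S/v = S/Vmax + Km/Vmax: deterministic,
# derivative-free start for the nonlinear refinement.
hanes_woolf_start <- function(S, v) {
  ok <- v > 0
  if (sum(ok) < 2L) return(list(vmax = max(v, 1e-8), km = stats::median(S)))
  fit <- lm(I(S[ok] / v[ok]) ~ S[ok])
  slope <- coef(fit)[[2]]; intercept <- coef(fit)[[1]]
  vmax <- if (slope > 0) 1 / slope else max(v)
  km <- if (slope > 0 && intercept > 0) intercept / slope else stats::median(S)
  list(vmax = max(vmax, 1e-8), km = max(km, 1e-8))
}

wald_ci <- function(fit) {
  se <- sqrt(diag(vcov(fit)))
  df <- stats::df.residual(fit)
  qt(0.975, df) * se
}

#' Fit the Michaelis-Menten model
#'
#' Nonlinear least squares for `v = kcat * E * S / (km + S)`, initialized by
#' the Hanes-Woolf linearization; 95% confidence intervals are Wald
#' intervals from the linearized covariance with the t quantile at the
#' residual degrees of freedom. Rates at or below zero are retained in the
#' loss, never clipped.
#'
#' @param data a [kinetics_dataset()] without inhibitor.
#' @return An [mm_fit()].
#' @export
fit_mm <- function(data) {
  stopifnot(inherits(data, "kinetics_dataset"))
  if (any(!is.na(data$I) & data$I > 0)) {
    stop("dataset contains inhibitor; use fit_ki_competitive()", call. = FALSE)
  }
  S <- data$S; v <- data$v
  if (all(v == 0)) stop("all rates are zero; nothing to fit", call. = FALSE)
  E <- attr(data, "enzyme_conc")
  if (length(unique(S)) < 3L) {
    warning("fewer than 3 distinct substrate concentrations; K_M is weakly determined")
  }
  start <- hanes_woolf_start(S, v)
  fit <- tryCatch(
    nls(v ~ vmax * S / (km + S),
        start = list(vmax = start$vmax, km = start$km),
        algorithm = "port", lower = c(vmax = 1e-12, km = 1e-12),
        control = nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) stop(sprintf(
      "Michaelis-Menten fit did not converge (%s); last start vmax=%.4g km=%.4g",
      conditionMessage(e), start$vmax, start$km), call. = FALSE))
  est <- coef(fit)
  if (min(est["km"], est["vmax"]) <= 0) stop("degenerate fit", call. = FALSE)
  ci <- wald_ci(fit)
  est_km <- unname(est["km"])
  if (est_km < min(S) || est_km > max(S)) {
    warning("fitted K_M lies outside the sampled substrate range; design does not span it")
  }
  mm_fit(km = est_km, kcat = unname(est["vmax"]) / E,
         ci95_km = unname(ci["km"]), ci95_kcat = unname(ci["vmax"]) / E,
         residual_sd = summary(fit)$sigma, n = length(v))
}

#' Fit a competitive-inhibition constant
#'
#' Model `v = kcat * E * S / (km * (1 + I / ki) + S)`. With `km`/`kcat`
#' supplied (or an uninhibited subset present, from which they are fitted),
#' only `ki` is estimated; with `cofit = TRUE` all three parameters are
#' estimated jointly.
#'
#' @param data a [kinetics_dataset()] with an `I` column, including `I = 0`
#'   points unless `km` and `kcat` are given.
#' @param km,kcat optionally fixed parameters (mM, 1/s).
#' @param cofit estimate km and kcat jointly with ki.
#' @return A list of class `ki_fit`: `ki`, `ci95_ki`, `km`, `kcat`,
#'   `cofitted`, `n`.
#' @export
fit_ki_competitive <- function(data, km = NULL, kcat = NULL, cofit = FALSE) {
  stopifnot(inherits(data, "kinetics_dataset"))
  if (all(is.na(data$I)) || !any(data$I > 0, na.rm = TRUE)) {
    stop("no inhibitor present in any point", call. = FALSE)
  }
  E <- attr(data, "enzyme_conc")
  d <- as.data.frame(data)
  d$I[is.na(d$I)] <- 0
  ki_start <- function(km0, kcat0) {
    # crude inversion of the apparent-Km shift at the largest inhibitor level
    inh <- d[d$I > 0, ]
    app <- pmax(kcat0 * E * inh$S / pmax(inh$v, 1e-12) - inh$S, km0 * 1.01)
    stats::median(inh$I / (app / km0 - 1))
  }
  if (cofit) {
    base <- hanes_woolf_start(d$S[d$I == 0], d$v[d$I == 0])
    if (!is.finite(base$vmax)) base <- hanes_woolf_start(d$S, d$v)
    start <- list(vmax = base$vmax, km = base$km,
                  ki = max(ki_start(base$km, base$vmax / E), 1e-6))
    fit <- nls(v ~ vmax * S / (km * (1 + I / ki) + S), data = d, start = start,
               algorithm = "port", lower = c(vmax = 1e-12, km = 1e-12, ki = 1e-12),
               control = nls.control(maxiter = 500, scaleOffset = 1))
    est <- coef(fit); ci <- wald_ci(fit)
    out <- list(ki = unname(est["ki"]), ci95_ki = unname(ci["ki"]),
                km = unname(est["km"]), kcat = unname(est["vmax"]) / E,
                cofitted = TRUE, n = nrow(d))
  } else {
    if (is.null(km) || is.null(kcat)) {
      zero <- d$I == 0
      if (!any(zero)) {
        stop("supply km and kcat, or include uninhibited (I = 0) points", call. = FALSE)
      }
      base <- fit_mm(kinetics_dataset(d$S[zero], d$v[zero], replicate = d$replicate[zero],
                                      enzyme_conc = E))
      km <- base$km; kcat <- base$kcat
    }
    vmax <- kcat * E
    start <- list(ki = max(ki_start(km, kcat), 1e-6))
    fit <- nls(v ~ vmax * S / (km * (1 + I / ki) + S), data = d, start = start,
               algorithm = "port", lower = c(ki = 1e-12),
               control = nls.control(maxiter = 500, scaleOffset = 1))
    est <- coef(fit); ci <- wald_ci(fit)
    out <- list(ki = unname(est["ki"]), ci95_ki = unname(ci["ki"]),
                km = km, kcat = kcat, cofitted = FALSE, n = nrow(d))
  }
  if (out$ki <= 0) stop("degenerate Ki fit", call. = FALSE)
  structure(out, class = "ki_fit")
}

#' Catalytic efficiency at the report precision
#'
#' `kcat / km` in 1/(s mM), rounded the way kinetic tables print it: two
#' significant figures below 100, nearest integer above (so 4750/46 reports
#' as 103 and 4.7/0.15 as 31).
#'
#' @param fit an [mm_fit()].
#' @param raw return the unrounded quotient.
#' @return Numeric scalar.
#' @export
catalytic_efficiency <- function(fit, raw = FALSE) {
  stopifnot(inherits(fit, "mm_fit"))
  eff <- fit$kcat / fit$km
  if (raw) return(eff)
  if (abs(eff) >= 100) round(eff) else signif(eff, 2)
}

#' Activity profile over pH or temperature
#'
#' @param x strictly increasing pH or temperature values.
#' @param activity measured activities (arbitrary units).
#' @return A data frame of class `activity_profile`.
#' @export
activity_profile <- function(x, activity) {
  if (length(x) != length(activity)) stop("x and activity lengths differ", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("x values must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(x = x, activity = activity),
            class = c("activity_profile", "data.frame"))
}

#' Activity optimum range
#'
#' The smallest and largest measured `x` at which activity is strictly
#' greater than `fraction` of the maximum (default 0.90, the ">90% of the
#' maximum activity" convention for optimal pH/temperature ranges). When
#' only the maximal point qualifies the range collapses to that point.
#'
#' @param profile an [activity_profile()].
#' @param fraction threshold fraction of the maximum.
#' @return List `x_low`, `x_high` (measured x values), `threshold`.
#' @export
optimum_range <- function(profile, fraction = 0.90) {
  if (!nrow(profile)) stop("empty activity profile", call. = FALSE)
  thr <- fraction * max(profile$activity)
  qual <- profile$x[profile$activity > thr]
  if (!length(qual)) {  # max == 0 edge case
    qual <- profile$x[which.max(profile$activity)]
  }
  list(x_low = min(qual), x_high = max(qual), threshold = thr)
}

#' Write a kinetics fit report as JSON
#' @param fits named list of [mm_fit()] / `ki_fit` objects.
#' @param path output file.
#' @export
write_kinetics_report <- function(fits, path) {
  payload <- lapply(fits, function(f) {
    if (inherits(f, "mm_fit")) {
      list(model = "michaelis_menten", km_mM = f$km, kcat_per_s = f$kcat,
           efficiency_per_s_mM = catalytic_efficiency(f),
           efficiency_raw = f$efficiency,
           ci95_km = f$ci95_km, ci95_kcat = f$ci95_kcat, n = f$n)
    } else {
      list(model = "competitive_inhibition", ki_mM = f$ki, ci95_ki = f$ci95_ki,
           km_mM = f$km, kcat_per_s = f$kcat, cofitted = f$cofitted, n = f$n)
    }
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
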