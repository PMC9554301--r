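#' Initial reaction rate from a trajectory
#'
#' Ordinary least-squares slope of the product concentration against time
#' over a window, the standard way initial rates are read off the early,
#' quasi-linear part of an assay curve.
#'
#' @param trajectory a [simulate_circuit()] result.
#' @param product_node name of the product node (default `"P"`).
#' @param window numeric `c(t0, t1)` in seconds within the trajectory span;
#'   the default uses the whole trajectory.
#' @return slope in M/s.
#' @export
initial_rate <- function(trajectory, product_node = "P", window = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (!product_node %in% colnames(trajectory$values))
    stop("unknown product node '", product_node, "'", call. = FALSE)
  t <- trajectory$times
  p <- trajectory$values[, product_node]
  if (!is.null(window)) {
    if (window[1] < t[1] || window[2] > t[length(t)])
      stop("window outside trajectory span", call. = FALSE)
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; p <- p[keep]
  }
  if (length(t) < 5L)
    stop("need at least 5 sample points in the rate window (have ",
         length(t), ")", call. = FALSE)
  unname(stats::coef(stats::lm(p ~ t))[2])
}

# Slope of values ~ times by OLS without lm() overhead (used in tight loops).
.ols_slope <- function(t, p) {
  tm <- t - mean(t)
  sum(tm * (p - mean(p))) / sum(tm^2)
}

#' Initial-rate curve over a substrate grid
#'
#' Simulates the motif once per initial substrate concentration and extracts
#' the initial rate from an automatically chosen window: the earliest 10% of
#' the simulated span, further capped so that substrate consumption stays
#' below `consumption_cap` (rate-window nonlinearity otherwise biases the
#' reciprocal fit).  If the capped window is too coarse the simulation is
#' rerun over just that window for resolution.
#'
#' @param builder a function `function(S0) -> circuit` constructing the motif
#'   at one substrate concentration.
#' @param S0_grid initial substrate concentrations (M).
#' @param t_end simulation span per point (s).
#' @param settings a [solver_settings()]; the default uses a 200-point grid.
#' @param product_node product node name.
#' @param consumption_cap maximal fraction of S0 converted inside the rate
#'   window (default 0.05).
#' @param window optional fixed `c(t0, t1)` window overriding the automatic
#'   choice.
#' @param E0 total enzyme (M), carried as metadata so fits can be compared.
#' @return an object of class `rate_analysis` with fields `S0`, `V0` and the
#'   per-point window series; pass it to [lineweaver_burk()].
#' @export
rate_curve <- function(builder, S0_grid, t_end,
                       settings = solver_settings(grid = 200),
                       product_node = "P", consumption_cap = 0.05,
                       window = NULL, E0 = NA_real_) {
  stopifnot(is.function(builder), all(S0_grid >= 0), t_end > 0)
  V0 <- numeric(length(S0_grid))
  windows <- vector("list", length(S0_grid))
  for (i in seq_along(S0_grid)) {
    s0 <- S0_grid[i]
    if (s0 == 0) { V0[i] <- 0; next }
    circ <- builder(s0)
    traj <- simulate_circuit(circ, t_end, settings)
    t <- traj$times
    p <- traj$values[, product_node]
    if (is.null(window)) {
      w_end <- t[1] + 0.1 * (t[length(t)] - t[1])
      over <- which(p > consumption_cap * s0)
      if (length(over)) w_end <- min(w_end, t[max(2L, over[1] - 1L)])
      keep <- t <= w_end
      if (sum(keep) < 8L) {
        traj <- simulate_circuit(circ, w_end, settings)
        t <- traj$times
        p <- traj$values[, product_node]
        keep <- rep(TRUE, length(t))
      }
    } else {
      keep <- t >= window[1] & t <= window[2]
      if (sum(keep) < 5L) stop("fewer than 5 points in window",
                               call. = FALSE)
    }
    V0[i] <- max(.ols_slope(t[keep], p[keep]), 0)
    windows[[i]] <- list(times = t[keep], product = p[keep])
  }
  structure(list(S0 = S0_grid, V0 = V0, windows = windows, E0 = E0,
                 product_node = product_node),
            class = "rate_analysis")
}

#' Lineweaver-Burk (double-reciprocal) fit
#'
#' Unweighted least squares of `1/V0` on `1/S0` (zero entries excluded
#' before the reciprocal transform).  Apparent constants come from the
#' intercepts: the Y-intercept is `1/V_max` and the X-intercept is
#' `-1/K_m`, so `V_max_app = 1/y_intercept` and `K_m_app = slope/y_intercept`.
#'
#' @param x a `rate_analysis` from [rate_curve()], or a numeric vector of
#'   substrate concentrations (M) when `V0` is supplied.
#' @param V0 initial rates (M/s) when `x` is a plain vector.
#' @return the `rate_analysis` augmented with `lb_slope`, `y_intercept`,
#'   `x_intercept`, `K_m_app`, `V_max_app` and `fit_residual`.
#' @export
lineweaver_burk <- function(x, V0 = NULL) {
  if (inherits(x, "rate_analysis")) {
    ra <- x
  } else {
    ra <- structure(list(S0 = as.numeric(x), V0 = as.numeric(V0),
                         E0 = NA_real_),
                    class = "rate_analysis")
  }
  use <- ra$S0 > 0 & ra$V0 > 0
  if (sum(use) < 3L)
    stop("need at least 3 points with S0 > 0 and V0 > 0 for the ",
         "double-reciprocal fit (have ", sum(use), ")", call. = FALSE)
  xr <- 1 / ra$S0[use]
  yr <- 1 / ra$V0[use]
  fit <- stats::lm(yr ~ xr)
  co <- stats::coef(fit)
  ra$y_intercept <- unname(co[1])          # s/M = 1/V_max
  ra$lb_slope <- unname(co[2])             # s   = K_m/V_max
  ra$x_intercept <- -ra$y_intercept / ra$lb_slope   # -1/K_m
  ra$K_m_app <- ra$lb_slope / ra$y_intercept
  ra$V_max_app <- 1 / ra$y_intercept
  ra$fit_residual <- sum(stats::residuals(fit)^2)
  ra
}

#' @export
print.rate_analysis <- function(x, ...) {
  cat("<rate_analysis> ", length(x$S0), " substrate points\n", sep = "")
  if (!is.null(x$K_m_app))
    cat(sprintf("  K_m_app   = %.6g M\n  V_max_app = %.6g M/s\n  slope     = %.6g s\n",
                x$K_m_app, x$V_max_app, x$lb_slope))
  invisible(x)
}

#' Classify the inhibition mechanism from two fits
#'
#' Compares apparent parameters fitted with and without inhibitor, using
#' relative-change thresholds: competitive inhibition raises the apparent
#' K_m at unchanged V_max; noncompetitive lowers V_max at unchanged K_m;
#' uncompetitive lowers both in the same proportion (unchanged
#' Lineweaver-Burk slope K_m/V_max); anything else with substantial change
#' is mixed.
#'
#' @param fit_without,fit_with [lineweaver_burk()] results for the
#'   uninhibited and inhibited experiment; enzyme totals must match.
#' @param threshold relative change counted as "changed" (default 0.1).
#' @return a list with `type` (one of `"competitive"`, `"noncompetitive"`,
#'   `"uncompetitive"`, `"mixed"`, `"none"`) and `evidence` (relative changes
#'   of K_m, V_max and the LB slope).
#' @export
classify_inhibition <- function(fit_without, fit_with, threshold = 0.1) {
  for (f in list(fit_without, fit_with))
    if (!inherits(f, "rate_analysis") || is.null(f$K_m_app))
      stop("both arguments must be fitted rate_analysis objects",
           call. = FALSE)
  e0 <- c(fit_without$E0, fit_with$E0)
  if (!anyNA(e0) && abs(e0[1] - e0[2]) > 1e-12 * max(e0))
    stop("fits are incomparable: different enzyme totals", call. = FALSE)
  d_km <- fit_with$K_m_app / fit_without$K_m_app - 1
  d_v  <- fit_with$V_max_app / fit_without$V_max_app - 1
  d_sl <- fit_with$lb_slope / fit_without$lb_slope - 1
  ev <- c(K_m_change = d_km, V_max_change = d_v, slope_change = d_sl)
  km_up   <- d_km >  threshold
  km_down <- d_km < -threshold
  v_down  <- d_v  < -threshold
  type <-
    if (abs(d_km) <= threshold && abs(d_v) <= threshold) "none"
    else if (km_up && abs(d_v) <= threshold)             "competitive"
    else if (abs(d_km) <= threshold && v_down)           "noncompetitive"
    else if (km_down && v_down && abs(d_sl) <= threshold) "uncompetitive"
    else                                                  "mixed"
  list(type = type, evidence = ev)
}
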