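#' Solver settings for circuit simulation
#'
#' Defaults suit concentrations spanning nM to mM: a stiff implicit
#' integrator at relative tolerance 1e-8 and absolute tolerance 1e-12 M, a
#' 500-point output grid (plate-reader-like sampling), and a damped Newton
#' solve for the quasi-steady-state (algebraic) nodes at each evaluation.
#'
#' @param rtol relative integration tolerance.
#' @param atol absolute integration tolerance (M).
#' @param grid number of evenly spaced output times.
#' @param newton_max_iter maximum damped-Newton iterations per algebraic solve.
#' @param newton_rtol relative flux-balance tolerance: an algebraic node is
#'   converged when its net current is below `newton_rtol` times the gross
#'   current flowing through it.
#' @param seed reserved for stochastic extensions; the solver is deterministic.
#' @return a `solver_settings` list.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-12, grid = 500,
                            newton_max_iter = 50L, newton_rtol = 1e-9,
                            seed = NULL) {
  stopifnot(rtol > 0, atol > 0, grid >= 2, newton_max_iter >= 1)
  structure(list(rtol = rtol, atol = atol, grid = as.integer(grid),
                 newton_max_iter = as.integer(newton_max_iter),
                 newton_rtol = newton_rtol, seed = seed),
            class = "solver_settings")
}

#' Compile a circuit to a differential-algebraic system
#'
#' Partitions nodes into dynamic (ODE: `dV/dt = net current / C`) and
#' algebraic (current-balance residual: `net current = 0`), and builds fast
#' index-based evaluators for node net currents, element currents, and pool
#' free values.  Pool arithmetic is linear in the node values and is
#' precomputed as `free = t0 + A %*% v`.
#'
#' @param circuit a validated circuit; any structural diagnostic from
#'   [validate_circuit()] is a compile error.
#' @return an object of class `compiled_system` with fields
#'   `dynamic_layout`, `algebraic_layout`, and pure evaluator closures.
#' @export
compile_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "circuit"))
  diag <- validate_circuit(circuit)
  if (length(diag))
    stop("cannot compile circuit: ", paste(diag, collapse = "; "),
         call. = FALSE)
  node_names <- names(circuit$nodes)
  pool_names <- names(circuit$pools)
  n <- length(node_names)
  p <- length(pool_names)
  kinds <- vapply(circuit$nodes, `[[`, "", "kind")
  dyn <- node_names[kinds == "dynamic"]
  alg <- node_names[kinds == "algebraic"]
  dyn_idx <- match(dyn, node_names)
  alg_idx <- match(alg, node_names)
  caps <- vapply(circuit$nodes[dyn], `[[`, 0, "capacitance")

  # pool linear form: free = t0 + A %*% v
  t0 <- numeric(p)
  A <- matrix(0, p, n, dimnames = list(pool_names, node_names))
  for (j in seq_along(circuit$pools)) {
    pl <- circuit$pools[[j]]
    if (is.character(pl$total)) {
      A[j, pl$total] <- A[j, pl$total] + 1
    } else {
      t0[j] <- pl$total
    }
    for (k in seq_along(pl$deductions))
      A[j, names(pl$deductions)[k]] <-
        A[j, names(pl$deductions)[k]] - pl$deductions[[k]]
  }

  # element tables in index space: nodes 1..n, pools n+1..n+p
  el_names <- vapply(circuit$elements, `[[`, "", "name")
  ref_idx <- function(ref) {
    i <- match(ref, node_names)
    if (!is.na(i)) i else n + match(ref, pool_names)
  }
  els <- lapply(circuit$elements, function(el) {
    if (el$type == "decay")
      list(kind = 1L, inputs = ref_idx(el$node), gain = 1 / el$resistance,
           target = ref_idx(el$node), sgn = -1)
    else
      list(kind = 2L, inputs = vapply(el$inputs, ref_idx, 0L),
           gain = el$gain, target = ref_idx(el$target),
           sgn = if (el$sign == "source") 1 else -1)
  })

  # Evaluate all currents at node-value vector v; returns net and gross
  # (sum of |current|) per node, element currents, and pool free values.
  eval_all <- function(v) {
    free <- if (p) t0 + as.numeric(A %*% v) else numeric(0)
    u <- c(v, free)
    net <- numeric(n)
    gross <- numeric(n)
    cur <- numeric(length(els))
    for (i in seq_along(els)) {
      e <- els[[i]]
      ci <- e$gain
      for (ii in e$inputs) ci <- ci * u[ii]
      cur[i] <- ci
      net[e$target] <- net[e$target] + e$sgn * ci
      gross[e$target] <- gross[e$target] + abs(ci)
    }
    list(net = net, gross = gross, currents = cur, free = free)
  }

  assemble <- function(y_dyn, y_alg) {
    v <- numeric(n)
    v[dyn_idx] <- y_dyn
    if (length(alg_idx)) v[alg_idx] <- y_alg
    v
  }

  scale0 <- sum(abs(t0)) + sum(abs(initial_state(circuit))) + 1e-12

  sys <- list(
    circuit = circuit,
    dynamic_layout = dyn, algebraic_layout = alg,
    pool_layout = pool_names, element_layout = el_names,
    n_dynamic = length(dyn), n_algebraic = length(alg),
    capacitances = caps, char_scale = scale0,
    eval_all = eval_all, assemble = assemble,
    dyn_idx = dyn_idx, alg_idx = alg_idx
  )
  sys$rhs <- function(t, y_dyn, y_alg) {
    ev <- eval_all(assemble(y_dyn, y_alg))
    ev$net[dyn_idx] / caps
  }
  sys$residual <- function(t, y_dyn, y_alg) {
    ev <- eval_all(assemble(y_dyn, y_alg))
    ev$net[alg_idx]
  }
  class(sys) <- "compiled_system"
  sys
}

#' @export
print.compiled_system <- function(x, ...) {
  cat("<compiled_system> ", x$circuit$meta$name, "\n",
      "  ODEs:      ", x$n_dynamic, " (", paste(x$dynamic_layout,
                                                collapse = ", "), ")\n",
      "  residuals: ", x$n_algebraic,
      if (x$n_algebraic) paste0(" (", paste(x$algebraic_layout,
                                            collapse = ", "), ")") else "",
      "\n", sep = "")
  invisible(x)
}

# residual and gross scale at algebraic values a, given dynamic values yd
.alg_resid <- function(system, yd, a) {
  ev <- system$eval_all(system$assemble(yd, a))
  list(r = ev$net[system$alg_idx], g = ev$gross[system$alg_idx])
}

#' Solve the algebraic (quasi-steady-state) nodes
#'
#' Damped Newton iteration on the current-balance residuals of all algebraic
#' nodes at fixed dynamic state, warm-started from `guess`.  Convergence is
#' relative flux balance: each residual must fall below `newton_rtol` times
#' the gross current through its node.  On Newton failure a bounded
#' bracketing root-finder handles the single-node case, and damped restarts
#' from zero handle the rest; persistent failure is an error carrying the
#' last residual.
#'
#' @param system a [compile_circuit()] result.
#' @param dynamic_state named or plain numeric vector of dynamic node values
#'   (M), in `dynamic_layout` order.
#' @param guess starting algebraic values (default all zeros, the
#'   complexes-start-empty state).
#' @param settings a [solver_settings()] object.
#' @return numeric vector of algebraic node values, all >= 0.
#' @export
solve_algebraic <- function(system, dynamic_state,
                            guess = rep(0, system$n_algebraic),
                            settings = solver_settings()) {
  m <- system$n_algebraic
  if (m == 0L) return(numeric(0))
  yd <- as.numeric(dynamic_state)
  a <- pmax(as.numeric(guess), 0)
  rtol <- settings$newton_rtol
  # purely relative flux balance: gross currents set the natural scale, and
  # an all-zero state has zero residual exactly, so no absolute floor is
  # needed (a floor would silently loosen nM-scale enzyme problems)
  conv <- function(rr) all(abs(rr$r) <= rtol * rr$g)

  newton <- function(a) {
    rr <- .alg_resid(system, yd, a)
    for (it in seq_len(settings$newton_max_iter)) {
      if (conv(rr)) return(list(a = a, rr = rr, ok = TRUE))
      J <- matrix(0, m, m)
      for (j in seq_len(m)) {
        h <- 1e-7 * max(abs(a[j]), 1e-4 * system$char_scale)
        ap <- a; ap[j] <- a[j] + h
        J[, j] <- (.alg_resid(system, yd, ap)$r - rr$r) / h
      }
      step <- tryCatch(solve(J, -rr$r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step)))
        return(list(a = a, rr = rr, ok = FALSE))
      lam <- 1
      repeat {
        a_new <- a + lam * step
        rr_new <- .alg_resid(system, yd, a_new)
        if (all(is.finite(rr_new$r)) &&
            (sum(rr_new$r^2) < sum(rr$r^2) || conv(rr_new))) {
          a <- a_new; rr <- rr_new
          break
        }
        lam <- lam / 2
        if (lam < 2^-25) return(list(a = a, rr = rr, ok = FALSE))
      }
    }
    list(a = a, rr = rr, ok = conv(rr))
  }

  res <- newton(a)
  if (!res$ok && any(a != 0)) res <- newton(rep(0, m))
  if (!res$ok && m == 1L) {
    # bounded bracketing fallback: the residual is decreasing in the
    # complex concentration for all shipped motifs
    f <- function(x) .alg_resid(system, yd, x)$r
    hi <- max(system$char_scale, 1e-12)
    lo <- 0
    f_lo <- f(lo)
    if (f_lo == 0) {
      res <- list(a = 0, rr = .alg_resid(system, yd, 0), ok = TRUE)
    } else {
      k <- 0
      while (sign(f(hi)) == sign(f_lo) && k < 60) { hi <- hi * 2; k <- k + 1 }
      if (sign(f(hi)) != sign(f_lo)) {
        root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
        res <- list(a = root, rr = .alg_resid(system, yd, root), ok = TRUE)
      }
    }
  }
  if (!res$ok)
    stop("algebraic solve did not converge; last residual = ",
         paste(signif(res$rr$r, 4), collapse = ", "), call. = FALSE)
  a <- res$a
  neg <- a < 0
  if (any(neg)) {
    if (any(a < -10 * settings$atol))
      stop("algebraic solve converged to a negative complex concentration (",
           paste(signif(a[neg], 4), collapse = ", "),
           "); model parameters are inconsistent", call. = FALSE)
    a[neg] <- 0
  }
  a
}

#' Integrate a compiled circuit over time
#'
#' Nested DAE strategy: the stiff ODE integrator (lsoda) advances the dynamic
#' nodes, and every right-hand-side evaluation re-solves the algebraic nodes
#' by damped Newton warm-started from the previous solution.  The algebraic
#' state at t = 0 is solved from an all-zeros guess (complexes equilibrate
#' essentially instantaneously).  Voltages in the returned trajectory are
#' concentrations (M) and element currents are reaction fluxes (M/s).
#'
#' @param system a `compiled_system` (a raw `circuit` is compiled on the fly).
#' @param t_end simulation end time (s), > 0.
#' @param settings a [solver_settings()].
#' @param times optional explicit output grid overriding `settings$grid`.
#' @return an object of class `trajectory` with fields `times`, `values`
#'   (time x node matrix, M), `currents` (time x element, M/s), `free`
#'   (time x pool, M) and `diagnostics`.
#' @export
simulate_circuit <- function(system, t_end, settings = solver_settings(),
                             times = NULL) {
  if (inherits(system, "circuit")) system <- compile_circuit(system)
  stopifnot(inherits(system, "compiled_system"), t_end > 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = settings$grid)
  if (is.unsorted(times, strictly = TRUE))
    stop("output times must be strictly increasing", call. = FALSE)

  y0 <- initial_state(system$circuit)
  yd0 <- y0[system$dyn_idx]
  warm <- new.env(parent = emptyenv())
  warm$a <- solve_algebraic(system, yd0, rep(0, system$n_algebraic), settings)

  deriv <- function(t, y, parms) {
    if (system$n_algebraic) {
      warm$a <- solve_algebraic(system, y, warm$a, settings)
    }
    ev <- system$eval_all(system$assemble(y, warm$a))
    list(ev$net[system$dyn_idx] / system$capacitances)
  }

  sol <- deSolve::ode(y = stats::setNames(yd0, system$dynamic_layout),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = settings$rtol,
                      atol = settings$atol)
  ds <- attributes(sol)$istate
  if (nrow(sol) < length(times))
    stop("integrator failed at t = ", sol[nrow(sol), 1],
         " after ", nrow(sol), " of ", length(times), " output points",
         call. = FALSE)

  # reconstruct algebraic values, currents and pool frees on the output grid
  n <- length(system$circuit$nodes)
  nt <- length(times)
  values <- matrix(NA_real_, nt, n,
                   dimnames = list(NULL, names(system$circuit$nodes)))
  currents <- matrix(NA_real_, nt, length(system$element_layout),
                     dimnames = list(NULL, system$element_layout))
  frees <- matrix(NA_real_, nt, length(system$pool_layout),
                  dimnames = list(NULL, system$pool_layout))
  a_prev <- rep(0, system$n_algebraic)
  max_resid <- 0
  for (i in seq_len(nt)) {
    yd <- sol[i, 1 + seq_len(system$n_dynamic)]
    a_prev <- solve_algebraic(system, yd, a_prev, settings)
    v <- system$assemble(yd, a_prev)
    ev <- system$eval_all(v)
    if (system$n_algebraic)
      max_resid <- max(max_resid, max(abs(ev$net[system$alg_idx])))
    values[i, ] <- v
    currents[i, ] <- ev$currents
    frees[i, ] <- ev$free
  }

  min_free <- if (length(frees)) min(frees) else 0
  min_node <- min(values)
  neg_tol <- 10 * (settings$atol + settings$rtol * system$char_scale)
  if (min_free < -neg_tol || min_node < -neg_tol)
    warning("negative concentration beyond solver tolerance (min = ",
            signif(min(min_free, min_node), 3),
            "); check model parameters", call. = FALSE)

  structure(
    list(times = times, values = values, currents = currents, free = frees,
         circuit = system$circuit, system = system, settings = settings,
         diagnostics = list(min_free = min_free, min_node = min_node,
                            max_alg_residual = max_resid,
                            n_rhs = unname(ds[3]))),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$circuit$meta$name, ": ",
      length(x$times), " points over [", x$times[1], ", ",
      x$times[length(x$times)], "] s, ",
      ncol(x$values), " nodes\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x$values, x$currents, check.names = FALSE)
}

#' Current (flux) time series of one element
#'
#' Recomputed pointwise from the stored node values, so it equals the stored
#' current column by construction; the flux through the catalytic
#' transconductor is the reaction rate d[P]/dt.
#'
#' @param trajectory a [simulate_circuit()] result.
#' @param element element name.
#' @return numeric vector of currents (M/s) on the trajectory time grid.
#' @export
flux_series <- function(trajectory, element) {
  stopifnot(inherits(trajectory, "trajectory"))
  i <- match(element, trajectory$system$element_layout)
  if (is.na(i)) stop("unknown element '", element, "'", call. = FALSE)
  vapply(seq_along(trajectory$times), function(k) {
    ev <- trajectory$system$eval_all(trajectory$values[k, ])
    ev$currents[i]
  }, 0)
}

#' Conservation report for a trajectory
#'
#' For every pool, the worst absolute violation of
#' `total - free - sum(multiplier * bound)` over the output grid, together
#' with the minimum free value.  Pool arithmetic is exact by construction,
#' so the violation should sit at machine precision; the minimum free value
#' is the meaningful well-posedness diagnostic.
#'
#' @param trajectory a trajectory.
#' @return data.frame with columns `pool`, `max_violation`, `min_free`.
#' @export
conservation_report <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  circ <- trajectory$circuit
  out <- lapply(names(circ$pools), function(pn) {
    pl <- circ$pools[[pn]]
    viol <- vapply(seq_along(trajectory$times), function(k) {
      st <- trajectory$values[k, ]
      tot <- if (is.character(pl$total)) st[[pl$total]] else pl$total
      bound <- 0
      for (j in seq_along(pl$deductions))
        bound <- bound + pl$deductions[[j]] * st[[names(pl$deductions)[j]]]
      abs(tot - trajectory$free[k, pn] - bound)
    }, 0)
    data.frame(pool = pn, max_violation = max(viol),
               min_free = min(trajectory$free[, pn]))
  })
  do.call(rbind, out)
}
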