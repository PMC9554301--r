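#' Create an empty kinetic circuit
#'
#' A circuit is the in-memory netlist of a reaction network: species are
#' voltage nodes, mass-action fluxes are transconductor currents, first-order
#' losses are resistor currents, and mass conservation is bookkept by pools
#' whose free value is `total - sum(multiplier * bound)`.  A node is either
#' `dynamic` (carries a capacitor; its concentration integrates net current)
#' or `algebraic` (capacitor removed under the quasi-steady-state
#' approximation; its net current is constrained to zero).
#'
#' @param name circuit label used in logs and trajectory metadata.
#' @param units_note free-text reminder; internal units are always M and s.
#' @return an object of class `circuit`.
#' @seealso [add_species()], [add_transconductor()], [add_decay()],
#'   [add_pool()], [compile_circuit()]
#' @export
new_circuit <- function(name = "circuit", units_note = "M, s") {
  structure(
    list(nodes = list(), elements = list(), pools = list(),
         meta = list(name = name, units = units_note)),
    class = "circuit"
  )
}

#' @export
print.circuit <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, "", "kind")
  cat("<circuit> ", x$meta$name, "\n",
      "  nodes:    ", length(x$nodes),
      " (", sum(kinds == "dynamic"), " dynamic, ",
      sum(kinds == "algebraic"), " algebraic)\n",
      "  elements: ", length(x$elements), "\n",
      "  pools:    ", length(x$pools), "\n", sep = "")
  invisible(x)
}

.assert_new_name <- function(circuit, name) {
  if (name %in% c(names(circuit$nodes), names(circuit$pools)))
    stop("name '", name, "' already used in circuit", call. = FALSE)
  if (!nzchar(name)) stop("empty name", call. = FALSE)
}

#' Add a species node
#'
#' @param circuit a [new_circuit()] object.
#' @param name unique species identifier.
#' @param kind `"dynamic"` (capacitor present, concentration integrates) or
#'   `"algebraic"` (capacitor removed, current balance solved each instant).
#' @param initial_value initial concentration in M, must be >= 0.  Algebraic
#'   nodes ignore this beyond using it as a solver hint.
#' @param capacitance volume-normalization constant; the default 1 represents
#'   a volume-normalized container so voltage equals concentration.
#'   Must be > 0 for dynamic nodes; algebraic nodes carry none.
#' @return the circuit with the node registered.
#' @export
add_species <- function(circuit, name, kind = c("dynamic", "algebraic"),
                        initial_value = 0, capacitance = 1) {
  stopifnot(inherits(circuit, "circuit"))
  kind <- match.arg(kind)
  .assert_new_name(circuit, name)
  if (!is.numeric(initial_value) || length(initial_value) != 1L ||
      is.na(initial_value) || initial_value < 0)
    stop("initial_value of '", name, "' must be a single number >= 0",
         call. = FALSE)
  if (kind == "dynamic") {
    if (!is.numeric(capacitance) || capacitance <= 0)
      stop("capacitance of dynamic node '", name, "' must be > 0",
           call. = FALSE)
  } else {
    capacitance <- NA_real_   # QSSA: no capacitor on this node
  }
  circuit$nodes[[name]] <- list(name = name, kind = kind,
                                capacitance = capacitance,
                                initial_value = initial_value)
  circuit
}

#' Add a transconductor flux element
#'
#' A voltage-controlled current source: its current is
#' `gain * prod(values of input_terms)`, in M/s.  Inputs may reference
#' species nodes or pool free values; two inputs make the element a
#' multiplier-fed bimolecular flux.
#'
#' @param circuit a circuit.
#' @param name unique element label.
#' @param gain rate constant: 1/s for one input, 1/(M s) for two.
#' @param inputs character vector of node and/or pool names.
#' @param target node receiving (`sign = "source"`) or losing
#'   (`sign = "sink"`) the current.
#' @param sign `"source"` or `"sink"`.
#' @return the circuit with the element appended.
#' @export
add_transconductor <- function(circuit, name, gain, inputs, target,
                               sign = c("source", "sink")) {
  stopifnot(inherits(circuit, "circuit"))
  sign <- match.arg(sign)
  if (!is.numeric(gain) || length(gain) != 1L || is.na(gain) || gain < 0)
    stop("gain of '", name, "' must be a single number >= 0", call. = FALSE)
  if (name %in% vapply(circuit$elements, `[[`, "", "name"))
    stop("element name '", name, "' already used", call. = FALSE)
  circuit$elements[[length(circuit$elements) + 1L]] <-
    list(type = "transconductor", name = name, gain = gain,
         inputs = as.character(inputs), target = target, sign = sign)
  circuit
}

#' Add a decay path (resistor)
#'
#' Ohm's law current `value / resistance` drains the node; with C = 1 the
#' resistance is the reciprocal of a first-order rate constant (R = 1/k) or,
#' on a QSSA complex node, the reciprocal of a dissociation constant
#' (R = 1/K_m, in which case the current is the dissociation flux
#' `[complex] * K_m`).
#'
#' @param circuit a circuit.
#' @param name unique element label.
#' @param node node drained by the resistor.
#' @param resistance R > 0 in Ohm (s, or M-reciprocal for QSSA resistors).
#' @return the circuit with the element appended.
#' @export
add_decay <- function(circuit, name, node, resistance) {
  stopifnot(inherits(circuit, "circuit"))
  if (!is.numeric(resistance) || length(resistance) != 1L ||
      is.na(resistance) || resistance <= 0)
    stop("resistance of '", name, "' must be > 0", call. = FALSE)
  if (name %in% vapply(circuit$elements, `[[`, "", "name"))
    stop("element name '", name, "' already used", call. = FALSE)
  circuit$elements[[length(circuit$elements) + 1L]] <-
    list(type = "decay", name = name, node = node, resistance = resistance)
  circuit
}

#' Add a conservation pool
#'
#' Bookkeeping of a conserved total: the pool's free value is
#' `total - sum(multiplier * node value)` (an adder/subtracter block).
#' Multipliers are signed stoichiometric weights and may be non-integer,
#' e.g. the polymerase sequestration count `1 + k_TX * Lm / Cm`; a negative
#' multiplier adds a node to the pool (used when newly made product feeds an
#' inhibitor pool).  `total` may also name a dynamic node, in which case the
#' pool tracks that node's current value (free mRNA = total mRNA - bound).
#'
#' @param circuit a circuit.
#' @param name unique pool identifier; flux inputs may reference it.
#' @param total conserved total concentration (M), or the name of a node.
#' @param deductions named numeric vector `c(node = multiplier, ...)`.
#' @return the circuit with the pool registered.
#' @export
add_pool <- function(circuit, name, total, deductions = numeric()) {
  stopifnot(inherits(circuit, "circuit"))
  .assert_new_name(circuit, name)
  if (is.character(total)) {
    if (length(total) != 1L) stop("total must be scalar", call. = FALSE)
  } else if (!is.numeric(total) || length(total) != 1L || is.na(total) ||
             total < 0) {
    stop("pool total of '", name, "' must be >= 0 or a node name",
         call. = FALSE)
  }
  if (length(deductions) && is.null(names(deductions)))
    stop("deductions must be a named vector", call. = FALSE)
  circuit$pools[[name]] <- list(name = name, total = total,
                                deductions = deductions)
  circuit
}

# Value of a node-or-pool reference under a state vector (named, M).
.ref_value <- function(circuit, ref, state) {
  if (ref %in% names(circuit$nodes)) {
    v <- state[[ref]]
    if (is.null(v)) stop("state lacks node '", ref, "'", call. = FALSE)
    return(v)
  }
  if (ref %in% names(circuit$pools))
    return(as.numeric(free_value(circuit$pools[[ref]], state,
                                 circuit = circuit)))
  stop("unknown node or pool '", ref, "'", call. = FALSE)
}

#' Free value of a conservation pool
#'
#' `total - sum(multiplier * node value)`.  A negative result is reported via
#' the `negative` attribute rather than silently clamped: conservation is
#' exact in the formalism, so a substantially negative free value signals bad
#' parameters or a failed solve, not physics.
#'
#' @param pool a pool (element of `circuit$pools`).
#' @param state named numeric state vector with all deduction nodes.
#' @param circuit the owning circuit (needed when `total` names a node).
#' @return the free concentration (M) with attribute `negative` (logical).
#' @export
free_value <- function(pool, state, circuit = NULL) {
  tot <- pool$total
  if (is.character(tot)) {
    tot <- state[[tot]]
    if (is.null(tot))
      stop("state lacks node '", pool$total, "' used as pool total",
           call. = FALSE)
  }
  val <- tot
  ded <- pool$deductions
  if (length(ded)) {
    for (i in seq_along(ded)) {
      v <- state[[names(ded)[i]]]
      if (is.null(v))
        stop("state lacks node '", names(ded)[i], "' deducted by pool '",
             pool$name, "'", call. = FALSE)
      val <- val - ded[[i]] * v
    }
  }
  attr(val, "negative") <- unname(val < 0)
  val
}

# Current of a single element under a state (M/s), unsigned.
.element_current <- function(circuit, el, state) {
  if (el$type == "decay") {
    state_val <- state[[el$node]]
    if (is.null(state_val)) stop("state lacks node '", el$node, "'",
                                 call. = FALSE)
    state_val / el$resistance
  } else {
    cur <- el$gain
    for (ref in el$inputs) cur <- cur * .ref_value(circuit, ref, state)
    cur
  }
}

#' Net current into a node (Kirchhoff's current law)
#'
#' Sum of source currents minus sink currents at a species node; for a
#' dynamic node this equals `C * dV/dt`, for an algebraic node it is the
#' residual constrained to zero.
#'
#' @param circuit a circuit.
#' @param node node name.
#' @param state named numeric vector of all node values (M); pool values are
#'   derived from it.
#' @return net current in M/s.
#' @export
net_current <- function(circuit, node, state) {
  if (!node %in% names(circuit$nodes))
    stop("unknown node '", node, "'", call. = FALSE)
  net <- 0
  for (el in circuit$elements) {
    if (el$type == "decay") {
      if (el$node == node) net <- net - .element_current(circuit, el, state)
    } else if (el$target == node) {
      cur <- .element_current(circuit, el, state)
      net <- net + if (el$sign == "source") cur else -cur
    }
  }
  net
}

#' Structural validation of a circuit
#'
#' Returns a character vector of diagnostics (empty when the circuit is
#' well-formed): dangling element or pool references, algebraic nodes missing
#' a source or a sink (their current balance would be degenerate), and
#' non-positive constants.  Diagnostics, not exceptions: callers decide what
#' is fatal ([compile_circuit()] treats all of them as fatal).
#'
#' @param circuit a circuit.
#' @return character vector of problems; `character(0)` when clean.
#' @export
validate_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "circuit"))
  out <- character()
  node_names <- names(circuit$nodes)
  pool_names <- names(circuit$pools)
  refs <- c(node_names, pool_names)
  for (el in circuit$elements) {
    if (el$type == "decay") {
      if (!el$node %in% node_names)
        out <- c(out, sprintf("decay '%s' drains unknown node '%s'",
                              el$name, el$node))
    } else {
      if (!el$target %in% node_names)
        out <- c(out, sprintf("transconductor '%s' targets unknown node '%s'",
                              el$name, el$target))
      bad <- setdiff(el$inputs, refs)
      for (b in bad)
        out <- c(out, sprintf("transconductor '%s' reads unknown input '%s'",
                              el$name, b))
    }
  }
  for (p in circuit$pools) {
    bad <- setdiff(names(p$deductions), node_names)
    for (b in bad)
      out <- c(out, sprintf("pool '%s' deducts unknown node '%s'", p$name, b))
    if (is.character(p$total) && !p$total %in% node_names)
      out <- c(out, sprintf("pool '%s' totals unknown node '%s'",
                            p$name, p$total))
  }
  for (nd in circuit$nodes) {
    if (nd$kind != "algebraic") next
    has_source <- FALSE; has_sink <- FALSE
    for (el in circuit$elements) {
      if (el$type == "decay" && el$node == nd$name) has_sink <- TRUE
      if (el$type == "transconductor" && el$target == nd$name) {
        if (el$sign == "source") has_source <- TRUE else has_sink <- TRUE
      }
    }
    if (!has_source || !has_sink)
      out <- c(out, sprintf("unbalanced algebraic node '%s' (needs >=1 source and >=1 sink)",
                            nd$name))
  }
  out
}

#' Resistances of all decay paths
#'
#' Named vector of the circuit's resistor values in Ohm; for QSSA motifs the
#' complex-dissociation resistor is `1/K_m` with K_m in M (so K_m = 0.167 mM
#' maps to 5988 Ohm).
#'
#' @param circuit a circuit.
#' @return named numeric vector (element name -> resistance).
#' @export
decay_resistances <- function(circuit) {
  els <- Filter(function(e) e$type == "decay", circuit$elements)
  stats::setNames(vapply(els, `[[`, 0, "resistance"),
                  vapply(els, `[[`, "", "name"))
}

#' Initial state vector of a circuit
#'
#' Node initial values in declaration order (algebraic nodes contribute their
#' stored hint, usually 0; the compiler re-solves them at t = 0).
#'
#' @param circuit a circuit.
#' @return named numeric vector.
#' @export
initial_state <- function(circuit) {
  stats::setNames(vapply(circuit$nodes, `[[`, 0, "initial_value"),
                  names(circuit$nodes))
}
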