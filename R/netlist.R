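#' @title Netlist files
#' @description A netlist is a YAML-style text file describing one circuit —
#'   either a `motif` block (motif name plus unit-tagged parameters) or a raw
#'   `circuit` block (nodes, pools, elements) — together with optional
#'   `simulate` and `analysis` blocks.  All concentrations carry explicit
#'   unit tags (`mM`, `uM`, `nM`, `M`) and rate constants `per_s` /
#'   `per_M_s` (or per-mM/uM/nM variants); untagged concentrations are
#'   rejected.  Parameters written as `UNKNOWN` are placeholders for values
#'   the user must supply and abort loading with an actionable message.
#' @name netlist
NULL

# registry: motif name -> (string-valued parameter names, builder)
.motif_registry <- list(
  production_decay = list(strings = character(),
                          fn = function(p) do.call(build_production_decay, p)),
  mm_exact         = list(strings = character(),
                          fn = function(p) do.call(build_mm_exact, p)),
  mm_qssa          = list(strings = character(),
                          fn = function(p) do.call(build_mm_qssa, p)),
  inhibition       = list(strings = "type",
                          fn = function(p) do.call(build_inhibition, p)),
  product_feedback = list(strings = character(),
                          fn = function(p) do.call(build_product_feedback, p)),
  two_substrate    = list(strings = "order",
                          fn = function(p) do.call(build_two_substrate, p)),
  reversible_bibi  = list(strings = character(),
                          fn = function(p) do.call(build_reversible_bibi, p)),
  txtl             = list(strings = character(),
                          fn = function(p) do.call(build_txtl, p))
)

.collect_unknowns <- function(x, path = character()) {
  if (is.list(x)) {
    out <- character()
    for (nm in names(x))
      out <- c(out, .collect_unknowns(x[[nm]], c(path, nm)))
    return(out)
  }
  if (is.character(x) && any(toupper(trimws(x)) == "UNKNOWN"))
    return(paste(path, collapse = "."))
  character()
}

.build_motif <- function(block) {
  if (is.null(block$name) || !block$name %in% names(.motif_registry))
    stop("unknown motif '", block$name %||% "<missing>", "'; available: ",
         paste(names(.motif_registry), collapse = ", "), call. = FALSE)
  reg <- .motif_registry[[block$name]]
  raw <- block$parameters %||% list()
  params <- lapply(names(raw), function(nm) {
    if (nm %in% reg$strings) as.character(raw[[nm]])
    else parse_quantity(raw[[nm]], require_unit = TRUE)
  })
  names(params) <- names(raw)
  reg$fn(params)
}

.build_raw_circuit <- function(block) {
  circ <- new_circuit(block$name %||% "netlist_circuit")
  for (nd in block$nodes %||% list())
    circ <- add_species(circ, nd$name, nd$kind %||% "dynamic",
                        initial_value = parse_quantity(nd$initial %||% "0 M"),
                        capacitance = nd$capacitance %||% 1)
  for (pl in block$pools %||% list()) {
    tot <- pl$total
    tot <- if (is.character(tot) && !grepl("[[:space:]]", trimws(tot)))
      trimws(tot) else parse_quantity(tot)
    ded <- unlist(pl$deduct %||% list())
    circ <- add_pool(circ, pl$name, total = tot,
                     deductions = if (length(ded)) ded else numeric())
  }
  for (el in block$elements %||% list()) {
    if (identical(el$type, "decay"))
      circ <- add_decay(circ, el$name, el$node,
                        parse_quantity(el$resistance, require_unit = FALSE))
    else
      circ <- add_transconductor(circ, el$name,
                                 parse_quantity(el$gain, require_unit = TRUE),
                                 el$inputs, el$target,
                                 el$sign %||% "source")
  }
  circ
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a netlist file
#'
#' Parses, unit-converts and validates the circuit; returns the circuit
#' together with the simulation settings and any analysis block.
#'
#' @param path path to a netlist (YAML) file.
#' @return an object of class `netlist`: list with `circuit`, `t_end`,
#'   `settings` ([solver_settings()]), `analysis` (or NULL) and `raw` (the
#'   parsed YAML, used for lossless re-serialization).
#' @export
load_netlist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
  unk <- .collect_unknowns(raw)
  if (length(unk))
    stop("netlist ", basename(path), " contains UNKNOWN placeholders (",
         paste(unk, collapse = ", "),
         "); supply numeric unit-tagged values for them", call. = FALSE)
  has_motif <- !is.null(raw$motif)
  has_circ <- !is.null(raw$circuit)
  if (has_motif == has_circ)
    stop("netlist must contain exactly one of 'motif' or 'circuit'",
         call. = FALSE)
  circ <- if (has_motif) .build_motif(raw$motif)
          else .build_raw_circuit(raw$circuit)
  diag <- validate_circuit(circ)
  if (length(diag))
    stop("invalid circuit in ", basename(path), ": ",
         paste(diag, collapse = "; "), call. = FALSE)
  sim <- raw$simulate %||% list()
  settings <- solver_settings(
    rtol = sim$rtol %||% 1e-8,
    atol = sim$atol %||% 1e-12,
    grid = sim$grid %||% 500
  )
  analysis <- NULL
  if (!is.null(raw$analysis)) {
    analysis <- list(
      S0_grid = unname(vapply(raw$analysis$S0_grid, parse_quantity, 0)),
      window = raw$analysis$window %||% NULL,
      t_end = raw$analysis$t_end %||% sim$t_end %||% NULL
    )
  }
  structure(list(circuit = circ, t_end = sim$t_end %||% NULL,
                 settings = settings, analysis = analysis, raw = raw,
                 path = path),
            class = "netlist")
}

#' Serialize a netlist back to a file
#'
#' Writes the loaded representation verbatim (lossless round trip: loading
#' the written file yields an equivalent circuit).
#'
#' @param netlist a [load_netlist()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_netlist <- function(netlist, path) {
  stopifnot(inherits(netlist, "netlist"))
  yaml::write_yaml(netlist$raw, path)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Header `time_s`, then node columns, then element-current columns, in
#' deterministic declaration order; values are printed at full double
#' precision (17 significant digits round-trip exactly).
#'
#' @param trajectory a trajectory.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- as.data.frame(trajectory)
  header <- paste(colnames(df), collapse = ",")
  rows <- apply(df, 1L, function(r)
    paste(sprintf("%.17g", as.numeric(r)), collapse = ","))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Path to a bundled example netlist
#'
#' @param name file name (e.g. `"betagal_mm.netlist"`); with no argument,
#'   lists the bundled examples.
#' @return a file path, or a character vector of available names.
#' @export
example_netlist <- function(name = NULL) {
  dir <- system.file("extdata", package = "kincirc")
  if (is.null(name)) return(list.files(dir, pattern = "[.]netlist$"))
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop("no bundled netlist '", name, "'; available: ",
         paste(list.files(dir, pattern = "[.]netlist$"), collapse = ", "),
         call. = FALSE)
  path
}
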