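#' Unit helpers for concentrations
#'
#' All quantities inside a circuit are expressed in molar (M) and seconds.
#' Published kinetic constants mix mM, uM and nM, so these tag-style helpers
#' convert at the boundary: `mM(0.167)` is the molar value `1.67e-4`.
#'
#' @param x numeric vector of concentrations in the tagged unit.
#' @return numeric vector in molar.
#' @examples
#' mM(2)        # 0.002 M
#' nM(0.3)      # 3e-10 M
#' @name units
NULL

#' @rdname units
#' @export
mM <- function(x) x * 1e-3

#' @rdname units
#' @export
uM <- function(x) x * 1e-6

#' @rdname units
#' @export
nM <- function(x) x * 1e-9

#' @rdname units
#' @export
molar <- function(x) x

# Conversion table used by the netlist reader.  Rate-constant tags are
# dimensionally distinct but numerically pass-through except per-mM-style
# bimolecular tags.
.unit_factors <- c(
  M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12,
  per_s = 1, per_M_s = 1, per_mM_s = 1e3, per_uM_s = 1e6, per_nM_s = 1e9,
  s = 1, nt = 1, nt_per_s = 1, dimensionless = 1
)

#' Parse a unit-tagged quantity string
#'
#' Netlist values are written as `"0.167 mM"` or `"2903 per_s"`.  Bare
#' numbers are rejected for concentrations so that unit mistakes fail loudly.
#'
#' @param x a string like `"0.167 mM"`, or a plain numeric (returned as-is
#'   only when `require_unit = FALSE`).
#' @param require_unit reject untagged numerics?
#' @return numeric scalar in internal units (M, s).
#' @export
parse_quantity <- function(x, require_unit = TRUE) {
  if (is.numeric(x)) {
    if (require_unit)
      stop("quantity ", deparse(x), " has no unit tag; write e.g. '",
           x, " mM' or '", x, " per_s'", call. = FALSE)
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  if (identical(toupper(x), "UNKNOWN"))
    stop("quantity is an UNKNOWN placeholder; supply a numeric value with ",
         "a unit tag before simulating", call. = FALSE)
  parts <- strsplit(x, "[[:space:]]+")[[1]]
  if (length(parts) == 1L) {
    val <- suppressWarnings(as.numeric(parts))
    if (is.na(val))
      stop("cannot parse quantity '", x, "'", call. = FALSE)
    if (require_unit)
      stop("quantity '", x, "' has no unit tag", call. = FALSE)
    return(val)
  }
  if (length(parts) != 2L)
    stop("cannot parse quantity '", x, "'", call. = FALSE)
  val <- suppressWarnings(as.numeric(parts[1L]))
  if (is.na(val))
    stop("cannot parse quantity '", x, "'", call. = FALSE)
  unit <- parts[2L]
  if (!unit %in% names(.unit_factors))
    stop("unknown unit tag '", unit, "' in '", x, "'", call. = FALSE)
  val * .unit_factors[[unit]]
}
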