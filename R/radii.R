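#' Van der Waals radius table
#'
#' Radii (in Angstrom) used by the surface-section contact algorithm.
#' The carbon radius of 1.88 A is fixed by the published candidate cutoff
#' for two carbons: each radius enlarged by the 1.4 A water probe gives
#' 2 x (1.88 + 1.4) = 6.56 A. The remaining values follow the
#' contacts-of-structural-units lineage and can be overridden.
#'
#' @param probe_radius Water probe radius in Angstrom (default 1.4).
#' @param default Radius used (with a warning) for elements not in the
#'   table.
#' @param ... Named element overrides, e.g. `C = 1.9`.
#' @return An object of class `fn_radius_table`.
#' @export
#' @examples
#' rt <- radius_table()
#' vdw_radius("C", rt) # 1.88
radius_table <- function(probe_radius = 1.4, default = 1.8, ...) {
  stopifnot(probe_radius > 0, default > 0)
  radii <- c(C = 1.88, N = 1.64, O = 1.42, S = 1.77, H = 1.0, SE = 1.9)
  overrides <- c(...)
  if (length(overrides) > 0) {
    stopifnot(!is.null(names(overrides)), all(overrides > 0))
    radii[names(overrides)] <- overrides
  }
  structure(
    list(radii = radii, probe_radius = probe_radius, default = default),
    class = "fn_radius_table"
  )
}

#' Look up van der Waals radii by element
#'
#' Unknown elements fall back to the table's default radius with a
#' warning.
#'
#' @param element Character vector of element symbols.
#' @param table A [radius_table()].
#' @return Numeric vector of radii (Angstrom).
#' @export
vdw_radius <- function(element, table = radius_table()) {
  element <- toupper(element)
  r <- unname(table$radii[element])
  unknown <- is.na(r)
  if (any(unknown)) {
    warn(paste0(
      "unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
      "; using default radius ", table$default, " A"
    ))
    r[unknown] <- table$default
  }
  r
}
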