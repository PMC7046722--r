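#' Bundled element property table
#'
#' Bondi van der Waals radii (Angstrom) and standard atomic masses (Da) for
#' the elements that occur in protein structures. Unknown elements fall back
#' to a 1.7 Angstrom radius and a 12 Da mass with a warning.
#'
#' @return data.frame with columns \code{element}, \code{vdw_radius}, \code{mass}.
#' @export
element_table <- function() {
  data.frame(
    element    = c("H",    "C",    "N",    "O",    "S",    "P",    "SE",   "F",   "CL",  "BR",  "I",   "FE",  "ZN",  "MG",  "CA",  "NA",  "K"),
    vdw_radius = c(1.20,   1.70,   1.55,   1.52,   1.80,   1.80,   1.90,   1.47,  1.75,  1.85,  1.98,  2.00,  1.39,  1.73,  2.31,  2.27,  2.75),
    mass       = c(1.008, 12.011, 14.007, 15.999, 32.06,  30.974, 78.971, 18.998, 35.45, 79.904, 126.90, 55.845, 65.38, 24.305, 40.078, 22.990, 39.098),
    stringsAsFactors = FALSE
  )
}

.element_fallback_radius <- 1.7
.element_fallback_mass <- 12.0

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element columns (77-78) of a PDB record are absent. The
#' leading digits of the atom name are stripped (e.g. "1HB1"), then the first
#' character is taken unless the two leading characters form a known
#' two-letter element (SE, CL, BR, FE, ZN, MG, NA).
#'
#' @param atom_name atom name string, whitespace allowed.
#' @return single-character (or two-character) element symbol, upper case.
#' @export
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  if (nchar(nm) == 0L) return("C")
  two <- substr(nm, 1L, 2L)
  # two-letter symbols that actually occur in PDB atom names; CA/CD etc. are
  # carbons in amino acids, so only unambiguous two-letter elements qualify
  if (two %in% c("SE", "CL", "BR", "FE", "ZN", "MG")) return(two)
  substr(nm, 1L, 1L)
}

# Look up radius/mass for a vector of element symbols, warning once per
# unknown symbol.
.element_props <- function(elements) {
  tab <- element_table()
  idx <- match(toupper(elements), tab$element)
  unknown <- unique(elements[is.na(idx)])
  if (length(unknown) > 0L) {
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using vdW radius ", .element_fallback_radius,
            " A and mass ", .element_fallback_mass, " Da", call. = FALSE)
  }
  list(
    vdw_radius = ifelse(is.na(idx), .element_fallback_radius, tab$vdw_radius[idx]),
    mass       = ifelse(is.na(idx), .element_fallback_mass, tab$mass[idx])
  )
}
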