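#' Select atoms with a small expression language
#'
#' Supported clauses, joined by \code{and}:
#' \itemize{
#'   \item \code{name CA} (one or more atom names)
#'   \item \code{backbone} — atoms named N, CA, C, O
#'   \item \code{calpha} — atoms named CA
#'   \item \code{resid 37:47} — author (PDB) residue number range or list
#'   \item \code{index 17:27} — 1-based residue sequence-position range or list
#'   \item \code{chain A} — chain identifiers
#'   \item \code{element C N} — element symbols
#' }
#' Author-numbered ranges and sequence-index ranges address the same residues
#' through the chain's numbering offset; for the TREM2 ectodomain (offset
#' +20) \code{"resid 37:47"} and \code{"index 17:27"} are the same CDR1 loop.
#'
#' @param structure a \code{\link{Structure}}.
#' @param expression selection string.
#' @return object of class \code{"AtomSelection"}: list with \code{indices}
#'   (ordered, duplicate-free, 1-based atom positions) and \code{label}.
#' @export
select_atoms <- function(structure, expression) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  if (length(clauses) == 0L || all(trimws(clauses) == "")) {
    stop("selection syntax error: empty expression")
  }
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(toks[1])
    args <- toks[-1]
    keep <- keep & switch(kw,
      backbone = a$name %in% c("N", "CA", "C", "O"),
      calpha   = a$name == "CA",
      name     = a$name %in% .sel_args(args, cl, character = TRUE),
      element  = a$element %in% toupper(.sel_args(args, cl, character = TRUE)),
      chain    = a$chain %in% .sel_args(args, cl, character = TRUE),
      resid    = a$author_resid %in% .sel_numbers(args, cl),
      index    = a$resindex %in% .sel_numbers(args, cl),
      stop("selection syntax error: unknown keyword '", kw, "' in '", cl, "'")
    )
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty selection: '", expression, "'")
  AtomSelection(idx, label = expression)
}

.sel_args <- function(args, clause, character = FALSE) {
  if (length(args) == 0L) stop("selection syntax error: '", clause,
                               "' needs arguments")
  args
}

.sel_numbers <- function(args, clause) {
  vals <- integer(0)
  .sel_args(args, clause)
  for (arg in args) {
    if (grepl("^-?[0-9]+:-?[0-9]+$", arg)) {
      ab <- as.integer(strsplit(arg, ":")[[1]])
      vals <- c(vals, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", arg)) {
      vals <- c(vals, as.integer(arg))
    } else {
      stop("selection syntax error: bad number '", arg, "' in '", clause, "'")
    }
  }
  vals
}

#' Construct an AtomSelection
#' @param indices ordered, duplicate-free 1-based atom positions.
#' @param label free-text label.
#' @return object of class \code{"AtomSelection"}.
#' @export
AtomSelection <- function(indices, label = "") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be duplicate-free")
  structure(list(indices = indices, label = label), class = "AtomSelection")
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat("AtomSelection '", x$label, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

# resolve a selection argument: AtomSelection, expression string, or NULL
# (meaning all atoms)
.resolve_selection <- function(structure, selection) {
  if (is.null(selection)) {
    AtomSelection(seq_len(n_atoms(structure)), "all")
  } else if (inherits(selection, "AtomSelection")) {
    if (max(selection$indices) > n_atoms(structure)) {
      stop("selection indices out of bounds")
    }
    selection
  } else {
    select_atoms(structure, selection)
  }
}
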