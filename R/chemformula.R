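#' @keywords internal
"_PACKAGE"

# Monoisotopic atomic masses (IUPAC), Da. Six supported elements are enough
# for every composition handled here (CHNOPS covers triterpenoids, their
# glycosides, nitrogenous congeners and lyso-PI lipids).
.ATOMIC_MASS <- c(
  C = 12.000000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.9737615120,
  S = 31.9720706912
)

#' Mass of the electron in daltons
#'
#' Singly charged anions weigh one electron more than the sum of their
#' atoms; this constant is what makes a computed \eqn{[M-H]^-} m/z agree
#' with high-resolution instrument output at the fourth decimal place.
#' @export
ELECTRON_MASS <- 0.00054857990907

.SUPPORTED_ELEMENTS <- names(.ATOMIC_MASS)

#' Parse an elemental formula string
#'
#' Accepts Hill-style concatenations of element symbols with optional
#' integer counts, e.g. `"C30H40O4"` or `"C44H73NO14"`. Supported elements
#' are C, H, N, O, P and S; anything else is rejected with an error naming
#' the offending token.
#'
#' @param text A single formula string.
#' @return An `elemental_formula`: a named integer vector of element counts
#'   (zero counts dropped), ordered C, H, then remaining elements
#'   alphabetically.
#' @examples
#' parse_formula("C30H40O4")
#' parse_formula("C44H73NO14")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string")
  }
  if (!nzchar(text)) stop("empty formula string")
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(tokens)) != nchar(text)) {
    bad <- substr(gsub(paste(tokens, collapse = "|"), "", text), 1, 8)
    stop("malformed formula '", text, "': unparsable token near '", bad, "'")
  }
  counts <- stats::setNames(rep(0L, length(.SUPPORTED_ELEMENTS)), .SUPPORTED_ELEMENTS)
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    if (!el %in% .SUPPORTED_ELEMENTS) {
      stop("unsupported element '", el, "' in formula '", text, "'")
    }
    num <- gsub("[A-Za-z]", "", tok)
    n <- if (nzchar(num)) suppressWarnings(as.integer(num)) else 1L
    if (is.na(n)) stop("malformed count '", num, "' in formula '", text, "'")
    counts[el] <- counts[el] + n
  }
  as_formula(counts)
}

#' Construct an elemental formula from a count vector
#'
#' @param counts Named numeric vector of non-negative element counts.
#' @return An `elemental_formula` object.
#' @export
as_formula <- function(counts) {
  if (inherits(counts, "elemental_formula")) return(counts)
  if (length(counts) && is.null(names(counts))) stop("counts must be named")
  bad <- setdiff(names(counts), .SUPPORTED_ELEMENTS)
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative element counts are not a formula")
  if (any(counts != round(counts))) stop("element counts must be integers")
  counts <- counts[counts > 0]
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  out <- stats::setNames(as.integer(counts[ord]), ord)
  structure(out, class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  if (!length(x)) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.4f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
`==.elemental_formula` <- function(e1, e2) {
  identical(unclass(as_formula(e1)), unclass(as_formula(e2)))
}

#' Combine two formulas by element-wise addition
#'
#' @param a,b Formulas (objects or strings).
#' @return Their elemental union as an `elemental_formula`.
#' @export
formula_add <- function(a, b) {
  a <- .as_counts(a); b <- .as_counts(b)
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  as_formula(out)
}

#' Subtract one formula from another
#'
#' @param a,b Formulas; every element count in `b` must be covered by `a`.
#' @return The difference as an `elemental_formula`.
#' @export
formula_subtract <- function(a, b) {
  a <- .as_counts(a); b <- .as_counts(b)
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) stop("formula subtraction would give negative counts")
  as_formula(out)
}

.as_counts <- function(f) {
  f <- if (is.character(f)) parse_formula(f) else as_formula(f)
  stats::setNames(as.numeric(f), names(f))
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum of count-weighted monoisotopic atomic masses. Additive over formula
#' union: `monoisotopic_mass(formula_add(a, b))` equals
#' `monoisotopic_mass(a) + monoisotopic_mass(b)`.
#'
#' @param f Formula object or string.
#' @return Mass in daltons.
#' @examples
#' monoisotopic_mass("C2H3NO") # the 57.02 Da nitrogenous loss
#' @export
monoisotopic_mass <- function(f) {
  cnt <- .as_counts(f)
  if (!length(cnt)) return(0)
  sum(.ATOMIC_MASS[names(cnt)] * cnt)
}

#' m/z of an anion from its ion composition
#'
#' Mass of an already-deprotonated composition (e.g. `C30H39O4` for the
#' \eqn{[M-H]^-} ion of a C30H40O4 triterpenoid, or `C8H12NO5` for the
#' deprotonated HexNAc fragment): atomic masses plus one electron.
#'
#' @param ion Formula of the ion itself (not the neutral).
#' @return m/z in daltons for charge 1-.
#' @examples
#' anion_mz("C30H39O4") # 463.2854
#' @export
anion_mz <- function(ion) {
  monoisotopic_mass(ion) + ELECTRON_MASS
}

#' m/z of the deprotonated ion of a neutral molecule
#'
#' \eqn{[M-H]^-} m/z = neutral monoisotopic mass minus one hydrogen atom
#' plus one electron.
#'
#' @param neutral Formula of the neutral molecule; must contain hydrogen.
#' @return m/z in daltons.
#' @examples
#' mz_deprotonated("C30H40O4") # 463.2854
#' @export
mz_deprotonated <- function(neutral) {
  f <- if (is.character(neutral)) parse_formula(neutral) else as_formula(neutral)
  cnt <- .as_counts(f)
  if (is.na(cnt["H"]) || cnt["H"] < 1) {
    stop("cannot deprotonate '", format(f), "': no hydrogen to remove")
  }
  monoisotopic_mass(f) - .ATOMIC_MASS[["H"]] + ELECTRON_MASS
}

#' Nominal (integer) mass
#'
#' Fragment ions in negative-mode triterpenoid work are conventionally
#' quoted at integer m/z; this rounds a monoisotopic value to the nearest
#' integer (half-up).
#'
#' @param mz A numeric mass or m/z.
#' @return Integer nominal mass.
#' @export
nominal_mass <- function(mz) {
  as.integer(floor(mz + 0.5))
}

#' Ring-and-double-bond equivalents of a neutral CHNOPS formula
#'
#' RDBE = C - H/2 + N/2 + P/2 + 1 (phosphorus treated as trivalent;
#' oxygen and sulfur do not contribute). Defined for neutral, even-electron
#' molecules, where it is an integer.
#'
#' @param f Formula object or string.
#' @return Number of degrees of unsaturation.
#' @examples
#' rdbe("C30H40O4") # 11
#' @export
rdbe <- function(f) {
  cnt <- .as_counts(f)
  g <- function(el) if (el %in% names(cnt)) cnt[[el]] else 0
  g("C") - g("H") / 2 + g("N") / 2 + g("P") / 2 + 1
}

#' Relative mass error in parts per million
#'
#' @param measured Observed m/z.
#' @param theoretical Computed m/z; must be positive.
#' @return `(measured - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(463.2850, 463.2854)
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (measured - theoretical) / theoretical * 1e6
}

#' Candidate formulas for an observed neutral mass difference
#'
#' Exhaustive search over a bounded CHNOPS lattice for compositions whose
#' neutral monoisotopic mass falls within a ppm tolerance of an observed
#' mass delta — the desk equivalent of instrument-software formula
#' generation with an error window.
#'
#' @param delta_mass Observed neutral mass difference in Da (>= 0).
#' @param tol_ppm Tolerance in ppm (default 10).
#' @param bounds Named integer vector of per-element maximum counts, e.g.
#'   `c(C = 12, H = 24, O = 10)`. Elements absent from `bounds` are not
#'   searched. An empty bounds vector yields an empty candidate list.
#' @param max_lattice Safety cap on the number of lattice points searched.
#' @return A list of `elemental_formula` candidates ordered by absolute ppm
#'   error, ties broken by formula string; empty list when nothing fits.
#' @examples
#' infer_delta_formula(43.9898, 10, c(C = 3, H = 6, O = 3))[[1]] # CO2
#' @export
infer_delta_formula <- function(delta_mass, tol_ppm = 10, bounds,
                                max_lattice = 1e6) {
  if (delta_mass < 0) stop("delta_mass must be non-negative")
  if (delta_mass == 0) return(list(as_formula(integer(0))))
  if (missing(bounds) || !length(bounds)) return(list())
  bad <- setdiff(names(bounds), .SUPPORTED_ELEMENTS)
  if (length(bad)) stop("unsupported element(s) in bounds: ",
                        paste(bad, collapse = ", "))
  n_points <- prod(bounds + 1)
  if (n_points > max_lattice) {
    stop("bounds define ", format(n_points), " lattice points (cap ",
         format(max_lattice), ")")
  }
  grid <- expand.grid(lapply(bounds, function(k) 0:k),
                      KEEP.OUT.ATTRS = FALSE)
  masses <- as.matrix(grid) %*% .ATOMIC_MASS[names(bounds)]
  ppm <- (masses - delta_mass) / delta_mass * 1e6
  keep <- which(abs(ppm) <= tol_ppm)
  if (!length(keep)) return(list())
  cand <- lapply(keep, function(i) as_formula(unlist(grid[i, , drop = TRUE])))
  strs <- vapply(cand, format, character(1))
  ord <- order(abs(ppm[keep]), strs)
  cand[ord]
}
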