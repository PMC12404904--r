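#' @include AllClasses.R
NULL

# Monoisotopic isotope masses (Da), CODATA/NIST, >= 6 decimal places.
# "D" is deuterium as a first-class symbol.
.ISOTOPE_MASS <- c(
  H  = 1.007825032,
  D  = 2.014101778,
  C  = 12.000000000,
  N  = 14.003074005,
  O  = 15.994914620,
  S  = 31.972071174,
  P  = 30.973761998,
  Na = 22.989769282,
  K  = 38.963706487,
  Cl = 34.968852682,
  F  = 18.998403163,
  Br = 78.918337600,
  I  = 126.904471900,
  Si = 27.976926535,
  Fe = 55.934935900,
  Se = 79.916521800
)

#' Physical-constant masses (Da)
#'
#' Proton and electron rest masses used in adduct and cation arithmetic.
#' The proton mass (not the hydrogen atom mass) is the \code{[M+H]+} mass
#' delta, so that the electron removed on protonation is accounted for.
#' @name mass-constants
#' @keywords internal
PROTON_MASS <- 1.007276466
ELECTRON_MASS <- 0.000548580

#' Parse a molecular formula into an element composition
#'
#' Hill-style formulas with deuterium as a first-class symbol \code{D}
#' (the alias \code{[2H]} is accepted on input and normalized to \code{D}).
#' Repeated symbols accumulate: \code{"C2C3"} is \code{C5}. Parsing is
#' case-sensitive for element symbols.
#'
#' @param text character(1) formula, e.g. \code{"C12H20D3NO4"}.
#' @return named integer vector of element counts (a composition); elements
#'   absent from the formula are simply absent (count 0).
#' @examples
#' parseFormula("C9H14D3NO4")
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    stop("formula must be a single string")
  text <- gsub("[2H]", "D", text, fixed = TRUE) # bracketed deuterium alias
  if (!nzchar(text)) stop("empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || !length(toks))
    stop("malformed formula: ", text)
  counts <- integer()
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.ISOTOPE_MASS))
      stop("unknown element symbol: ", sym)
    if (is.na(n) || n < 1L) stop("malformed count in token: ", tok)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' Composition arithmetic
#'
#' Element-wise addition and subtraction of compositions; subtraction that
#' would make any count negative is an error.
#'
#' @param a,b named integer vectors as returned by [parseFormula()].
#' @return named integer vector; zero counts are dropped.
#' @export
addComposition <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    (if (s %in% names(a)) a[[s]] else 0L) + (if (s %in% names(b)) b[[s]] else 0L)
  }, integer(1))
  out[out != 0L]
}

#' @rdname addComposition
#' @export
subtractComposition <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    (if (s %in% names(a)) a[[s]] else 0L) - (if (s %in% names(b)) b[[s]] else 0L)
  }, integer(1))
  if (any(out < 0L))
    stop("subtraction yields negative count for: ",
         paste(names(out)[out < 0L], collapse = ", "))
  out[out != 0L]
}

#' Monoisotopic mass of a composition
#'
#' @param comp named integer vector of element counts, or a formula string
#'   (parsed with [parseFormula()]).
#' @return mass in Da. Additive: \code{monoisotopicMass(a) +
#'   monoisotopicMass(b)} equals the mass of the combined composition.
#' @examples
#' monoisotopicMass("C3H9N") # trimethylamine, 59.0735
#' @export
monoisotopicMass <- function(comp) {
  if (is.character(comp)) comp <- parseFormula(comp)
  if (!length(comp)) return(0)
  if (any(comp < 0)) stop("negative element counts")
  bad <- setdiff(names(comp), names(.ISOTOPE_MASS))
  if (length(bad)) stop("no tabulated mass for: ", paste(bad, collapse = ", "))
  sum(.ISOTOPE_MASS[names(comp)] * as.numeric(comp))
}

# Small built-in adduct set; mass_delta includes the electron bookkeeping.
.ADDUCTS <- list(
  "[M+H]+"  = list(massDelta = PROTON_MASS, charge = 1L),
  "[M+Na]+" = list(massDelta = 22.989769282 - 0.000548580, charge = 1L),
  "[M-H]-"  = list(massDelta = -(1.007825032 - 0.000548580), charge = -1L)
)

#' m/z of an adduct ion
#'
#' \code{(monoisotopicMass(comp) + massDelta) / |charge|} for a small
#' built-in adduct set (\code{[M+H]+}, \code{[M+Na]+}, \code{[M-H]-}).
#' The mass delta accounts for electron mass (protonation adds a proton,
#' 1.007276466 Da, not a hydrogen atom).
#'
#' @param comp composition or formula string of the neutral molecule.
#' @param adduct character(1) adduct label, default \code{"[M+H]+"}.
#' @return m/z (full precision; round for display).
#' @examples
#' adductMz("C12H20D3NO4")            # 249.1888 (valeryl-carnitine-d3)
#' adductMz("C9H14D3NO4", "[M+H]+")   # 207.1419
#' @export
adductMz <- function(comp, adduct = "[M+H]+") {
  spec <- .ADDUCTS[[adduct]]
  if (is.null(spec)) stop("unknown adduct: ", adduct,
                          " (supported: ", paste(names(.ADDUCTS), collapse = ", "), ")")
  if (spec$charge == 0L) stop("adduct charge must be nonzero")
  (monoisotopicMass(comp) + spec$massDelta) / abs(spec$charge)
}

#' Product-ion m/z after a neutral loss
#'
#' For a singly-charged precursor, the product ion m/z is the precursor m/z
#' minus the monoisotopic mass of the departed neutral (e.g. trimethylamine
#' \code{C3H9N} or its d3 analog \code{C3H6D3N} for acylcarnitines).
#'
#' @param precursorMz precursor m/z at charge 1.
#' @param loss composition or formula string of the neutral loss.
#' @return product-ion m/z.
#' @examples
#' neutralLossProductMz(207.1419, "C3H9N") # 148.0684
#' @export
neutralLossProductMz <- function(precursorMz, loss) {
  lm <- monoisotopicMass(loss)
  if (precursorMz <= lm)
    stop("neutral loss (", format(lm), " Da) is not lighter than the precursor")
  precursorMz - lm
}

#' m/z of a bare cation from its formula
#'
#' Sum of atom masses minus \code{charge} electron masses, divided by the
#' charge; used e.g. for the acylcarnitine-diagnostic fragment
#' \code{C4H5O2+} at m/z 85.0284.
#'
#' @param comp composition or formula string of the ion's atoms.
#' @param charge positive integer charge, default 1.
#' @return m/z.
#' @examples
#' cationMz("C4H5O2") # 85.0284
#' @export
cationMz <- function(comp, charge = 1L) {
  if (charge <= 0) stop("charge must be a positive integer")
  (monoisotopicMass(comp) - charge * ELECTRON_MASS) / charge
}

#' Signed ppm error of an observed m/z against a reference
#'
#' Computed against the reference (query) m/z, the fixed anchor:
#' \code{(observed - reference) / reference * 1e6}.
#'
#' @param observed,reference m/z values; \code{reference > 0}.
#' @return signed ppm (vectorized over \code{observed}).
#' @export
ppmError <- function(observed, reference) {
  if (any(reference <= 0)) stop("reference m/z must be positive")
  (observed - reference) / reference * 1e6
}

#' Tolerance test for an m/z match
#'
#' Boundary-inclusive: in ppm mode \code{|ppmError| <= value}, in absolute
#' mode \code{|observed - reference| <= value}.
#'
#' @param observed,reference m/z values.
#' @param tol \code{list(mode, value)} with mode \code{"ppm"} or
#'   \code{"absolute_mz"} and a positive value, e.g.
#'   \code{tolerancePpm(10)}.
#' @return logical, vectorized over \code{observed}.
#' @export
withinTolerance <- function(observed, reference, tol = tolerancePpm(10)) {
  stopifnot(is.list(tol), tol$value > 0)
  if (tol$mode == "ppm") abs(ppmError(observed, reference)) <= tol$value
  else if (tol$mode == "absolute_mz") abs(observed - reference) <= tol$value
  else stop("unknown tolerance mode: ", tol$mode)
}

#' Tolerance constructors
#'
#' @param value positive tolerance (ppm, or Da for the absolute form).
#' @return \code{list(mode, value)}.
#' @export
tolerancePpm <- function(value = 10) {
  stopifnot(is.numeric(value), length(value) == 1, value > 0)
  list(mode = "ppm", value = value)
}

#' @rdname tolerancePpm
#' @export
toleranceMz <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, value > 0)
  list(mode = "absolute_mz", value = value)
}
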