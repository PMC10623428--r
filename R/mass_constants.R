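#' Monoisotopic atomic masses
#'
#' Masses (Da) of the most abundant isotope of each supported element, taken
#' from standard atomic-mass tables (AME-derived values as used by common
#' mass-spectrometry calculators), plus the electron rest mass. All adduct
#' arithmetic in the package flows through these constants so that every
#' theoretical m/z in the pipeline is traceable to this one table.
#'
#' @format Named numeric vector of monoisotopic masses in Da.
#' @export
atomic_monoisotopic_masses <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692820,
  K  = 38.9637064864,
  I  = 126.904473
)

#' Electron rest mass in Da
#' @export
electron_mass_da <- 0.000548579909

#' Supported cation adducts
#'
#' Mass shifts (Da) added to a neutral monoisotopic mass M to obtain the
#' singly charged adduct m/z. Each shift is the summed atomic mass of the
#' adduct atoms minus lost atoms, minus one electron mass for the positive
#' charge (e.g. \code{M+K} adds 38.963158 Da, not the neutral 38.963706).
#'
#' @return Named numeric vector of adduct mass shifts in Da.
#' @export
adduct_mass_shifts <- function() {
  am <- atomic_monoisotopic_masses
  e <- electron_mass_da
  c(
    "M+H"     = unname(am["H"] - e),
    "M+Na"    = unname(am["Na"] - e),
    "M+K"     = unname(am["K"] - e),
    "M+2Na-H" = unname(2 * am["Na"] - am["H"] - e)
  )
}

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style formula string (e.g. \code{"C10H13N4O8P"}) and sums the
#' monoisotopic masses of its atoms. Only elements present in
#' [atomic_monoisotopic_masses] are supported; an unknown element symbol is an
#' error naming the symbol.
#'
#' @param formula character scalar, e.g. \code{"C39H71O8P"}.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")          # 18.010565
#' monoisotopic_mass("C10H13N4O8P") # inosine monophosphate, 348.0471
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  formula <- trimws(formula)
  if (!nzchar(formula)) stop("empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("unparsable formula: '", formula, "'")
  }
  el <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(el, names(atomic_monoisotopic_masses))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  sum(atomic_monoisotopic_masses[el] * cnt)
}

#' Theoretical adduct m/z
#'
#' @param formula elemental formula of the neutral molecule.
#' @param adduct one of the adducts named by [adduct_mass_shifts()].
#' @return Theoretical m/z (Da) of the singly charged adduct.
#' @export
adduct_mz <- function(formula, adduct) {
  shifts <- adduct_mass_shifts()
  if (!adduct %in% names(shifts)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(shifts), collapse = ", "))
  }
  monoisotopic_mass(formula) + shifts[[adduct]]
}
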