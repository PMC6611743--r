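# Monoisotopic mass arithmetic. Deuterium is a first-class element symbol "D"
# throughout the package so that H and D bookkeeping never mixes.

.hdx_masses <- c(
  H  = 1.007825,
  D  = 2.014102,
  B  = 11.009305,
  C  = 12.000000,
  N  = 14.003074,
  O  = 15.994915,
  F  = 18.998403,
  Na = 22.989770,
  Si = 27.976927,
  P  = 30.973762,
  S  = 31.972071,
  Cl = 34.968853,
  K  = 38.963707,
  Br = 78.918338,
  I  = 126.904473
)

.electron_mass <- 0.00054858
.mass_13C <- 13.003355
# mass gained per H -> D exchange
.delta_hd <- unname(.hdx_masses["D"] - .hdx_masses["H"])

#' Monoisotopic mass table
#'
#' Element symbol to monoisotopic mass (Da). Deuterium is listed as a distinct
#' element `"D"`; the electron mass is returned as attribute `electron`.
#'
#' @return Named numeric vector of masses in Da.
#' @export
#' @examples
#' hdx_mass_table()[c("H", "D")]
hdx_mass_table <- function() {
  structure(.hdx_masses, electron = .electron_mass)
}

#' Mass gained per hydrogen/deuterium exchange
#'
#' m(D) - m(H) = 1.006277 Da, the shift per exchanged hydrogen.
#'
#' @return Length-one numeric (Da).
#' @export
hdx_mass_shift <- function() .delta_hd

#' Molecular formula with separate deuterium accounting
#'
#' Builds a formula object from an element -> count map. Deuterium (`"D"`) is a
#' separate entry from hydrogen. The string rendering uses Hill order (C, H, D,
#' then remaining elements alphabetically) with a trailing charge sign, and
#' [parse_formula()] round-trips it.
#'
#' @param counts Named integer vector (element -> count), all counts >= 0.
#' @param charge Integer formal charge of the species (default 0).
#' @return An object of class `mol_formula`.
#' @export
#' @examples
#' f <- mol_formula(c(C = 4, H = 3, D = 6, O = 1), charge = 1)
#' format(f)
#' monoisotopic_mass(f)
mol_formula <- function(counts, charge = 0L) {
  if (length(counts) && is.null(names(counts)))
    stop("`counts` must be a named vector (element -> count)")
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("formula counts must be >= 0")
  bad <- setdiff(names(counts), names(.hdx_masses))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- vapply(split(as.integer(counts), names(counts)), sum, integer(1))
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  cnt <- x$counts
  lead <- intersect(c("C", "H", "D"), names(cnt))
  rest <- sort(setdiff(names(cnt), lead))
  ord <- c(lead, rest)
  body <- paste0(ord, ifelse(cnt[ord] > 1L, cnt[ord], ""), collapse = "")
  sign <- if (x$charge > 0) strrep("+", x$charge)
          else if (x$charge < 0) strrep("-", -x$charge)
          else ""
  paste0(body, sign)
}

#' @export
print.mol_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a molecular formula string
#'
#' Inverse of `format()` on [mol_formula()] objects: element symbols with
#' optional counts and an optional trailing run of `+`/`-` charge signs.
#'
#' @param text Formula string, e.g. `"C7H6O5"` or `"C4H3D6O+"`.
#' @return A `mol_formula` object.
#' @export
parse_formula <- function(text) {
  text <- trimws(text)
  charge <- nchar(gsub("[^+]", "", text)) - nchar(gsub("[^-]", "", text))
  body <- gsub("[+-]", "", text)
  if (!grepl("^([A-Z][a-z]?[0-9]*)*$", body))
    stop("cannot parse formula: ", text)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", body)[[1]]
  toks <- regmatches(body, list(m))[[1]]
  if (length(toks) == 0 && nzchar(body)) stop("cannot parse formula: ", text)
  el <- sub("[0-9]+$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  counts <- stats::setNames(n, el)
  mol_formula(counts, charge = charge)
}

#' Monoisotopic mass of a formula
#'
#' Sum of element monoisotopic masses minus `charge` electron masses; neutral
#' formulas have no electron term.
#'
#' @param f A `mol_formula` object or a formula string.
#' @return Mass in Da (m/z for charged formulas, assuming |z| = 1 per sign).
#' @export
#' @examples
#' monoisotopic_mass("C10H8O6S")   # 256.0042
#' monoisotopic_mass("C7H7+")      # 91.0542
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "mol_formula"))
  if (length(f$counts) == 0 && f$charge == 0) return(0)
  sum(.hdx_masses[names(f$counts)] * f$counts) - f$charge * .electron_mass
}

.adducts <- list(
  "M+H" = c(sign = +1, mass =  1.007825 - 0.00054858),
  "M+D" = c(sign = +1, mass =  2.014102 - 0.00054858),
  "M-H" = c(sign = -1, mass = -1.007825 + 0.00054858),
  "M-D" = c(sign = -1, mass = -2.014102 + 0.00054858)
)

.normalize_adduct <- function(adduct) {
  a <- gsub("\\[|\\]|\\^|\\s", "", adduct)
  a <- sub("\\+$|-$", "", a)   # trailing charge sign of e.g. "[M+H]+"
  a <- gsub("−", "-", a)  # unicode minus
  if (!a %in% names(.adducts)) stop("unsupported adduct: ", adduct)
  a
}

#' Ion m/z under a protonation/deuteronation adduct
#'
#' Supported adducts are `[M+H]+`, `[M+D]+`, `[M-H]-`, `[M-D]-`. Positive
#' adducts add the proton (1.007276 Da) or deuteron (2.013553 Da) mass; negative
#' adducts subtract the neutral H or D mass and add back one electron.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), > 0.
#' @param adduct Adduct label, with or without brackets ("M+H" or "[M+H]+").
#' @return Ion m/z in Da.
#' @export
#' @examples
#' ion_mz(100, "M+H")  # 101.007276
ion_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0)) stop("neutral_mass must be > 0")
  a <- .normalize_adduct(adduct)
  neutral_mass + unname(.adducts[[a]]["mass"])
}

.adduct_mode <- function(adduct) {
  if (unname(.adducts[[.normalize_adduct(adduct)]]["sign"]) > 0) "+" else "-"
}

#' Neutral mass from an ion m/z
#'
#' Inverse of [ion_mz()] for the supported adducts.
#'
#' @inheritParams ion_mz
#' @param mz Observed ion m/z (Da).
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(mz, adduct) {
  a <- .normalize_adduct(adduct)
  mz - unname(.adducts[[a]]["mass"])
}
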