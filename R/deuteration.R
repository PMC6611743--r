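# In silico deuteration: infer the experimentally exchanged hydrogen count X
# from a precursor pair and enumerate deuterated candidate variants.

#' Number of experimentally exchanged hydrogens from a precursor-mass pair
#'
#' Each exchanged hydrogen shifts the neutral mass by m(D) - m(H) = 1.006277 Da,
#' so X is the nearest integer to the mass difference over that shift. The
#' residual deviation is attached in ppm (of the deuterated mass); residuals
#' beyond `max_residual_ppm` trigger a warning (e.g. a wrong isotopic peak
#' picked during data-dependent acquisition) but the pair is never rejected.
#'
#' @param mass_h Neutral monoisotopic mass from the normal spectrum (Da).
#' @param mass_d Neutral monoisotopic mass from the deuterated spectrum (Da).
#' @param max_residual_ppm Residual flag threshold in ppm (default 10).
#' @return Integer X >= 0 with attribute `residual_ppm`.
#' @export
#' @examples
#' determine_X(256.0042, 257.0104)  # 1
determine_X <- function(mass_h, mass_d, max_residual_ppm = 10) {
  stopifnot(mass_h > 0, mass_d > 0)
  diff <- mass_d - mass_h
  x <- as.integer(round(diff / .delta_hd))
  if (x < 0) {
    if (abs(diff) > max_residual_ppm * 1e-6 * mass_d + .delta_hd / 2)
      stop("invalid spectrum pair: deuterated mass below normal mass (dm = ",
           signif(diff, 6), " Da)")
    x <- 0L
  }
  residual_ppm <- (diff - x * .delta_hd) / mass_d * 1e6
  if (abs(residual_ppm) > max_residual_ppm)
    warning(sprintf("precursor pair residual %.1f ppm exceeds %.1f ppm; X = %d may be corrupted",
                    residual_ppm, max_residual_ppm, x))
  structure(x, residual_ppm = residual_ppm)
}

#' Deuterated variants of a candidate
#'
#' A candidate with eH easily exchangeable hydrogens and an observed exchange
#' count X yields: one variant with all exchangeable hydrogens exchanged when
#' eH = X; one variant with all exchanged plus `vH = X - eH` position-unknown
#' deuteriums when eH < X; and `choose(eH, X)` variants (one per X-subset of the
#' exchangeable hydrogens) when eH > X. Disagreement between eH and X is always
#' handled by scoring, never by elimination.
#'
#' Each variant is a list with `d_count` (per-atom deuterium counts over the
#' parent's atoms), `vH` (position-unknown deuterium count), and `ambiguous`
#' (`TRUE` only for the capped combinatorial fallback).
#'
#' @param mol A `molgraph`.
#' @param X Observed exchanged-hydrogen count (integer >= 0).
#' @param max_eH Cap on eH for combinatorial generation (default 20).
#' @param max_variants Cap on the variant count itself (default 5000).
#' @return Object of class `hdx_variants`: list with `eH`, `X`, `variants`.
#' @export
#' @examples
#' mol <- parse_structure("OCC(N)=O")  # eH = 3
#' length(deuterate_candidate(mol, 2)$variants)  # choose(3, 2) = 3
deuterate_candidate <- function(mol, X, max_eH = 20L, max_variants = 5000L) {
  stopifnot(inherits(mol, "molgraph"), X >= 0)
  X <- as.integer(X)
  atoms <- mol$atoms
  n <- nrow(atoms)
  exch_atom <- which(atoms$exchangeable)
  slots <- rep(exch_atom, atoms$nH[exch_atom])  # one slot per exchangeable H
  eH <- length(slots)

  all_exchanged <- function() {
    d <- integer(n)
    d[exch_atom] <- atoms$nH[exch_atom]
    d
  }
  variants <- if (eH <= X) {
    list(list(d_count = all_exchanged(), vH = X - eH, ambiguous = FALSE))
  } else if (eH > max_eH || choose(eH, X) > max_variants) {
    warning(sprintf("eH = %d, X = %d exceeds the combinatorial cap; using one positionally ambiguous variant", eH, X))
    list(list(d_count = integer(n), vH = X, ambiguous = TRUE))
  } else {
    subsets <- utils::combn(eH, X)
    lapply(seq_len(ncol(subsets)), function(j) {
      d <- integer(n)
      for (a in slots[subsets[, j]]) d[a] <- d[a] + 1L
      list(d_count = d, vH = 0L, ambiguous = FALSE)
    })
  }
  structure(list(eH = eH, X = X, variants = variants), class = "hdx_variants")
}

#' @export
print.hdx_variants <- function(x, ...) {
  cat(sprintf("<hdx_variants: eH = %d, X = %d, %d variant(s)>\n",
              x$eH, x$X, length(x$variants)))
  invisible(x)
}

#' Predict the fully exchanged HDX species
#'
#' Replaces every heteroatom-bound hydrogen with deuterium (SH -> SD, OH -> OD,
#' NH2 -> ND2) and reports the deuterated structure with its deuteron-adduct
#' ion masses.
#'
#' @param mol A `molgraph` or a SMILES/InChI string.
#' @return List with `mol` (deuterated graph), `smiles`, `n_d` (number of
#'   deuteriums introduced), `neutral_mass`, `mz_pos` (`[M+D]+`), and `mz_neg`
#'   (`[M-D]-`).
#' @export
#' @examples
#' predict_hdx_species("OC(=O)c1cc(O)c(O)c(O)c1")$n_d  # 4
predict_hdx_species <- function(mol) {
  if (is.character(mol)) mol <- parse_structure(mol)
  stopifnot(inherits(mol, "molgraph"))
  d <- mol
  i <- d$atoms$element %in% c("O", "N", "S")
  n_d <- sum(d$atoms$nH[i])
  d$atoms$nD[i] <- d$atoms$nD[i] + d$atoms$nH[i]
  d$atoms$nH[i] <- 0L
  d$atoms$exchangeable <- FALSE
  m <- structure_mass(d)
  list(mol = d, smiles = write_smiles(d), n_d = n_d, neutral_mass = m,
       mz_pos = ion_mz(m, "M+D"), mz_neg = ion_mz(m, "M-D"))
}

#' Batch HDX species prediction
#'
#' CSV in (identifier, SMILES) to CSV out (identifier, deuterated SMILES, number
#' of deuteriums, `[M+D]+` and `[M-D]-` m/z).
#'
#' @param infile Input CSV with Identifier and SMILES columns.
#' @param outfile Output CSV path; if `NULL` the table is returned only.
#' @return The output table, invisibly when written.
#' @export
predict_hdx_batch <- function(infile, outfile = NULL) {
  cand <- read_candidates(infile)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    p <- predict_hdx_species(parse_structure(cand$smiles[i], id = cand$id[i]))
    data.frame(Identifier = cand$id[i], DeuteratedSMILES = p$smiles,
               nD = p$n_d, mz_MplusD = p$mz_pos, mz_MminusD = p$mz_neg)
  })
  out <- do.call(rbind, rows)
  if (!is.null(outfile)) {
    utils::write.csv(out, outfile, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Probability that all labile hydrogens are exchanged
#'
#' With deuterium atom purity p and n labile hydrogens, complete exchange has
#' probability p^n (e.g. 99% purity and 40 labile hydrogens: 0.99^40 = 66%).
#'
#' @param atom_purity Deuterium atom fraction of the mobile phase, in `[0, 1]`.
#' @param n_labile Number of labile hydrogens (integer >= 0).
#' @return Probability in `[0, 1]`.
#' @export
exchange_completeness_probability <- function(atom_purity, n_labile) {
  stopifnot(atom_purity >= 0, atom_purity <= 1, n_labile >= 0)
  atom_purity^n_labile
}

#' Mass separation between a 13C isotopologue and a monodeuterated species
#'
#' The +1 isotope peak of the undeuterated compound sits only
#' (m(D) - m(H)) - (m(13C) - m(12C)) = 0.00292 Da below a monodeuterated
#' species, which limits untargeted pairing at low resolving power.
#'
#' @param mz m/z at which to express the separation (Da), > 0.
#' @return List with `delta_da` (constant, 5 d.p.) and `ppm` at the given m/z.
#' @export
#' @examples
#' isotope_confusability(400)$ppm  # ~7.3 ppm
isotope_confusability <- function(mz) {
  stopifnot(mz > 0)
  dm <- .delta_hd - (.mass_13C - .hdx_masses[["C"]])
  list(delta_da = round(dm, 5), ppm = dm / mz * 1e6)
}
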