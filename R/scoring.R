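# The four per-candidate scoring terms and the weighted consensus ranking.

#' Default consensus weights
#'
#' The cross-validated weights for (MetFrag, MetFragHD, PairHD, OSN):
#' (0.109, 0.004, 0.497, 0.390).
#'
#' @return Named numeric vector summing to 1.
#' @export
hdx_default_weights <- function() {
  c(MetFrag = 0.109, MetFragHD = 0.004, PairHD = 0.497, OSN = 0.390)
}

.check_weights <- function(w) {
  stopifnot(length(w) == 4, all(w >= 0))
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  if (is.null(names(w))) names(w) <- c("MetFrag", "MetFragHD", "PairHD", "OSN")
  w
}

#' Match fragment hypotheses against a spectrum
#'
#' A peak is matched when some hypothesis mass lies within
#' `max(rel_ppm * m/z / 1e6, abs_da)` of it; among competing hypotheses the
#' lowest-BDE fragment wins, ties broken by smallest mass deviation. Each peak
#' is matched at most once.
#'
#' @param hyps Hypothesis data frame from [fragment_mz_hypotheses()].
#' @param spec An [hdx_spectrum()].
#' @param rel_ppm Relative tolerance (ppm), > 0.
#' @param abs_da Absolute tolerance (Da), > 0.
#' @param all If `TRUE`, return every in-tolerance (peak, hypothesis)
#'   combination instead of the single best explanation per peak; used for
#'   fragment-pair counting, where any valid explanation may pair.
#' @return Object of class `hdx_match`: data frame with one row per matched
#'   peak (`peak`, `mz`, `intensity`, `frag`, `bde`, `dev`, `h_shift`,
#'   `d_shift`, `k`, `nD_exch`) and attribute `n_peaks`.
#' @export
match_fragments <- function(hyps, spec, rel_ppm = 5, abs_da = 0.001,
                            all = FALSE) {
  stopifnot(rel_ppm > 0, abs_da > 0, inherits(spec, "hdx_spectrum"))
  rows <- vector("list", length(spec$mz))
  if (nrow(hyps)) {
    o <- order(hyps$mz)
    hmz <- hyps$mz[o]
    for (p in seq_along(spec$mz)) {
      mzp <- spec$mz[p]
      tol <- max(rel_ppm * mzp / 1e6, abs_da)
      lo <- findInterval(mzp - tol, hmz) + 1L
      hi <- findInterval(mzp + tol, hmz)
      if (hi < lo) next
      cand <- o[lo:hi]
      dev <- hyps$mz[cand] - mzp
      pick <- if (all) cand[order(hyps$bde[cand], abs(dev))]
              else cand[order(hyps$bde[cand], abs(dev))][1]
      ndi <- if (is.null(hyps$nD_ion)) rep(0L, length(pick)) else hyps$nD_ion[pick]
      rows[[p]] <- data.frame(peak = p, mz = mzp, intensity = spec$intensity[p],
                              frag = hyps$frag[pick], bde = hyps$bde[pick],
                              dev = hyps$mz[pick] - mzp,
                              h_shift = hyps$h_shift[pick],
                              d_shift = hyps$d_shift[pick],
                              k = hyps$k[pick], nD_exch = hyps$nD_exch[pick],
                              nD_ion = ndi)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(peak = integer(), mz = numeric(),
                                      intensity = numeric(), frag = integer(),
                                      bde = numeric(), dev = numeric(),
                                      h_shift = integer(), d_shift = integer(),
                                      k = integer(), nD_exch = integer(),
                                      nD_ion = integer())
  structure(out, n_peaks = length(spec$mz),
            max_intensity = if (length(spec$intensity)) max(spec$intensity) else 0,
            class = c("hdx_match", "data.frame"))
}

#' Spectral-match (fragmenter) score
#'
#' Sum over matched peaks of `I_rel^0.6 * mz^3 * exp(-BDE / E0)`, where `I_rel`
#' is the intensity relative to the base peak. The exponents and the energy
#' scale `E0` are declared defaults; rankings rely only on the ordering this
#' induces, not on absolute values.
#'
#' @param match An `hdx_match` from [match_fragments()].
#' @param intensity_exp Exponent on relative intensity (default 0.6).
#' @param mz_exp Exponent on m/z (default 3).
#' @param e0 BDE scale in the same energy units as [bde_table()] (default 500).
#' @return Non-negative raw score.
#' @export
score_fragmenter <- function(match, intensity_exp = 0.6, mz_exp = 3, e0 = 500) {
  if (nrow(match) == 0) return(0)
  base <- max(attr(match, "max_intensity") %||% max(match$intensity), 1e-300)
  sum((match$intensity / base)^intensity_exp * match$mz^mz_exp *
        exp(-match$bde / e0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deuterated spectral-match score
#'
#' Same calculation rule as [score_fragmenter()], applied to a match of the
#' deuterated hypotheses against the deuterated spectrum.
#'
#' @inheritParams score_fragmenter
#' @return Non-negative raw score.
#' @export
score_hd_fragmenter <- function(match, intensity_exp = 0.6, mz_exp = 3, e0 = 500) {
  score_fragmenter(match, intensity_exp, mz_exp, e0)
}

#' Fragment-pair count between the normal and deuterated spectrum
#'
#' Counts fragments whose normal form explains a peak in the normal spectrum
#' and whose deuterated form explains a peak in the deuterated spectrum, where
#' the two peak masses differ by `k * (m(D) - m(H))` within `eps` and `k`
#' equals the deuterium count of the hypothesized fragment ion (its
#' exchange-derived deuteriums `eH(dFrag) + vH(dFrag)`, bounded by X, plus
#' dynamic +-D shifts and the ionizing deuteron); `k = 0` pairs (fragment ions
#' carrying no deuterium at all, identical m/z in both spectra) count as well.
#'
#' Each fragment can pair at most once and consumes its normal and deuterated
#' peak (fragments are visited in increasing BDE order), so the count never
#' exceeds the number of peaks in either spectrum or the number of fragments.
#' Matches computed with `all = TRUE` in [match_fragments()] allow any valid
#' explanation of a peak to pair, not only the single best one.
#'
#' @param match_h `hdx_match` of the normal hypotheses on S_H.
#' @param match_d `hdx_match` of the deuterated hypotheses on S_D.
#' @param X Observed exchanged-hydrogen count.
#' @param eps Pair mass deviation (Da), > 0.
#' @return Integer pair count.
#' @export
score_pair_hd <- function(match_h, match_d, X, eps = 0.001) {
  stopifnot(eps > 0)
  if (nrow(match_h) == 0 || nrow(match_d) == 0) return(0L)
  frs <- intersect(unique(match_h$frag), unique(match_d$frag))
  if (!length(frs)) return(0L)
  bde <- match_h$bde[match(frs, match_h$frag)]
  frs <- frs[order(bde)]
  used_h <- logical(max(match_h$peak))
  used_d <- logical(max(match_d$peak))
  n <- 0L
  for (f in frs) {
    ph <- match_h[match_h$frag == f & !used_h[match_h$peak], , drop = FALSE]
    pd <- match_d[match_d$frag == f & !used_d[match_d$peak], , drop = FALSE]
    if (!nrow(ph) || !nrow(pd)) next
    found <- FALSE
    for (i in seq_len(nrow(ph))) {
      # k on raw peak m/z is the deuterium count of the fragment ION (the
      # ionizing deuteron included); the exchange-derived part stays <= X
      k <- pd$nD_ion
      ok <- which(pd$nD_exch <= X & abs(ph$mz[i] + k * .delta_hd - pd$mz) <= eps)
      if (length(ok)) {
        used_h[ph$peak[i]] <- TRUE
        used_d[pd$peak[ok[1]]] <- TRUE
        n <- n + 1L
        found <- TRUE
        break
      }
    }
    if (found) next
  }
  n
}

#' Exchangeable-hydrogen agreement score
#'
#' `1 / (|X - eH| + 1)`: 1 when the predicted exchangeable-hydrogen count
#' matches the observed exchange count exactly, decaying as they deviate.
#'
#' @param X Observed exchanged-hydrogen count (>= 0).
#' @param eH Candidate's easily exchangeable hydrogen count (>= 0).
#' @return Score in (0, 1].
#' @export
#' @examples
#' score_osn(1, 1)  # 1
#' score_osn(1, 3)  # 1/3
score_osn <- function(X, eH) {
  stopifnot(X >= 0, eH >= 0)
  1 / (abs(X - eH) + 1)
}

#' Filter a raw candidate list
#'
#' Removes candidates that cannot be scored: unparsable structures,
#' multi-component structures (salts, mixtures), and structures carrying
#' isotope labels other than deuterium. Removal counts are reported via
#' `message()`.
#'
#' @param candidates Data frame with columns `id` and `smiles`.
#' @param cache Optional environment reusing parsed structures across calls
#'   (keyed by SMILES).
#' @return Filtered data frame with a `mol` list-column of parsed graphs.
#' @export
filter_candidates <- function(candidates, cache = NULL) {
  stopifnot(all(c("id", "smiles") %in% names(candidates)))
  keep <- logical(nrow(candidates))
  mols <- vector("list", nrow(candidates))
  n_parse <- n_multi <- n_iso <- 0L
  parse_cached <- function(smi, id) {
    if (!is.null(cache)) {
      ent <- cache[[smi]]
      if (!is.null(ent)) return(ent$mol)
    }
    mol <- parse_structure(smi, id = id)
    if (!is.null(cache)) cache[[smi]] <- list(mol = mol)
    mol
  }
  for (i in seq_len(nrow(candidates))) {
    mol <- tryCatch(parse_cached(candidates$smiles[i], candidates$id[i]),
                    error = function(e) NULL)
    if (is.null(mol)) { n_parse <- n_parse + 1L; next }
    if (mol$n_components > 1 || grepl(".", candidates$smiles[i], fixed = TRUE)) {
      n_multi <- n_multi + 1L; next
    }
    if (grepl("\\[1[0-9]{1,2}[A-Z]", candidates$smiles[i]) ||
        grepl("\\[[3-9]H\\]", candidates$smiles[i])) {
      n_iso <- n_iso + 1L; next
    }
    keep[i] <- TRUE
    mols[[i]] <- mol
  }
  if (n_parse + n_multi + n_iso > 0)
    message(sprintf("filtered %d candidate(s): %d unparsable, %d multi-component, %d non-standard isotopes",
                    n_parse + n_multi + n_iso, n_parse, n_multi, n_iso))
  out <- candidates[keep, , drop = FALSE]
  out$mol <- mols[keep]
  rownames(out) <- NULL
  out
}

#' Max-normalize raw scores and rank by weighted consensus
#'
#' Each raw score column is divided by its maximum over the candidate list
#' (columns whose maximum is 0 stay 0), the consensus is the weighted sum of
#' the normalized terms, candidates are sorted by descending consensus, and
#' tied candidates receive the average rank.
#'
#' @param scores Data frame or matrix with columns `MetFrag`, `MetFragHD`,
#'   `PairHD`, `OSN` of raw scores (one row per candidate, variant maxima
#'   already taken).
#' @param weights Weight vector over the four terms, summing to 1.
#' @return Data frame with the normalized scores (`*_norm`), `consensus`, and
#'   `rank` (average rank under ties), in the input row order.
#' @export
consensus_rank <- function(scores, weights = hdx_default_weights()) {
  w <- .check_weights(weights)
  scores <- as.data.frame(scores)
  need <- c("MetFrag", "MetFragHD", "PairHD", "OSN")
  stopifnot(all(need %in% names(scores)))
  if (nrow(scores) == 0) stop("empty candidate list")
  norm <- vapply(need, function(cn) {
    v <- scores[[cn]]
    m <- max(v)
    if (m <= 0) rep(0, length(v)) else v / m
  }, numeric(nrow(scores)))
  norm <- matrix(norm, nrow = nrow(scores),
                 dimnames = list(NULL, paste0(need, "_norm")))
  consensus <- as.numeric(norm %*% w[need])
  out <- cbind(scores[need], as.data.frame(norm))
  out$consensus <- consensus
  out$rank <- rank(-consensus, ties.method = "average")
  out
}
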