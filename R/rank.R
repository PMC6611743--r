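# End-to-end candidate ranking for one normal/deuterated spectrum pair.

#' Ranking configuration
#'
#' @param rel_ppm Relative fragment-match tolerance in ppm (default 5; use 10
#'   for lower-accuracy QTOF data).
#' @param abs_da Absolute fragment-match tolerance in Da (default 0.001; 0.01
#'   for QTOF data).
#' @param eps Pair-count mass deviation in Da; defaults to the combined match
#'   tolerance (`max(rel_ppm * precursor/1e6, abs_da)` evaluated per pair).
#' @param max_depth Fragmentation tree depth (cleavage events, default 2).
#' @param max_hshift Dynamic +-H/+-D hypothesis range (default 2).
#' @param e0 FragmenterScore BDE scale (default 500).
#' @param exclude_precursor Drop peaks at or above the precursor m/z before
#'   scoring (default `TRUE`).
#' @param max_eH,max_variants Combinatorial caps for [deuterate_candidate()].
#' @return Named list of settings.
#' @export
hdx_config <- function(rel_ppm = 5, abs_da = 0.001, eps = NULL, max_depth = 2L,
                       max_hshift = 2L, e0 = 500, exclude_precursor = TRUE,
                       max_eH = 20L, max_variants = 5000L) {
  stopifnot(rel_ppm > 0, abs_da > 0, max_depth >= 0)
  list(rel_ppm = rel_ppm, abs_da = abs_da, eps = eps, max_depth = max_depth,
       max_hshift = max_hshift, e0 = e0, exclude_precursor = exclude_precursor,
       max_eH = max_eH, max_variants = max_variants)
}

.strip_precursor <- function(spec, tol) {
  if (is.na(spec$precursor_mz)) return(spec)
  keep <- spec$mz < spec$precursor_mz - tol
  hdx_spectrum(spec$mz[keep], spec$intensity[keep],
               precursor_mz = spec$precursor_mz, adduct = spec$adduct,
               mode = spec$mode, label = spec$label,
               annotations = spec$annotations)
}

# raw four-term score vector for one candidate (variant maxima taken);
# fragment sets are cached per SMILES in `cache` when given
.score_candidate <- function(mol, spec_h, spec_d, X, cfg, cache = NULL) {
  key <- mol$smiles
  ent <- if (!is.null(cache) && !is.null(key)) cache[[key]] else NULL
  fs <- ent$frags
  if (is.null(fs)) {
    fs <- generate_fragments(mol, max_depth = cfg$max_depth)
    if (!is.null(cache) && !is.null(key)) {
      ent <- ent %||% list(mol = mol)
      ent$frags <- fs
      cache[[key]] <- ent
    }
  }
  mode <- spec_h$mode %||% "+"
  if (is.na(mode)) mode <- "+"
  eps <- cfg$eps %||% max(cfg$rel_ppm * (spec_h$precursor_mz %||% 500) / 1e6,
                          cfg$abs_da)
  if (is.na(eps)) eps <- cfg$abs_da

  best_of <- function(m) {
    b <- m[!duplicated(m$peak), , drop = FALSE]  # rows per peak sorted best-first
    attributes(b)[c("n_peaks", "max_intensity", "class")] <-
      attributes(m)[c("n_peaks", "max_intensity", "class")]
    b
  }
  hyp_h <- fragment_mz_hypotheses(fs, mode = mode, deuterated = FALSE,
                                  max_hshift = cfg$max_hshift)
  match_h_all <- match_fragments(hyp_h, spec_h, cfg$rel_ppm, cfg$abs_da,
                                 all = TRUE)
  s_metfrag <- score_fragmenter(best_of(match_h_all), e0 = cfg$e0)

  dv <- deuterate_candidate(mol, X, max_eH = cfg$max_eH,
                            max_variants = cfg$max_variants)
  s_hd <- 0
  s_pair <- 0L
  for (v in dv$variants) {
    hyp_d <- fragment_mz_hypotheses(fs, mode = mode, deuterated = TRUE,
                                    variant = v, X = X,
                                    max_hshift = cfg$max_hshift)
    match_d_all <- match_fragments(hyp_d, spec_d, cfg$rel_ppm, cfg$abs_da,
                                   all = TRUE)
    s_hd <- max(s_hd, score_hd_fragmenter(best_of(match_d_all), e0 = cfg$e0))
    s_pair <- max(s_pair, score_pair_hd(match_h_all, match_d_all, X, eps))
  }
  c(MetFrag = s_metfrag, MetFragHD = s_hd, PairHD = as.numeric(s_pair),
    OSN = score_osn(X, dv$eH), eH = dv$eH, n_variants = length(dv$variants))
}

#' Rank candidate structures against a normal/deuterated spectrum pair
#'
#' The full pipeline: filter the candidate list (salts, non-standard isotopes),
#' collapse duplicates on the InChIKey connectivity block, infer the exchanged
#' hydrogen count X from the precursor pair, deuterate and fragment every
#' candidate, compute the four scoring terms, and rank by the weighted
#' max-normalized consensus.
#'
#' @param candidates Data frame with columns `id` and `smiles`.
#' @param spec_h Normal [hdx_spectrum()] with precursor m/z and adduct.
#' @param spec_d Deuterated [hdx_spectrum()] with precursor m/z and adduct.
#' @param weights Consensus weights (default [hdx_default_weights()]).
#' @param config Settings from [hdx_config()].
#' @param X Exchanged-hydrogen count; inferred from the precursor pair when
#'   `NULL`.
#' @param cache Optional environment used to reuse fragment sets across calls
#'   (keyed by SMILES).
#' @return Object of class `hdx_rank`: list with `results` (one row per
#'   candidate, sorted by rank: identifiers, `eH`, `n_variants`, the four raw
#'   and normalized scores, `consensus`, `rank`), `X`, `weights`, `config`.
#' @export
#' @examples
#' \donttest{
#' fix <- generate_fixture_pair("OC(=O)c1cc(O)c(O)c(O)c1", seed = 1)
#' cands <- data.frame(id = c("true", "decoy"),
#'                     smiles = c("OC(=O)c1cc(O)c(O)c(O)c1", "COC(=O)c1cc(O)c(O)cc1"))
#' hdx_rank(cands, fix$normal, fix$hdx)
#' }
hdx_rank <- function(candidates, spec_h, spec_d,
                     weights = hdx_default_weights(), config = hdx_config(),
                     X = NULL, cache = NULL) {
  stopifnot(inherits(spec_h, "hdx_spectrum"), inherits(spec_d, "hdx_spectrum"))
  w <- .check_weights(weights)
  flt <- filter_candidates(candidates, cache = cache)
  if (nrow(flt) == 0) stop("no scoreable candidates")

  # duplicate collapse on the InChIKey connectivity block (first occurrence kept)
  fb <- vapply(flt$smiles, function(smi) {
    if (!is.null(cache)) {
      ent <- cache[[smi]]
      if (!is.null(ent$key)) return(ent$key)
    }
    k <- inchikey(smi, first_block = TRUE)
    if (!is.null(cache)) {
      ent <- cache[[smi]] %||% list()
      ent$key <- k
      cache[[smi]] <- ent
    }
    k
  }, "", USE.NAMES = FALSE)
  flt <- flt[!duplicated(fb), , drop = FALSE]

  adduct_h <- spec_h$adduct %||% "M+H"
  adduct_d <- spec_d$adduct %||% "M+D"
  if (is.na(adduct_h)) adduct_h <- if (identical(spec_h$mode, "-")) "M-H" else "M+H"
  if (is.na(adduct_d)) adduct_d <- if (identical(spec_d$mode, "-")) "M-D" else "M+D"
  if (is.null(X)) {
    if (is.na(spec_h$precursor_mz) || is.na(spec_d$precursor_mz))
      stop("X not given and precursor m/z missing; cannot infer exchange count")
    X <- determine_X(neutral_mass(spec_h$precursor_mz, adduct_h),
                     neutral_mass(spec_d$precursor_mz, adduct_d))
  }

  cfg <- config
  if (cfg$exclude_precursor) {
    tol_h <- max(cfg$rel_ppm * (spec_h$precursor_mz %||% 0) / 1e6, cfg$abs_da, na.rm = TRUE)
    spec_h <- .strip_precursor(spec_h, tol_h)
    spec_d <- .strip_precursor(spec_d, tol_h)
  }

  Xv <- as.integer(X)
  raw <- t(vapply(flt$mol, function(m)
    .score_candidate(m, spec_h, spec_d, Xv, cfg, cache), numeric(6)))
  ranked <- consensus_rank(as.data.frame(raw[, 1:4, drop = FALSE]), w)
  res <- cbind(data.frame(id = flt$id, smiles = flt$smiles,
                          eH = as.integer(raw[, "eH"]),
                          n_variants = as.integer(raw[, "n_variants"])),
               ranked)
  res <- res[order(res$rank, res$id), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, X = as.integer(X), weights = w, config = cfg,
                 n_candidates = nrow(res)),
            class = "hdx_rank")
}

#' @export
print.hdx_rank <- function(x, n = 5L, ...) {
  cat(sprintf("HDX candidate ranking: %d candidates, X = %d exchanged hydrogen(s)\n",
              x$n_candidates, x$X))
  cat(sprintf("weights: MetFrag %.3f, MetFragHD %.3f, PairHD %.3f, OSN %.3f\n\n",
              x$weights[1], x$weights[2], x$weights[3], x$weights[4]))
  top <- utils::head(x$results[, c("rank", "id", "eH", "consensus",
                                   "MetFrag_norm", "MetFragHD_norm",
                                   "PairHD_norm", "OSN_norm")], n)
  print(top, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.hdx_rank <- function(object, ...) {
  cat(sprintf("HDX candidate ranking (X = %d)\n", object$X))
  cat(sprintf("  candidates scored: %d\n", object$n_candidates))
  r <- object$results
  cat(sprintf("  consensus range: [%.4f, %.4f]\n", min(r$consensus), max(r$consensus)))
  cat(sprintf("  top candidate: %s (eH = %d, consensus %.4f)\n",
              r$id[1], r$eH[1], r$consensus[1]))
  invisible(object)
}

#' @method plot hdx_rank
#' @export
plot.hdx_rank <- function(x, n = 10L, ...) {
  r <- utils::head(x$results, n)
  m <- t(as.matrix(r[, c("MetFrag_norm", "MetFragHD_norm", "PairHD_norm", "OSN_norm")]) *
           x$weights)
  graphics::barplot(t(m), beside = FALSE, names.arg = r$id, las = 2,
                    col = c("#4477AA", "#66CCEE", "#228833", "#CCBB44"),
                    ylab = "weighted normalized score",
                    main = "consensus score contributions", ...)
  graphics::legend("topright", fill = c("#4477AA", "#66CCEE", "#228833", "#CCBB44"),
                   legend = c("MetFrag", "MetFragHD", "PairHD", "OSN"), bty = "n")
  invisible(x)
}

#' Export ranking results
#'
#' @param x An `hdx_rank` object.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_results <- function(x, path) {
  stopifnot(inherits(x, "hdx_rank"))
  utils::write.csv(x$results, path, row.names = FALSE)
  invisible(path)
}
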