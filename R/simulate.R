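# Seeded synthetic spectrum pairs and formula-matched decoy candidate families.
# The generator emulates the complete-exchange regime: every heteroatom-bound
# hydrogen of the true structure is deuterated in the HDX acquisition, fragment
# peaks appear at in silico fragment masses with small mass error, and random
# decoy peaks model unexplained signal.

#' Generate a synthetic normal/deuterated spectrum pair
#'
#' Fragments the molecule, selects up to `n_fragment_peaks` low-BDE fragments,
#' places their `[M+H]+`-type ions (with log-normal intensities and `mz_ppm`
#' gaussian mass error) in the normal spectrum and the fully exchanged
#' deuterated fragment ions in the HDX spectrum, then appends `n_decoy_peaks`
#' uniform random decoy peaks to each. Byte-identical under a fixed seed.
#'
#' @param mol A `molgraph` or SMILES/InChI string of the true compound.
#' @param mode Ion mode `"+"` or `"-"`.
#' @param n_fragment_peaks Maximum number of fragment peaks (default 12).
#' @param n_decoy_peaks Random unexplained peaks per spectrum (default 5).
#' @param mz_ppm Gaussian mass-error s.d. in ppm (default 1).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model
#'   (defaults log(1000) and 1).
#' @param max_depth Fragmentation depth used (default 2).
#' @param seed Integer seed.
#' @return List of class `hdx_fixture`: `normal` and `hdx` spectra
#'   ([hdx_spectrum()]), and `truth` (true SMILES, `X`, fragment record).
#' @export
generate_fixture_pair <- function(mol, mode = c("+", "-"),
                                  n_fragment_peaks = 12L, n_decoy_peaks = 5L,
                                  mz_ppm = 1, intensity_meanlog = log(1000),
                                  intensity_sdlog = 1, max_depth = 2L,
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (is.character(mol)) mol <- parse_structure(mol)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  add_h <- if (mode == "+") "M+H" else "M-H"
  add_d <- if (mode == "+") "M+D" else "M-D"
  X <- count_exchangeable_hydrogens(mol)
  m0 <- structure_mass(mol)
  prec_h <- ion_mz(m0, add_h)
  prec_d <- ion_mz(m0 + X * .delta_hd, add_d)

  fs <- generate_fragments(mol, max_depth = max_depth)
  fr <- fs$frags
  sel <- which(fr$depth > 0 & fr$mass >= 40 &
                 abs(fr$mass - m0) > 2)        # true sub-fragments only
  sel <- sel[!duplicated(round(fr$mass[sel], 4))]
  sel <- sel[order(fr$bde[sel])]
  sel <- utils::head(sel, n_fragment_peaks)
  if (!length(sel)) stop("molecule yields no usable fragments")

  jitter <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, mz_ppm * 1e-6))
  inten <- function(n) stats::rlnorm(n, intensity_meanlog, intensity_sdlog)

  mz_h <- jitter(ion_mz(fr$mass[sel], add_h))
  mz_d <- jitter(ion_mz(fr$mass[sel] + fr$eH_sites[sel] * .delta_hd, add_d))
  int_shared <- inten(length(sel))

  decoys <- function(prec) {
    if (n_decoy_peaks == 0) return(list(mz = numeric(), int = numeric()))
    list(mz = stats::runif(n_decoy_peaks, 50, max(prec - 5, 55)),
         int = inten(n_decoy_peaks) * 0.2)
  }
  dh <- decoys(prec_h); dd <- decoys(prec_d)

  normal <- hdx_spectrum(c(mz_h, dh$mz), c(int_shared, dh$int),
                         precursor_mz = prec_h, adduct = add_h, mode = mode,
                         label = "normal")
  hdx <- hdx_spectrum(c(mz_d, dd$mz), c(int_shared, dd$int),
                      precursor_mz = prec_d, adduct = add_d, mode = mode,
                      label = "deuterated")
  truth <- list(smiles = mol$smiles, id = mol$id, X = X,
                fragments = data.frame(mass = fr$mass[sel],
                                       eH = fr$eH_sites[sel],
                                       bde = fr$bde[sel]))
  structure(list(normal = normal, hdx = hdx, truth = truth),
            class = "hdx_fixture")
}

#' @export
print.hdx_fixture <- function(x, ...) {
  cat(sprintf("<hdx_fixture: %s, X = %d, %d/%d peaks (normal/HDX)>\n",
              x$truth$smiles, x$truth$X, length(x$normal$mz), length(x$hdx$mz)))
  invisible(x)
}

.family_cache <- new.env(parent = emptyenv())

# ring substituents: SMILES branch and elemental contribution + eH
.substituents <- data.frame(
  name = c("OH", "OCH3", "OC2H5", "CH3", "C2H5", "CH2OH", "CHOHCH3", "CH2OCH3",
           "CH2CH2OH", "NH2", "NHCH3", "NCH32", "CH2NH2", "CHO", "COOH",
           "COOCH3", "COCH3", "OC3H7", "OCHC2", "CH2OC2H5", "C3H6OH",
           "CHOHC2H5", "NHC2H5"),
  smi = c("O", "OC", "OCC", "C", "CC", "CO", "C(O)C", "COC",
          "CCO", "N", "NC", "N(C)C", "CN", "C=O", "C(=O)O",
          "C(=O)OC", "C(C)=O", "OCCC", "OC(C)C", "COCC", "CCCO",
          "C(O)CC", "NCC"),
  C = c(0, 1, 2, 1, 2, 1, 2, 2, 2, 0, 1, 2, 1, 1, 1, 2, 2, 3, 3, 3, 3, 3, 2),
  H = c(1, 3, 5, 3, 5, 3, 5, 5, 5, 2, 4, 6, 4, 1, 1, 3, 3, 7, 7, 7, 7, 7, 6),
  O = c(1, 1, 1, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0, 1, 2, 2, 1, 1, 1, 1, 1, 1, 0),
  N = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1),
  eH = c(1, 0, 0, 0, 0, 1, 1, 0, 1, 2, 1, 0, 2, 0, 1, 0, 0, 0, 0, 0, 1, 1, 1)
)

.ring_patterns <- list(
  `2` = list(c(1, 2), c(1, 3), c(1, 4)),
  `3` = list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 5))
)

.build_benzene_smiles <- function(subs, positions) {
  branch <- character(6)
  branch[positions] <- paste0("(", subs, ")")
  paste0("c1", branch[1],
         paste0("c", branch[2:6], collapse = ""), "1")
}

#' Formula-matched isomer candidate family
#'
#' Enumerates substituted benzenes (two or three substituents drawn from a
#' fixed hydroxyl/ether/amine/carbonyl vocabulary, at the distinct ring
#' substitution patterns) whose molecular formula equals `formula`, and
#' collapses duplicates on the InChIKey connectivity block. Members share one
#' formula (hence one precursor m/z) but differ in structure and in
#' exchangeable-hydrogen count, which makes them decoy sets for ranking
#' experiments.
#'
#' @param formula Target neutral formula string, e.g. `"C8H10O2"`.
#' @return Data frame with `id`, `smiles`, `eH`.
#' @export
#' @examples
#' fam <- candidate_family("C8H10O2")
#' table(fam$eH)
candidate_family <- function(formula) {
  if (!is.null(.family_cache[[formula]])) return(.family_cache[[formula]])
  f <- parse_formula(formula)
  want <- function(counts_sub, nsub) {
    ring <- c(C = 6, H = 6 - nsub, O = 0, N = 0)
    tot <- ring + counts_sub
    tgt <- c(C = 0, H = 0, O = 0, N = 0)
    tgt[names(f$counts)] <- f$counts
    all(tot == tgt[names(tot)])
  }
  s <- .substituents
  rows <- list()
  add <- function(subs_idx) {
    nsub <- length(subs_idx)
    csum <- c(C = sum(s$C[subs_idx]), H = sum(s$H[subs_idx]),
              O = sum(s$O[subs_idx]), N = sum(s$N[subs_idx]))
    if (!want(csum, nsub)) return()
    for (pos in .ring_patterns[[as.character(nsub)]]) {
      for (perm in unique(.permutations(subs_idx))) {
        smi <- .build_benzene_smiles(s$smi[perm], pos)
        rows[[length(rows) + 1L]] <<- data.frame(
          smiles = smi, eH = sum(s$eH[subs_idx]))
      }
    }
  }
  n <- nrow(s)
  for (i in seq_len(n)) for (j in i:n) add(c(i, j))
  for (i in seq_len(n)) for (j in i:n) for (k in j:n) add(c(i, j, k))
  if (!length(rows)) stop("no family members for formula ", formula)
  df <- unique(do.call(rbind, rows))
  key <- inchikey(df$smiles, first_block = TRUE)
  df <- df[!duplicated(key), , drop = FALSE]
  # verify the formula from the parsed structure (drops accidental mismatches)
  ok <- vapply(df$smiles, function(sm) {
    fm <- molecular_formula(parse_structure(sm))
    identical(format(fm), format(f))
  }, TRUE)
  df <- df[ok, , drop = FALSE]
  df$id <- sprintf("%s_%02d", formula, seq_len(nrow(df)))
  rownames(df) <- NULL
  df <- df[c("id", "smiles", "eH")]
  .family_cache[[formula]] <- df
  df
}

.permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  unique(out)
}

#' Fixture benchmark: spectrum pairs with formula-matched decoys
#'
#' Builds `n_pairs` synthetic spectrum pairs. For each pair a true compound is
#' drawn (seeded) from one of the isomer families, its spectrum pair is
#' simulated with [generate_fixture_pair()], and the whole family (true
#' compound plus its formula-matched decoys) forms the candidate list.
#'
#' @param n_pairs Number of spectrum pairs (default 50).
#' @param formulas Family formulas (defaults give families of >= 21 members
#'   with varying eH).
#' @param seed Integer seed.
#' @param ... Passed to [generate_fixture_pair()].
#' @return List of entries: `fixture`, `candidates` (data frame), `true_id`.
#' @export
fixture_benchmark <- function(n_pairs = 50L,
                              formulas = c("C8H10O2", "C8H11NO", "C9H12O2"),
                              seed = 1L, ...) {
  fams <- lapply(formulas, candidate_family)
  names(fams) <- formulas
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    fam <- fams[[((i - 1L) %% length(fams)) + 1L]]
    eligible <- which(fam$eH >= 1)       # X >= 1 so the HDX run is informative
    ti <- sample(eligible, 1)
    mol <- parse_structure(fam$smiles[ti], id = fam$id[ti])
    fix <- generate_fixture_pair(mol, seed = seed + 1000L + i, ...)
    out[[i]] <- list(fixture = fix, candidates = fam[c("id", "smiles")],
                     true_id = fam$id[ti])
  }
  out
}
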