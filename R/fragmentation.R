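# Combinatorial bond disconnection. A cleavage event removes one acyclic bond
# or a pair of ring bonds (one ring opening); events recurse to a configured
# depth and every fragment accumulates the dissociation energies of the bonds
# it cost to make.

# homolytic bond dissociation energies (kJ/mol-scale units) by element pair and
# order; aromatic bonds are 1.5x the single-bond entry; missing pairs fall back
# to .bde_default. Exact values only shift a penalty that is max-normalized
# downstream.
.bde_default <- 348
.bde_table <- local({
  single <- c("C C" = 346, "C N" = 305, "C O" = 358, "C S" = 272, "N N" = 167,
              "N O" = 201, "O O" = 146, "O S" = 265, "S S" = 266, "C F" = 485,
              "C Cl" = 327, "C Br" = 285, "C I" = 213, "C P" = 264, "N S" = 247,
              "O P" = 335, "C Si" = 318)
  dbl <- c("C C" = 602, "C N" = 615, "C O" = 749, "C S" = 573, "N N" = 418,
           "N O" = 607, "O S" = 522, "O P" = 544)
  trp <- c("C C" = 835, "C N" = 887, "N N" = 942)
  list(`1` = single, `2` = dbl, `3` = trp)
})

.bond_bde <- function(el1, el2, order, aromatic) {
  key <- paste(pmin(el1, el2), pmax(el1, el2))
  out <- numeric(length(key))
  for (i in seq_along(key)) {
    if (aromatic[i]) {
      v <- .bde_table[["1"]][key[i]]
      out[i] <- 1.5 * if (is.na(v)) .bde_default else v
    } else {
      tab <- .bde_table[[as.character(min(order[i], 3L))]]
      v <- if (is.null(tab)) NA_real_ else tab[key[i]]
      out[i] <- if (is.na(v)) .bde_default * min(order[i], 3L) else v
    }
  }
  unname(out)
}

#' Bond dissociation energy table
#'
#' The built-in per-bond cleavage penalties, by element pair and bond order.
#'
#' @return List of named numeric vectors (`"1"`, `"2"`, `"3"` = bond order) with
#'   attribute `default` for missing pairs; aromatic bonds use 1.5x the single
#'   bond value.
#' @export
bde_table <- function() structure(.bde_table, default = .bde_default)

# components of the subgraph induced by `at` (global atom ids) after keeping
# only the bonds in la1/la2 (local indices into `at`); returns list of global
# atom-id vectors
.sub_split <- function(at, la1, la2) {
  comp <- .components(length(at), la1, la2)
  lapply(seq_len(max(comp)), function(ci) at[comp == ci])
}

#' Generate fragments by combinatorial bond disconnection
#'
#' Starting from the intact molecule, every acyclic bond cleavage and every
#' disconnecting pair of ring-bond cleavages produces child fragments,
#' recursively up to `max_depth` events. Duplicated atom subsets keep the
#' minimal cumulative bond dissociation energy, so the output is independent of
#' cleavage order.
#'
#' @param mol A connected `molgraph`.
#' @param max_depth Maximum number of cleavage events (default 2); 0 returns
#'   only the intact molecule.
#' @return Object of class `fragment_set`: list with the parent `mol` and
#'   `frags`, a data frame with list-column `atoms` (parent atom indices) and
#'   columns `bde`, `depth`, `mass` (neutral, labels included), `nH`, `nD`,
#'   `eH_sites` (retained exchangeable-H count), `vH_cap` (retained
#'   non-exchangeable-H count).
#' @export
#' @examples
#' frags <- generate_fragments(parse_structure("CCO"), max_depth = 1)
#' nrow(frags$frags)  # intact + 4 single-cleavage fragments
generate_fragments <- function(mol, max_depth = 2L) {
  stopifnot(inherits(mol, "molgraph"))
  if (nrow(mol$atoms) == 0) stop("empty molecule")
  if (mol$n_components != 1) stop("molecule must be connected")
  max_depth <- as.integer(max_depth)
  stopifnot(max_depth >= 0)

  n <- nrow(mol$atoms)
  ba1 <- mol$bonds$a1; ba2 <- mol$bonds$a2; bbde <- mol$bonds$bde

  best <- new.env(parent = emptyenv())  # key -> list(atoms, bde, depth)
  keyof <- function(at) paste(at, collapse = ",")
  put <- function(at, bde, depth) {
    k <- keyof(at)
    cur <- best[[k]]
    if (is.null(cur) || bde < cur$bde) {
      best[[k]] <- list(atoms = at, bde = bde, depth = if (is.null(cur)) depth else min(depth, cur$depth))
      TRUE
    } else FALSE
  }
  put(seq_len(n), 0, 0L)

  level <- list(list(atoms = seq_len(n), bde = 0))
  depth <- 0L
  while (depth < max_depth && length(level)) {
    depth <- depth + 1L
    nxt <- new.env(parent = emptyenv())
    for (fr in level) {
      at <- fr$atoms
      if (length(at) < 2) next
      member <- logical(n); member[at] <- TRUE
      bsel <- which(member[ba1] & member[ba2])
      if (!length(bsel)) next
      la1 <- match(ba1[bsel], at); la2 <- match(ba2[bsel], at)
      m <- length(bsel)
      split_counts <- integer(m)
      pieces <- vector("list", m)
      for (k in seq_len(m)) {
        cc <- .sub_split(at, la1[-k], la2[-k])
        split_counts[k] <- length(cc)
        pieces[[k]] <- cc
      }
      emit <- function(cc, add_bde) {
        for (piece in cc) {
          b <- fr$bde + add_bde
          kk <- keyof(piece)
          cur <- nxt[[kk]]
          if (is.null(cur) || b < cur$bde)
            nxt[[kk]] <- list(atoms = piece, bde = b)
        }
      }
      bridges <- which(split_counts > 1L)
      for (k in bridges) emit(pieces[[k]], bbde[bsel[k]])
      ringb <- setdiff(seq_len(m), bridges)
      if (length(ringb) >= 2) {
        for (ii in seq_len(length(ringb) - 1L)) {
          for (jj in seq((ii + 1L), length(ringb))) {
            i <- ringb[ii]; j <- ringb[jj]
            cc <- .sub_split(at, la1[-c(i, j)], la2[-c(i, j)])
            if (length(cc) > 1L) emit(cc, bbde[bsel[i]] + bbde[bsel[j]])
          }
        }
      }
    }
    level <- list()
    for (kk in ls(nxt)) {
      fr <- nxt[[kk]]
      if (put(fr$atoms, fr$bde, depth)) level <- c(level, list(fr))
      else level <- c(level, list(fr))  # expand regardless; dedup keeps min bde
    }
  }

  keys <- ls(best)
  frs <- lapply(keys, function(k) best[[k]])
  atoms_l <- lapply(frs, `[[`, "atoms")
  bde <- vapply(frs, `[[`, 0, "bde")
  dpt <- vapply(frs, function(f) as.integer(f$depth), 0L)
  am <- mol$atoms
  el_mass <- .hdx_masses[am$element]
  nH <- vapply(atoms_l, function(a) sum(am$nH[a]), 0L)
  nD <- vapply(atoms_l, function(a) sum(am$nD[a]), 0L)
  eHs <- vapply(atoms_l, function(a) sum(am$nH[a][am$exchangeable[a]]), 0L)
  mass <- vapply(atoms_l, function(a) sum(el_mass[a]), 0) +
    nH * .hdx_masses[["H"]] + nD * .hdx_masses[["D"]]
  frags <- data.frame(bde = bde, depth = dpt, mass = mass, nH = nH, nD = nD,
                      eH_sites = eHs, vH_cap = nH - eHs)
  frags$atoms <- atoms_l
  ord <- order(frags$depth, frags$bde)
  frags <- frags[ord, , drop = FALSE]
  rownames(frags) <- NULL
  structure(list(mol = mol, frags = frags, max_depth = max_depth),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set: %d fragments of %s at depth <= %d>\n",
              nrow(x$frags), format(molecular_formula(x$mol)), x$max_depth))
  invisible(x)
}

#' Formula of one fragment
#'
#' @param fs A `fragment_set`.
#' @param i Fragment row index.
#' @param extra_d Additional deuterium count to fold in (exchanged hydrogens).
#' @param charge Formal charge for rendering.
#' @return A `mol_formula`.
#' @export
fragment_formula <- function(fs, i, extra_d = 0L, charge = 0L) {
  at <- fs$frags$atoms[[i]]
  el <- table(fs$mol$atoms$element[at])
  counts <- stats::setNames(as.integer(el), names(el))
  h <- fs$frags$nH[i] - extra_d
  d <- fs$frags$nD[i] + extra_d
  if (h < 0) stop("extra_d exceeds fragment hydrogen count")
  if (h > 0) counts["H"] <- h
  if (d > 0) counts["D"] <- d
  mol_formula(counts, charge = charge)
}

# (sH, sD) dynamic hydrogen/deuterium shifts: every integer combination with
# |sH| + |sD| <= max_shift. Mixed signs (e.g. +1H/-1D) express gas-phase
# H/D scrambling: a deuterium swapped back for a hydrogen.
.dynamic_shifts <- function(max_shift, allow_d) {
  dr <- if (allow_d) (-max_shift):max_shift else 0L
  g <- expand.grid(h = (-max_shift):max_shift, d = dr)
  m <- as.matrix(g[abs(g$h) + abs(g$d) <= max_shift, , drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' m/z hypotheses for fragments
#'
#' For the normal spectrum each fragment is hypothesized at its ionized mass
#' shifted by 0, +-1, or +-2 hydrogens. For the deuterated spectrum the
#' fragment mass first gains `eH(Frag) * (m(D) - m(H))` for its retained
#' exchanged hydrogens, then optionally `k * (m(D) - m(H))` for
#' `1 <= k <= vH` position-unknown exchanges, and each such mass is again
#' shifted by up to `max_hshift` hydrogens or deuteriums; ionization uses the
#' proton for normal and the deuteron for deuterated spectra.
#'
#' @param fs A `fragment_set`.
#' @param mode Ion mode, `"+"` or `"-"`.
#' @param deuterated If `TRUE`, build hypotheses for the deuterated spectrum.
#' @param variant A single variant from [deuterate_candidate()] (required when
#'   `deuterated = TRUE`; `NULL` means the fully exchanged species).
#' @param X Observed exchange count; caps the total deuterium load of
#'   position-ambiguous variants.
#' @param max_hshift Maximum dynamic +-H/+-D shift (default 2).
#' @return Data frame: `frag` (row in `fs$frags`), `mz`, `bde`, `h_shift`,
#'   `d_shift`, `k` (position-unknown exchanges used), `nD_exch`
#'   (exchange-derived deuteriums on the fragment = eH(dFrag) + vH(dFrag)),
#'   and `nD_ion` (total deuterium on the hypothesized ion: exchange-derived
#'   plus dynamic +-D shifts plus the ionizing deuteron (+1 for `[M+D]+`, -1
#'   for `[M-D]-`); this is the k of the fragment-pair mass relation on raw
#'   peak m/z values).
#' @export
fragment_mz_hypotheses <- function(fs, mode = c("+", "-"), deuterated = FALSE,
                                   variant = NULL, X = 0L, max_hshift = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(fs, "fragment_set"))
  fr <- fs$frags
  nf <- nrow(fr)
  adduct <- if (deuterated) (if (mode == "+") "M+D" else "M-D")
            else (if (mode == "+") "M+H" else "M-H")
  amass <- unname(.adducts[[adduct]]["mass"])
  mH <- .hdx_masses[["H"]]; mD <- .hdx_masses[["D"]]

  if (!deuterated) {
    sh <- .dynamic_shifts(max_hshift, allow_d = FALSE)
    ns <- nrow(sh)
    out <- data.frame(
      frag = rep(seq_len(nf), ns),
      mz = rep(fr$mass + amass, ns) + rep(sh[, 1], each = nf) * mH,
      bde = rep(fr$bde, ns),
      h_shift = rep(sh[, 1], each = nf), d_shift = 0L,
      k = 0L, nD_exch = 0L, nD_ion = 0L)
    return(out[out$mz > 0, , drop = FALSE])
  }

  if (is.null(variant)) {
    nat <- nrow(fs$mol$atoms)
    variant <- list(d_count = {
      d <- integer(nat)
      i <- which(fs$mol$atoms$exchangeable)
      d[i] <- fs$mol$atoms$nH[i]
      d
    }, vH = 0L, ambiguous = FALSE)
  }
  adduct_d <- if (mode == "+") 1L else -1L
  sh <- .dynamic_shifts(max_hshift, allow_d = TRUE)
  ns <- nrow(sh)
  if (variant$ambiguous) {
    eH_v <- integer(nf)
    kmax <- pmin(X, fr$nH)
  } else {
    dpos <- which(variant$d_count > 0L)
    eH_v <- if (length(dpos)) {
      vapply(fr$atoms, function(a) sum(variant$d_count[a[a %in% dpos]]), 0L)
    } else integer(nf)
    kmax <- pmin(variant$vH, fr$vH_cap)
  }
  # rows (frag, k) for 0 <= k <= kmax[frag], crossed with the shift table
  fi <- rep(seq_len(nf), kmax + 1L)
  kv <- unlist(lapply(kmax, function(km) 0:km), use.names = FALSE)
  base <- fr$mass[fi] + (eH_v[fi] + kv) * .delta_hd + amass
  nb <- length(fi)
  out <- data.frame(
    frag = rep(fi, ns),
    mz = rep(base, ns) + rep(sh[, 1], each = nb) * mH + rep(sh[, 2], each = nb) * mD,
    bde = rep(fr$bde[fi], ns),
    h_shift = rep(sh[, 1], each = nb),
    d_shift = rep(sh[, 2], each = nb),
    k = rep(kv, ns),
    nD_exch = rep(eH_v[fi] + kv, ns))
  out$nD_ion <- out$nD_exch + out$d_shift + adduct_d
  out <- out[out$mz > 0 & out$nD_ion >= 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dump fragments as a data frame / CSV
#'
#' One row per fragment with formula, neutral mass, BDE and depth; written for
#' debugging and for the fixture generator.
#'
#' @param fs A `fragment_set`.
#' @param path Optional CSV output path.
#' @return Data frame (invisibly if written).
#' @export
fragment_table <- function(fs, path = NULL) {
  fr <- fs$frags
  df <- data.frame(
    id = if (is.null(fs$mol$id)) NA_character_ else fs$mol$id,
    formula = vapply(seq_len(nrow(fr)), function(i) format(fragment_formula(fs, i)), ""),
    mass = fr$mass, nD = fr$nD, eH = fr$eH_sites, bde = fr$bde, depth = fr$depth)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
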