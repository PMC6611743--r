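# Structure parsing. OpenBabel (via ChemmineOB) handles SMILES/InChI reading,
# explicit-hydrogen expansion and InChIKey generation; the resulting V2000
# molblock is folded into a light heavy-atom graph with per-atom H/D counts,
# which is the substrate of deuteration and fragmentation.

.ob_convert <- function(from, to, text, add_h = FALSE) {
  out <- suppressWarnings(if (add_h) {
    ChemmineOB::convertFormat(from, to, text,
                              options = data.frame(names = "h", args = ""))
  } else {
    ChemmineOB::convertFormat(from, to, text)
  })
  if (!nzchar(trimws(out))) stop("could not parse structure: ", text)
  out
}

.structure_format <- function(text) {
  if (grepl("^InChI=", trimws(text))) "INCHI" else "SMI"
}

#' Parse a SMILES or InChI string into a molecular graph
#'
#' The graph keeps heavy atoms only; hydrogens are folded into per-atom
#' attached-H counts, and `[2H]` isotope labels into per-atom deuterium counts.
#' Bonds carry order, an aromaticity flag, and a homolytic bond dissociation
#' energy used as the cleavage penalty during fragmentation.
#'
#' @param text A SMILES string (isotope labels `[2H]` accepted) or an InChI.
#' @param id Optional provenance identifier stored with the graph.
#' @return An object of class `molgraph` with components `atoms` (data frame:
#'   `element`, `charge`, `nH`, `nD`, `exchangeable`), `bonds` (data frame:
#'   `a1`, `a2`, `order`, `aromatic`, `ring`, `bde`), `n_components`, `smiles`,
#'   and `id`.
#' @export
#' @examples
#' mol <- parse_structure("OC(=O)c1cc(O)c(O)c(O)c1", id = "gallic acid")
#' format(molecular_formula(mol))        # "C7H6O5"
#' count_exchangeable_hydrogens(mol)     # 4
parse_structure <- function(text, id = NULL) {
  text <- trimws(text)
  mb <- .ob_convert(.structure_format(text), "SDF", text, add_h = TRUE)
  mol <- .parse_molblock(mb)
  mol$smiles <- text
  mol$id <- id
  mol
}

.parse_molblock <- function(mb) {
  lines <- strsplit(mb, "\n", fixed = TRUE)[[1]]
  cnt <- lines[4]
  natoms <- as.integer(substr(cnt, 1, 3))
  nbonds <- as.integer(substr(cnt, 4, 6))
  if (is.na(natoms) || natoms < 1) stop("empty or malformed molblock")
  atom_lines <- lines[5:(4 + natoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  bond_lines <- if (nbonds > 0) lines[(5 + natoms):(4 + natoms + nbonds)] else character(0)
  b1 <- as.integer(substr(bond_lines, 1, 3))
  b2 <- as.integer(substr(bond_lines, 4, 6))
  bord <- as.integer(substr(bond_lines, 7, 9))

  iso <- integer(natoms)
  chg <- integer(natoms)
  for (ln in grep("^M  (ISO|CHG)", lines, value = TRUE)) {
    n <- as.integer(substr(ln, 7, 9))
    if (is.na(n) || n < 1) next
    for (i in seq_len(n)) {
      off <- 10 + (i - 1) * 8
      a <- as.integer(substr(ln, off, off + 3))
      v <- as.integer(substr(ln, off + 4, off + 7))
      if (startsWith(ln, "M  ISO")) iso[a] <- v else chg[a] <- v
    }
  }

  is_h <- element == "H"
  # hydrogens with mass number 2 are deuterium labels
  is_d <- is_h & iso == 2L
  heavy <- which(!is_h)
  if (length(heavy) == 0) stop("structure has no heavy atoms")
  if (any(is_h & iso != 0L & iso != 2L))
    warning("hydrogen with unusual mass number retained as plain H")
  heavy_idx <- match(seq_len(natoms), heavy)  # original -> heavy index

  nH <- integer(length(heavy))
  nD <- integer(length(heavy))
  keep_bond <- logical(length(b1))
  for (k in seq_along(b1)) {
    i <- b1[k]; j <- b2[k]
    if (is_h[i] && is_h[j]) next                  # molecular hydrogen: ignored
    if (is_h[i] || is_h[j]) {
      h <- if (is_h[i]) i else j
      a <- heavy_idx[if (is_h[i]) j else i]
      if (is_d[h]) nD[a] <- nD[a] + 1L else nH[a] <- nH[a] + 1L
    } else {
      keep_bond[k] <- TRUE
    }
  }
  bonds <- data.frame(
    a1 = heavy_idx[b1[keep_bond]],
    a2 = heavy_idx[b2[keep_bond]],
    order = bord[keep_bond]
  )
  el <- element[heavy]
  unknown <- setdiff(unique(el), names(.hdx_masses))
  if (length(unknown)) stop("unsupported element(s): ", paste(unknown, collapse = ", "))

  atoms <- data.frame(element = el, charge = chg[heavy], nH = nH, nD = nD)
  atoms$exchangeable <- atoms$element %in% c("O", "N", "S") & atoms$nH > 0L

  arom <- .aromatic_bonds(mb, nrow(atoms), bonds)
  bonds$aromatic <- arom
  bonds$ring <- .ring_bonds(nrow(atoms), bonds)
  bonds$bde <- .bond_bde(el[bonds$a1], el[bonds$a2], bonds$order, bonds$aromatic)

  mol <- structure(list(atoms = atoms, bonds = bonds,
                        n_components = .n_components(nrow(atoms), bonds),
                        smiles = NULL, id = NULL),
                   class = "molgraph")
  mol
}

# aromatic ring perception via ChemmineR on the same molblock
.aromatic_bonds <- function(mb, natoms_heavy, bonds) {
  arom <- logical(nrow(bonds))
  if (nrow(bonds) == 0) return(arom)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(mb, tf)
  sdf <- tryCatch(ChemmineR::read.SDFset(tf), error = function(e) NULL)
  if (is.null(sdf)) return(arom)
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf[[1]], type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (is.null(r) || length(r$RINGS) == 0) return(arom)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  bkey <- key(bonds$a1, bonds$a2)
  for (ri in seq_along(r$RINGS)) {
    if (!isTRUE(r$AROMATIC[[ri]])) next
    at <- as.integer(sub(".*_", "", r$RINGS[[ri]]))
    at <- at[at <= natoms_heavy]  # H atoms never in rings, but be safe
    if (length(at) < 3) next
    pairs <- key(at, c(at[-1], at[1]))
    arom[bkey %in% pairs] <- TRUE
  }
  arom
}

.adjacency <- function(natoms, a1, a2) {
  adj <- vector("list", natoms)
  for (k in seq_along(a1)) {
    adj[[a1[k]]] <- c(adj[[a1[k]]], a2[k])
    adj[[a2[k]]] <- c(adj[[a2[k]]], a1[k])
  }
  adj
}

# connected components by BFS; returns component id per atom
.components <- function(natoms, a1, a2) {
  adj <- .adjacency(natoms, a1, a2)
  comp <- integer(natoms)
  cid <- 0L
  for (s in seq_len(natoms)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

.n_components <- function(natoms, bonds) {
  max(.components(natoms, bonds$a1, bonds$a2))
}

# a bond is a ring bond iff removing it leaves the graph connected
.ring_bonds <- function(natoms, bonds) {
  n <- nrow(bonds)
  out <- logical(n)
  if (n == 0) return(out)
  base <- max(.components(natoms, bonds$a1, bonds$a2))
  for (k in seq_len(n)) {
    out[k] <- max(.components(natoms, bonds$a1[-k], bonds$a2[-k])) == base
  }
  out
}

#' Molecular formula of a graph
#'
#' @param mol A `molgraph`.
#' @return A [mol_formula()] with H and D counted separately.
#' @export
molecular_formula <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  el <- table(mol$atoms$element)
  counts <- stats::setNames(as.integer(el), names(el))
  h <- sum(mol$atoms$nH); d <- sum(mol$atoms$nD)
  if (h > 0) counts["H"] <- h
  if (d > 0) counts["D"] <- d
  mol_formula(counts, charge = sum(mol$atoms$charge))
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph %s: %d heavy atoms, %d bonds, formula %s, eH = %d>\n",
              if (is.null(x$id)) "" else x$id,
              nrow(x$atoms), nrow(x$bonds),
              format(molecular_formula(x)),
              count_exchangeable_hydrogens(x)))
  invisible(x)
}

#' Count easily exchangeable hydrogens
#'
#' Hydrogens attached to oxygen, nitrogen, or sulfur (hydroxyl/carboxyl, amino,
#' thiol, ...) exchange on the LC timescale in deuterated mobile phase. The
#' count is purely topological; deuteriums already present do not count.
#'
#' @param mol A `molgraph`.
#' @return Non-negative integer eH.
#' @export
count_exchangeable_hydrogens <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  sum(mol$atoms$nH[mol$atoms$element %in% c("O", "N", "S")])
}

#' Neutral monoisotopic mass of a graph
#' @param mol A `molgraph`.
#' @return Mass in Da.
#' @export
structure_mass <- function(mol) monoisotopic_mass(molecular_formula(mol))

# --- SMILES writing (deuterated output) -------------------------------------

.write_molblock <- function(mol) {
  atoms <- mol$atoms
  # explicit D atoms appended so isotope labels survive the round trip
  nheavy <- nrow(atoms)
  d_at <- rep(seq_len(nheavy), atoms$nD)
  natoms <- nheavy + length(d_at)
  lines <- c("", " hdxrank", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     natoms, nrow(mol$bonds) + length(d_at)))
  at_line <- function(el) sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", el)
  lines <- c(lines, vapply(atoms$element, at_line, ""), vapply(rep("H", length(d_at)), at_line, ""))
  bl <- sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  dl <- sprintf("%3d%3d  1  0  0  0  0", d_at, nheavy + seq_along(d_at))
  lines <- c(lines, bl, dl)
  if (length(d_at)) {
    di <- nheavy + seq_along(d_at)
    for (chunk in split(di, ceiling(seq_along(di) / 8))) {
      lines <- c(lines, paste0("M  ISO", sprintf("%3d", length(chunk)),
                               paste0(sprintf("%4d%4d", chunk, 2L), collapse = "")))
    }
  }
  chi <- which(atoms$charge != 0)
  if (length(chi)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chi)),
                             paste0(sprintf("%4d%4d", chi, atoms$charge[chi]), collapse = "")))
  }
  paste(c(lines, "M  END", "$$$$"), collapse = "\n")
}

#' Write a graph as SMILES
#'
#' Deuterium labels are emitted as `[2H]` atoms.
#'
#' @param mol A `molgraph`.
#' @return A SMILES string.
#' @export
write_smiles <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  smi <- .ob_convert("SDF", "CAN", .write_molblock(mol))
  trimws(strsplit(smi, "\t|\n")[[1]][1])
}

#' InChIKey of a structure
#'
#' @param text SMILES or InChI string.
#' @param first_block If `TRUE`, return only the 14-character connectivity
#'   block used for duplicate collapsing.
#' @return Character key.
#' @export
inchikey <- function(text, first_block = FALSE) {
  vapply(text, function(t) {
    k <- trimws(.ob_convert(.structure_format(t), "INCHIKEY", t))
    k <- strsplit(k, "\\s+")[[1]][1]
    if (first_block) substr(k, 1, 14) else k
  }, "", USE.NAMES = FALSE)
}

#' Read a candidate list
#'
#' Candidates come as a CSV with columns `Identifier` and `SMILES` (case
#' insensitive; optional `InChIKey`), or as an SDF V2000 file.
#'
#' @param path File path (`.csv` or `.sdf`).
#' @return Data frame with columns `id` and `smiles`.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop("candidate file not found: ", path)
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    ids <- vapply(ChemmineR::SDFset2SDF(sdf), function(x) ChemmineR::header(x)[["Molecule_Name"]], "")
    return(data.frame(id = ids, smiles = unname(smi)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  idc <- which(nm %in% c("identifier", "id"))[1]
  smc <- which(nm == "smiles")[1]
  if (is.na(idc) || is.na(smc))
    stop("candidate CSV needs Identifier and SMILES columns: ", path)
  data.frame(id = as.character(df[[idc]]), smiles = df[[smc]])
}
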