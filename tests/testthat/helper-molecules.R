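# Shared structures and independent oracles. Parsed molecules are cached per
# session because OpenBabel round trips dominate test runtime.

.test_mols <- new.env(parent = emptyenv())

mol_of <- function(smiles, id = NULL) {
  if (is.null(.test_mols[[smiles]]))
    .test_mols[[smiles]] <- parse_structure(smiles, id = id)
  .test_mols[[smiles]]
}

SMI <- list(
  gallic      = "OC(=O)c1cc(O)c(O)c(O)c1",       # C7H6O5, eH = 4
  mus         = "Cc1cc(=O)oc2cc(OS(=O)(=O)O)ccc12",  # 4-methylumbelliferyl sulfate
  benzene     = "c1ccccc1",
  ethanol     = "CCO",
  cysteine    = "NC(CS)C(=O)O",
  ipda        = "CC1(C)CC(N)CC(C)(CN)C1",        # isophorone diamine C10H22N2
  metolachlor = "CCc1cccc(C)c1N(C(C)COC)C(=O)CCl",
  metformin   = "CN(C)C(=N)NC(=N)N"
)

DELTA_HD <- hdx_mass_shift()

# exhaustive oracle: all connected induced heavy-atom subsets of a molecule,
# found by breadth-first growth over the power set -- independent of the
# fragmenter's cleavage-event recursion
oracle_connected_subsets <- function(mol) {
  n <- nrow(mol$atoms)
  stopifnot(n <= 14)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  is_conn <- function(at) {
    seen <- at[1]
    front <- at[1]
    while (length(front)) {
      nxt <- setdiff(intersect(unlist(adj[front]), at), seen)
      seen <- c(seen, nxt)
      front <- nxt
    }
    length(seen) == length(at)
  }
  keys <- character(0)
  for (m in seq_len(2^n - 1)) {
    at <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (is_conn(at)) keys <- c(keys, paste(at, collapse = ","))
  }
  sort(keys)
}

frag_keys <- function(fs) {
  sort(vapply(fs$frags$atoms, paste, "", collapse = ","))
}
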