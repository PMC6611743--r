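# Combinatorial bond disconnection and H/D-aware m/z hypotheses.

test_that("ethanol at depth 1 yields the four single-cleavage fragments", {
  fs <- generate_fragments(mol_of(SMI$ethanol), max_depth = 1)
  # atoms: 1 = CH3, 2 = CH2, 3 = OH
  expect_setequal(frag_keys(fs), c("1,2,3", "1", "2,3", "1,2", "3"))
  fr <- fs$frags
  expect_equal(fr$bde[fr$depth == 0], 0)
  ch3 <- which(vapply(fr$atoms, identical, TRUE, y = 1L))
  expect_equal(fr$bde[ch3], 346)  # one C-C cleavage
  oh <- which(vapply(fr$atoms, identical, TRUE, y = 3L))
  expect_equal(fr$bde[oh], 358)   # one C-O cleavage
  expect_equal(fr$eH_sites[oh], 1L)
})

test_that("benzene at depth 1 opens the ring via bond pairs", {
  fs <- generate_fragments(mol_of(SMI$benzene), max_depth = 1)
  sizes <- sort(vapply(fs$frags$atoms, length, 0L))
  # 15 ring-bond pairs each give two arcs; distinct subsets are the 30 proper
  # arcs (lengths 1..5 at six positions) plus the intact ring
  expect_equal(nrow(fs$frags), 31L)
  expect_equal(sizes, c(rep(1:5, each = 6), 6L))
  # every ring opening cleaves two aromatic bonds: BDE = 2 * 1.5 * 346
  expect_true(all(fs$frags$bde[fs$frags$depth == 1] == 2 * 1.5 * 346))
})

test_that("depth 0 returns only the intact molecule", {
  fs <- generate_fragments(mol_of(SMI$mus), max_depth = 0)
  expect_equal(nrow(fs$frags), 1L)
  expect_equal(fs$frags$atoms[[1]], seq_len(nrow(fs$mol$atoms)))
  expect_error(generate_fragments(parse_structure("CC.O"), 1), "connected")
})

test_that("deep fragmentation equals the exhaustive connected-subset oracle", {
  mols <- c(SMI$ethanol, SMI$benzene, SMI$cysteine, SMI$gallic, SMI$metformin,
            "CCOC(=O)C", "c1ccncc1", "OCC1OC(O)C(O)C1O", "CC(C)CC(N)C(=O)O",
            "Clc1ccc(O)cc1")
  expect_length(mols, 10L)
  for (s in mols) {
    mol <- mol_of(s)
    expect_lte(nrow(mol$atoms), 12L)
    fs <- generate_fragments(mol, max_depth = nrow(mol$bonds))
    expect_setequal(frag_keys(fs), oracle_connected_subsets(mol))
  }
})

test_that("cumulative BDE grows along the fragmentation tree", {
  fs <- generate_fragments(mol_of("CCCO"), max_depth = 2)
  fr <- fs$frags
  # middle carbon alone requires both C-C and C-O context: two cleavages
  mid <- which(vapply(fr$atoms, identical, TRUE, y = 2L))
  expect_equal(fr$depth[mid], 2L)
  expect_equal(fr$bde[mid], 346 + 346)
  # each event adds a full bond energy: depth-d fragments cost at least d
  # times the cheapest bond
  cheapest <- min(fs$mol$bonds$bde)
  expect_true(all(fr$bde >= fr$depth * cheapest))
  expect_true(all(fr$bde[fr$depth == 1] %in% fs$mol$bonds$bde))
})

test_that("duplicate subsets keep the minimal BDE regardless of route", {
  # in gallic acid the lone ring carbons are reachable through several
  # cleavage orders; dedup must keep one entry per subset
  fs <- generate_fragments(mol_of(SMI$gallic), max_depth = 3)
  keys <- vapply(fs$frags$atoms, paste, "", collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("normal-mode hypotheses are the ionized mass with 0/1/2 H shifts", {
  fs <- generate_fragments(mol_of(SMI$ethanol), max_depth = 1)
  hyp <- fragment_mz_hypotheses(fs, mode = "+", deuterated = FALSE)
  expect_setequal(unique(hyp$h_shift), -2:2)
  base <- hyp[hyp$frag == 1 & hyp$h_shift == 0, "mz"]
  expect_equal(base, ion_mz(fs$frags$mass[1], "M+H"))
  expect_true(all(hyp$nD_ion == 0L))
})

test_that("deuterated hypotheses shift by exchanged and variable deuteriums", {
  # metolachlor has eH = 0; in a mobile-deuterium experiment with X = 6 all
  # deuteriums are position-unknown, and the C4H9O side-chain fragment can be
  # observed fully exchanged as C4H3D6O+
  mol <- mol_of(SMI$metolachlor)
  fs <- generate_fragments(mol, max_depth = 2)
  i <- which(vapply(seq_len(nrow(fs$frags)), function(i)
    format(fragment_formula(fs, i)) == "C4H9O", TRUE))
  expect_gte(length(i), 1L)
  dv <- deuterate_candidate(mol, 6L)
  expect_equal(dv$variants[[1]]$vH, 6L)
  hyp <- fragment_mz_hypotheses(fs, mode = "+", deuterated = TRUE,
                                variant = dv$variants[[1]], X = 6L)
  # the observed bare cation C4H3D6O+ is the deuteronated base minus one D
  h <- hyp[hyp$frag == i[1] & hyp$k == 6 & hyp$h_shift == 0 & hyp$d_shift == -1, ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$mz, monoisotopic_mass("C4H3D6O+"), tolerance = 1e-4)
  expect_equal(h$nD_exch, 6L)
  expect_equal(h$nD_ion, 6L)
  # six exchanges over the normal C4H9O+ ion at m/z 73.0648
  expect_equal(h$mz - monoisotopic_mass("C4H9O+"), 6 * DELTA_HD,
               tolerance = 1e-4)
})

test_that("a deuterium-free fragment ion can coincide with its normal m/z", {
  # H/D swap hypotheses let a D-ionized fragment shed all deuterium, as for
  # the terminal C10H17+ fragment of isophorone diamine
  mol <- mol_of(SMI$ethanol)
  fs <- generate_fragments(mol, max_depth = 1)
  dv <- deuterate_candidate(mol, 1L)
  hyp_d <- fragment_mz_hypotheses(fs, mode = "+", deuterated = TRUE,
                                  variant = dv$variants[[1]], X = 1L)
  hyp_h <- fragment_mz_hypotheses(fs, mode = "+", deuterated = FALSE)
  # the CH3 fragment retains no exchange site: its D-free ion (deuteron
  # swapped for a proton) sits exactly at the normal-mode m/z
  ch3 <- which(vapply(fs$frags$atoms, identical, TRUE, y = 1L))
  base_h <- hyp_h[hyp_h$frag == ch3 & hyp_h$h_shift == 0, "mz"]
  same <- hyp_d[hyp_d$frag == ch3 & hyp_d$nD_ion == 0 &
                  abs(hyp_d$mz - base_h) < 1e-9, ]
  expect_gte(nrow(same), 1L)
})

test_that("deuterated-vs-normal mass differences decompose into shifts", {
  mol <- mol_of(SMI$cysteine)
  fs <- generate_fragments(mol, max_depth = 2)
  dv <- deuterate_candidate(mol, 4L)
  hyp_d <- fragment_mz_hypotheses(fs, mode = "+", deuterated = TRUE,
                                  variant = dv$variants[[1]], X = 4L)
  base_h <- ion_mz(fs$frags$mass, "M+H")
  dmz <- hyp_d$mz - base_h[hyp_d$frag]
  resid <- dmz - hyp_d$nD_ion * DELTA_HD -
    (hyp_d$h_shift + hyp_d$d_shift) * 1.007825
  expect_true(all(abs(resid) < 1e-9))
})

test_that("fragment dump lists formula, deuterium and provenance columns", {
  fs <- generate_fragments(mol_of(SMI$ethanol), max_depth = 1)
  tab <- fragment_table(fs)
  expect_true(all(c("formula", "mass", "nD", "eH", "bde", "depth") %in% names(tab)))
  expect_true("CH3O" %in% tab$formula)  # the CH2OH piece keeps its 3 H
})
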