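# The four scoring terms and the consensus ranking.

make_match <- function(df, n_peaks = nrow(df), max_int = max(df$intensity)) {
  structure(df, n_peaks = n_peaks, max_intensity = max_int,
            class = c("hdx_match", "data.frame"))
}

test_that("the intact molecule explains its own [M+H]+ peak at depth 0", {
  fs <- generate_fragments(mol_of(SMI$gallic), max_depth = 2)
  hyp <- fragment_mz_hypotheses(fs, mode = "+")
  spec <- hdx_spectrum(ion_mz(structure_mass(mol_of(SMI$gallic)), "M+H"), 100)
  m <- match_fragments(hyp, spec)
  expect_equal(nrow(m), 1L)
  expect_equal(m$bde, 0)
  expect_equal(fs$frags$depth[m$frag], 0L)
})

test_that("peaks outside the combined tolerance stay unmatched", {
  hyp <- data.frame(frag = 1L, mz = 80.0, bde = 0, h_shift = 0L,
                    d_shift = 0L, k = 0L, nD_exch = 0L, nD_ion = 0L)
  # at m/z 80 the 5 ppm term (0.0004) is below abs_da = 0.001
  hit <- match_fragments(hyp, hdx_spectrum(80.0009, 1), 5, 0.001)
  miss <- match_fragments(hyp, hdx_spectrum(80.0015, 1), 5, 0.001)
  expect_equal(nrow(hit), 1L)
  expect_equal(nrow(miss), 0L)
})

test_that("a fixture without decoy peaks is fully explained by its truth", {
  fix <- generate_fixture_pair(mol_of(SMI$mus), n_decoy_peaks = 0, seed = 5)
  fs <- generate_fragments(mol_of(SMI$mus), max_depth = 2)
  m <- match_fragments(fragment_mz_hypotheses(fs, "+"), fix$normal)
  expect_equal(nrow(m), length(fix$normal$mz))
  dv <- deuterate_candidate(mol_of(SMI$mus), fix$truth$X)
  md <- match_fragments(
    fragment_mz_hypotheses(fs, "+", deuterated = TRUE,
                           variant = dv$variants[[1]], X = fix$truth$X),
    fix$hdx)
  expect_equal(nrow(md), length(fix$hdx$mz))
})

test_that("the fragmenter score rewards explained intensity and m/z", {
  m0 <- make_match(data.frame(peak = integer(), mz = numeric(),
                              intensity = numeric(), frag = integer(),
                              bde = numeric())[0, ], n_peaks = 3, max_int = 1)
  expect_equal(score_fragmenter(m0), 0)
  m1 <- make_match(data.frame(peak = 1:2, mz = c(100, 150),
                              intensity = c(50, 100), frag = 1:2,
                              bde = c(300, 300)))
  # superset of matched peaks with equal BDE scores strictly higher
  m2 <- make_match(data.frame(peak = 1:3, mz = c(100, 150, 200),
                              intensity = c(50, 100, 10), frag = 1:3,
                              bde = c(300, 300, 300)))
  expect_gt(score_fragmenter(m2), score_fragmenter(m1))
  # relative intensities: doubling everything changes nothing
  m1x2 <- make_match(transform(as.data.frame(m1), intensity = intensity * 2))
  expect_equal(score_fragmenter(m1x2), score_fragmenter(m1))
  # HD variant shares the calculation rule
  expect_equal(score_hd_fragmenter(m1), score_fragmenter(m1))
})

test_that("an undeuterated candidate scores S_D like S_H when spectra agree", {
  mol <- mol_of(SMI$benzene)  # eH = 0
  fs <- generate_fragments(mol, max_depth = 1)
  spec <- hdx_spectrum(c(53.0386, 79.0542), c(10, 100))
  mh <- match_fragments(fragment_mz_hypotheses(fs, "+"), spec)
  dv <- deuterate_candidate(mol, 0L)
  md <- match_fragments(
    fragment_mz_hypotheses(fs, "+", deuterated = TRUE,
                           variant = dv$variants[[1]], X = 0L), spec)
  expect_equal(score_hd_fragmenter(md), score_fragmenter(mh))
})

test_that("isophorone diamine yields at least three fragment pairs", {
  mol <- mol_of(SMI$ipda)
  M <- structure_mass(mol)
  X <- 4L
  # constructed spectra: precursor, NH3/ND3 loss, terminal C10H17+ (no D left)
  nh3 <- monoisotopic_mass("NH3"); nd3 <- nh3 + 3 * DELTA_HD
  sh <- hdx_spectrum(c(ion_mz(M, "M+H"), ion_mz(M, "M+H") - nh3,
                       monoisotopic_mass("C10H17+")),
                     c(100, 80, 60))
  sd <- hdx_spectrum(c(ion_mz(M + X * DELTA_HD, "M+D"),
                       ion_mz(M + X * DELTA_HD, "M+D") - nd3,
                       monoisotopic_mass("C10H17+")),
                     c(100, 80, 60), label = "deuterated")
  fs <- generate_fragments(mol, max_depth = 2)
  dv <- deuterate_candidate(mol, X)
  mh <- match_fragments(fragment_mz_hypotheses(fs, "+"), sh, all = TRUE)
  md <- match_fragments(
    fragment_mz_hypotheses(fs, "+", deuterated = TRUE,
                           variant = dv$variants[[1]], X = X),
    sd, all = TRUE)
  expect_gte(score_pair_hd(mh, md, X, eps = 0.002), 3L)
})

test_that("disjoint spectra and over-shifted peaks yield no pairs", {
  mol <- mol_of("Oc1ccccc1")  # phenol, eH = 1
  fs <- generate_fragments(mol, max_depth = 1)
  dv <- deuterate_candidate(mol, 1L)
  p <- ion_mz(structure_mass(mol), "M+H")
  sh <- hdx_spectrum(p, 100)
  mh <- match_fragments(fragment_mz_hypotheses(fs, "+"), sh, all = TRUE)
  # disjoint: deuterated spectrum far from any hypothesis
  sd_far <- hdx_spectrum(400.2, 1, label = "deuterated")
  md <- match_fragments(
    fragment_mz_hypotheses(fs, "+", deuterated = TRUE,
                           variant = dv$variants[[1]], X = 1L),
    sd_far, all = TRUE)
  expect_equal(score_pair_hd(mh, md, 1L, 0.002), 0L)
  # a peak pair implying more exchanges than X + the deuteron finds no partner
  sd_over <- hdx_spectrum(p + 4 * DELTA_HD, 100, label = "deuterated")
  md2 <- match_fragments(
    fragment_mz_hypotheses(fs, "+", deuterated = TRUE,
                           variant = dv$variants[[1]], X = 1L),
    sd_over, all = TRUE)
  expect_equal(score_pair_hd(mh, md2, 1L, 0.002), 0L)
})

test_that("pair counts are bounded by peaks and fragments", {
  for (seed in 1:4) {
    fix <- generate_fixture_pair(mol_of(SMI$gallic), seed = seed)
    mol <- mol_of(SMI$gallic)
    fs <- generate_fragments(mol, max_depth = 2)
    dv <- deuterate_candidate(mol, fix$truth$X)
    mh <- match_fragments(fragment_mz_hypotheses(fs, "+"), fix$normal, all = TRUE)
    md <- match_fragments(
      fragment_mz_hypotheses(fs, "+", deuterated = TRUE,
                             variant = dv$variants[[1]], X = fix$truth$X),
      fix$hdx, all = TRUE)
    n <- score_pair_hd(mh, md, fix$truth$X, 0.002)
    expect_lte(n, min(length(fix$normal$mz), length(fix$hdx$mz), nrow(fs$frags)))
  }
})

test_that("S_OSN follows 1 / (|X - eH| + 1)", {
  expect_equal(score_osn(3, 3), 1)
  expect_equal(score_osn(1, 3), 1 / 3)
  expect_equal(score_osn(0, 0), 1)
  # strictly decreasing in the disagreement
  vals <- vapply(0:5, function(d) score_osn(2 + d, 2), 0)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("candidate filtering drops salts and non-standard isotopes", {
  cands <- data.frame(
    id = c("salt", "c13", "ok", "broken"),
    smiles = c("OC(=O)C(=O)[O-].[Na+]", "[13CH3]O", SMI$gallic, "C1CC"))
  expect_message(flt <- filter_candidates(cands), "filtered 3")
  expect_equal(flt$id, "ok")
})

test_that("consensus ranking max-normalizes, weights, and average-ranks ties", {
  sc <- data.frame(MetFrag = c(10, 5, 0), MetFragHD = c(2, 2, 2),
                   PairHD = c(4, 8, 0), OSN = c(1, 0.5, 0.25))
  w <- c(MetFrag = 0.25, MetFragHD = 0.25, PairHD = 0.25, OSN = 0.25)
  r <- consensus_rank(sc, w)
  expect_equal(r$MetFrag_norm, c(1, 0.5, 0))
  expect_equal(r$consensus,
               as.numeric(as.matrix(r[paste0(names(w), "_norm")]) %*% w))
  # invariance under positive rescaling of a raw column
  sc2 <- transform(sc, PairHD = PairHD * 1000)
  expect_equal(consensus_rank(sc2, w)$rank, r$rank)
  # w = (1,0,0,0) reduces to the plain fragmenter ordering
  r_mf <- consensus_rank(sc, c(1, 0, 0, 0))
  expect_equal(r_mf$rank, rank(-sc$MetFrag))
  # all-zero column normalizes to zero, not NaN
  sc3 <- transform(sc, MetFragHD = 0)
  expect_true(all(consensus_rank(sc3, w)$MetFragHD_norm == 0))
  # total ties share the average rank (k + 1) / 2
  sc4 <- sc[c(1, 1, 1), ]
  expect_equal(consensus_rank(sc4, w)$rank, rep(2, 3))
  expect_error(consensus_rank(sc[0, ], w), "empty")
  expect_error(consensus_rank(sc, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})
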