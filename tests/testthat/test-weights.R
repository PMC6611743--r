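# Simplex sampling, weight optimization, and cross-validation.

random_instance <- function(n_cand, correct_boost, seed_mat) {
  # raw scores with the correct candidate boosted along PairHD and OSN
  m <- matrix(seed_mat, n_cand, 4)
  colnames(m) <- c("MetFrag", "MetFragHD", "PairHD", "OSN")
  m
}

test_that("simplex draws are uniform, normalized, and reproducible", {
  w <- sample_simplex(1000, seed = 42)
  expect_equal(dim(w), c(1000L, 4L))
  expect_true(all(abs(rowSums(w) - 1) < 1e-9))
  expect_true(all(w >= 0))
  expect_identical(sample_simplex(1000, seed = 42), w)
  expect_false(identical(sample_simplex(1000, seed = 43), w))
  # Dirichlet(1,1,1,1) mean is (1/4, 1/4, 1/4, 1/4)
  big <- sample_simplex(1e5, seed = 7)
  expect_true(all(abs(colMeans(big) - 0.25) < 0.01))
})

test_that("weight optimization maximizes training top-1 with tie rules", {
  set.seed(99)
  # only OSN separates the correct candidate from the decoys
  instances <- lapply(1:12, function(i) {
    sc <- data.frame(MetFrag = c(0.8, rep(1, 9)), MetFragHD = rep(1, 10),
                     PairHD = rep(1, 10), OSN = c(1, rep(0.2, 9)))
    hdx_instance(sc, correct = 1L)
  })
  w <- optimize_weights(instances, n_draws = 200, seed = 5)
  expect_equal(attr(w, "top1"), 12L)
  # the winning draws are exactly those putting enough mass on OSN
  expect_gt(w[["OSN"]] * 0.8, w[["MetFrag"]] * 0.2)
  expect_equal(sum(w), 1, tolerance = 1e-9)

  # degenerate case: correct candidate dominates every column, so the very
  # first draw already wins and is returned
  dom <- lapply(1:3, function(i)
    hdx_instance(data.frame(MetFrag = c(1, 0.1), MetFragHD = c(1, 0.1),
                            PairHD = c(1, 0.1), OSN = c(1, 0.1)), 1L))
  w1 <- optimize_weights(dom, n_draws = 50, seed = 11)
  expect_equal(as.numeric(w1), sample_simplex(50, seed = 11)[1, ],
               tolerance = 1e-12)
  expect_error(optimize_weights(dom, n_draws = 0), "n_draws")
})

test_that("an uninformative constant column never hurts attainable top-1", {
  set.seed(3)
  instances <- lapply(1:10, function(i) {
    sc <- data.frame(MetFrag = runif(8), MetFragHD = 1,
                     PairHD = runif(8), OSN = runif(8))
    hdx_instance(sc, correct = which.max(sc$MetFrag))
  })
  w_small <- optimize_weights(instances, n_draws = 300, seed = 2,
                              terms = c("MetFrag", "PairHD", "OSN"))
  w_full <- optimize_weights(instances, n_draws = 300, seed = 2)
  expect_gte(attr(w_full, "top1") + 1L, attr(w_small, "top1"))
})

test_that("cross-validation pools fold results and honors the seed", {
  set.seed(17)
  instances <- lapply(1:20, function(i) {
    sc <- data.frame(MetFrag = runif(15), MetFragHD = runif(15),
                     PairHD = c(2, runif(14)), OSN = c(1, runif(14)))
    hdx_instance(sc, correct = 1L)
  })
  cv <- cross_validate(instances, k_folds = 5, n_draws = 100, seed = 9)
  expect_equal(as.integer(sort(table(cv$folds))), rep(4L, 5))
  counts <- cv$counts
  expect_true(all(diff(counts) >= 0))          # top1 <= top3 <= top5 <= top10
  expect_lte(counts[["top10"]], cv$n)
  cv2 <- cross_validate(instances, k_folds = 5, n_draws = 100, seed = 9)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$counts, cv2$counts)
  expect_error(cross_validate(instances, k_folds = 21), "folds")
})

test_that("k = n cross-validation is leave-one-out", {
  set.seed(31)
  instances <- lapply(1:8, function(i)
    hdx_instance(data.frame(MetFrag = runif(5), MetFragHD = runif(5),
                            PairHD = c(1.5, runif(4)), OSN = c(1, runif(4))),
                 1L))
  cv <- cross_validate(instances, k_folds = 8, n_draws = 50, seed = 13)
  expect_equal(length(cv$per_fold), 8L)
  expect_true(all(vapply(cv$per_fold, function(f) f$n, 0L) == 1L))
})

test_that("optimization recovers generating weights at least as well as equal weights", {
  # instances generated so that PairHD and OSN carry the signal, mirroring
  # fitted weights of roughly (0.1, 0, 0.5, 0.4)
  set.seed(123)
  w_true <- c(0.1, 0, 0.5, 0.4)
  instances <- lapply(1:25, function(i) {
    n <- 20
    m <- cbind(MetFrag = runif(n), MetFragHD = runif(n),
               PairHD = runif(n), OSN = runif(n))
    correct <- sample.int(n, 1)
    m[correct, ] <- pmin(1, m[correct, ] + w_true)
    hdx_instance(as.data.frame(m), correct)
  })
  top1_of <- function(w) sum(vapply(instances, function(inst) {
    s <- as.numeric(inst$norm %*% w)
    rank(-s, ties.method = "average")[inst$correct] <= 1
  }, TRUE))
  w_opt <- optimize_weights(instances, n_draws = 500, seed = 77)
  expect_gte(top1_of(as.numeric(w_opt)), top1_of(rep(0.25, 4)))
})

test_that("cross-validation reports export as JSON and table-shaped CSV", {
  set.seed(5)
  instances <- lapply(1:10, function(i)
    hdx_instance(data.frame(MetFrag = runif(5), MetFragHD = runif(5),
                            PairHD = c(1.5, runif(4)), OSN = c(1, runif(4))),
                 1L))
  cv <- cross_validate(instances, k_folds = 5, n_draws = 50, seed = 1)
  tf_json <- tempfile(fileext = ".json"); tf_csv <- tempfile(fileext = ".csv")
  df <- write_cv_report(list(all_terms = cv), json = tf_json, csv = tf_csv)
  expect_true(file.exists(tf_json) && file.exists(tf_csv))
  back <- jsonlite::read_json(tf_json)
  expect_equal(back$all_terms$n, 10L)
  tab <- read.csv(tf_csv)
  expect_equal(tab$terms, "all_terms")
  expect_equal(tab$top1, unname(cv$counts["top1"]))
  unlink(c(tf_json, tf_csv))
})
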