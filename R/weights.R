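# Consensus-weight optimization: randomized search over the weight simplex,
# maximizing the training top-1 count, wrapped in k-fold cross-validation.

#' Uniform draws from the weight simplex
#'
#' Draws vectors of `dim` non-negative entries summing to 1, uniformly on the
#' simplex, via normalized i.i.d. exponential variates (exact
#' Dirichlet(1, ..., 1)).
#'
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; draws are reproducible.
#' @param dim Simplex dimension (default 4 scoring terms).
#' @return `n` x `dim` matrix, rows summing to 1.
#' @export
sample_simplex <- function(n, seed = NULL, dim = 4L) {
  stopifnot(n >= 1, dim >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  e <- matrix(stats::rexp(n * dim), nrow = n)
  e / rowSums(e)
}

#' Training instance for weight optimization
#'
#' Bundles the precomputed raw score matrix of one spectrum pair's candidate
#' list with the index of the correct candidate.
#'
#' @param scores Matrix/data frame of raw scores with columns `MetFrag`,
#'   `MetFragHD`, `PairHD`, `OSN` (variant maxima taken), one row per candidate.
#' @param correct Row index of the correct candidate.
#' @return Object of class `hdx_instance` holding the max-normalized score
#'   matrix.
#' @export
hdx_instance <- function(scores, correct) {
  scores <- as.data.frame(scores)
  need <- c("MetFrag", "MetFragHD", "PairHD", "OSN")
  stopifnot(all(need %in% names(scores)),
            correct >= 1, correct <= nrow(scores),
            all(is.finite(as.matrix(scores[need]))))
  norm <- vapply(need, function(cn) {
    v <- scores[[cn]]
    m <- max(v)
    if (m <= 0) rep(0, length(v)) else v / m
  }, numeric(nrow(scores)))
  structure(list(norm = matrix(norm, nrow = nrow(scores),
                               dimnames = list(NULL, need)),
                 correct = as.integer(correct)),
            class = "hdx_instance")
}

# average rank of the correct candidate under weight vector w
.instance_rank <- function(inst, w) {
  s <- as.numeric(inst$norm %*% w)
  rank(-s, ties.method = "average")[inst$correct]
}

.topk_counts <- function(ranks, ks = c(1, 3, 5, 10)) {
  stats::setNames(vapply(ks, function(k) sum(ranks <= k), 0L),
                  paste0("top", ks))
}

#' Optimize consensus weights on a training set
#'
#' Evaluates `n_draws` uniform simplex draws and returns the one maximizing the
#' number of correctly top-1 ranked candidates (average rank under ties); ties
#' between draws are broken by the top-3 count, then by first occurrence.
#'
#' @param instances List of [hdx_instance()] objects.
#' @param n_draws Number of simplex draws (default 1000).
#' @param seed Integer seed for the draws.
#' @param terms Character subset of
#'   `c("MetFrag", "MetFragHD", "PairHD", "OSN")` to allow nonzero weight;
#'   excluded terms get weight 0.
#' @return Named weight vector (length 4, summing to 1) with attributes `top1`
#'   and `top3` on the training set.
#' @export
optimize_weights <- function(instances, n_draws = 1000L, seed = NULL,
                             terms = c("MetFrag", "MetFragHD", "PairHD", "OSN")) {
  stopifnot(length(instances) >= 1, n_draws >= 1)
  all_terms <- c("MetFrag", "MetFragHD", "PairHD", "OSN")
  terms <- match.arg(terms, all_terms, several.ok = TRUE)
  draws <- matrix(0, n_draws, 4, dimnames = list(NULL, all_terms))
  draws[, terms] <- sample_simplex(n_draws, seed = seed, dim = length(terms))
  best <- NULL
  for (i in seq_len(n_draws)) {
    w <- draws[i, ]
    ranks <- vapply(instances, .instance_rank, 0, w = w)
    t1 <- sum(ranks <= 1); t3 <- sum(ranks <= 3)
    if (is.null(best) || t1 > best$t1 || (t1 == best$t1 && t3 > best$t3))
      best <- list(w = w, t1 = t1, t3 = t3)
  }
  structure(best$w, top1 = best$t1, top3 = best$t3)
}

#' Cross-validated weight optimization
#'
#' Randomized fold assignment under `seed`; per fold, weights are fitted on the
#' complement (restricted to `terms`) and the held-out instances are ranked
#' with them. Top-1/3/5/10 counts are pooled over folds; `k_folds` equal to the
#' instance count gives leave-one-out behavior.
#'
#' @inheritParams optimize_weights
#' @param k_folds Number of folds (2 <= k <= number of instances).
#' @return Object of class `hdx_cv`: list with `folds` (assignment), per-fold
#'   `weights` and counts, pooled `counts`, `percent`, `ranks`, and `n`.
#' @export
cross_validate <- function(instances, k_folds = 10L, n_draws = 1000L,
                           seed = NULL,
                           terms = c("MetFrag", "MetFragHD", "PairHD", "OSN")) {
  n <- length(instances)
  if (k_folds > n) stop("more folds than instances")
  stopifnot(k_folds >= 2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  folds <- sample(rep(seq_len(k_folds), length.out = n))
  ranks <- numeric(n)
  per_fold <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    w <- optimize_weights(instances[train], n_draws = n_draws,
                          seed = if (is.null(seed)) NULL else seed + f,
                          terms = terms)
    ranks[test] <- vapply(instances[test], .instance_rank, 0, w = as.numeric(w))
    per_fold[[f]] <- list(fold = f, weights = as.numeric(w),
                          n = length(test), counts = .topk_counts(ranks[test]))
  }
  counts <- .topk_counts(ranks)
  structure(list(folds = folds, per_fold = per_fold, ranks = ranks,
                 counts = counts, percent = 100 * counts / n, n = n,
                 terms = terms),
            class = "hdx_cv")
}

#' @export
print.hdx_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation on %d spectrum pairs (terms: %s)\n",
              length(x$per_fold), x$n, paste(x$terms, collapse = ", ")))
  tab <- rbind(count = x$counts, percent = round(x$percent, 1))
  print(tab)
  invisible(x)
}

#' Write a cross-validation report
#'
#' JSON (full report) and/or a results-table-shaped CSV (one row per scoring
#' term subset, top-1/3/5/10 counts and percentages).
#'
#' @param reports A single `hdx_cv` or a named list of them (names = term-set
#'   labels).
#' @param json Optional JSON output path.
#' @param csv Optional CSV output path.
#' @return The summary data frame, invisibly.
#' @export
write_cv_report <- function(reports, json = NULL, csv = NULL) {
  if (inherits(reports, "hdx_cv")) reports <- list(all = reports)
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(terms = nm, n = r$n, t(r$counts), t(round(r$percent, 1)),
               check.names = FALSE)
  }))
  names(df) <- c("terms", "n", "top1", "top3", "top5", "top10",
                 "top1_pct", "top3_pct", "top5_pct", "top10_pct")
  if (!is.null(json)) {
    payload <- lapply(reports, function(r)
      list(n = r$n, counts = as.list(r$counts),
           percent = as.list(round(r$percent, 2)),
           folds = lapply(r$per_fold, function(pf)
             list(fold = pf$fold, n = pf$n, weights = pf$weights,
                  counts = as.list(pf$counts)))))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  invisible(df)
}
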