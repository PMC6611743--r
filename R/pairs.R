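# Untargeted MS1 pairing: match features between the normal and the
# deuterium-flooded run by retention time and a mass difference of
# k * 1.006277 Da.

#' Read an MS1 feature table
#'
#' CSV with columns `mz`, `rt` (minutes), `intensity` (case insensitive).
#'
#' @param path CSV path.
#' @return Data frame with columns `mz`, `rt`, `intensity`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("mz", "rt", "intensity")
  if (!all(need %in% names(df)))
    stop("feature CSV needs mz, rt, intensity columns: ", path)
  stopifnot(all(df$mz > 0), all(df$rt >= 0))
  df[need]
}

#' Pair normal and deuterated MS1 features
#'
#' Finds all (normal, deuterated) feature pairs whose neutral-mass difference
#' matches `k * 1.006277` Da for some `0 <= k <= max_X` within `mass_tol_da`,
#' and whose retention times agree within `rt_window`. Positive-mode deuterated
#' features are treated as `[M+D]+` and negative as `[M-D]-`. Pairs with
#' `k >= 1` are flagged as isotope-confusable when the mass tolerance (or a
#' given resolving power) cannot separate a 13C isotopologue from a
#' monodeuterated species (0.00292 Da apart).
#'
#' @param normal,deuterated Feature tables (`mz`, `rt`, `intensity`).
#' @param max_X Largest exchange count considered (default 20).
#' @param rt_window Retention-time window in minutes (default 0.4).
#' @param mode Ion mode `"+"` or `"-"`.
#' @param mass_tol_da Mass-difference tolerance in Da (default 0.002).
#' @param resolution Optional instrument resolving power used for the isotope
#'   flag.
#' @param isolation_width MS/MS isolation width (m/z) used to warn when another
#'   pair's precursor falls inside the window of a pair (default 1.3).
#' @return Data frame: indices `i_normal`, `i_deut`, neutral masses, `k`,
#'   `adduct_deut` (the deuteron adduct, or the protonated fallback for
#'   unexchanged compounds seen at identical m/z), `residual_da`, `drt`,
#'   `isotope_risk`, `isolation_overlap`.
#' @export
find_pairs <- function(normal, deuterated, max_X = 20L, rt_window = 0.4,
                       mode = c("+", "-"), mass_tol_da = 0.002,
                       resolution = NULL, isolation_width = 1.3) {
  mode <- match.arg(mode)
  stopifnot(nrow(normal) > 0, nrow(deuterated) > 0, rt_window > 0,
            mass_tol_da > 0, max_X >= 0)
  add_h <- if (mode == "+") "M+H" else "M-H"
  add_d <- if (mode == "+") "M+D" else "M-D"
  mn <- neutral_mass(normal$mz, add_h)
  md <- neutral_mass(deuterated$mz, add_d)
  # fallback: an unexchanged compound can still ionize with H+ (or lose H) in
  # the deuterium-flooded run, appearing at identical m/z in both runs
  md_h <- neutral_mass(deuterated$mz, add_h)
  rows <- list()
  for (i in seq_len(nrow(normal))) {
    drt <- abs(deuterated$rt - normal$rt[i])
    for (j in which(drt <= rt_window)) {
      adduct_d <- add_d
      dm <- md[j] - mn[i]
      k <- round(dm / .delta_hd)
      residual <- dm - k * .delta_hd
      if (k < 0 || abs(residual) > mass_tol_da) {
        dm2 <- md_h[j] - mn[i]
        k2 <- round(dm2 / .delta_hd)
        if (k2 < 0 || abs(dm2 - k2 * .delta_hd) > mass_tol_da) next
        k <- k2; residual <- dm2 - k2 * .delta_hd; adduct_d <- add_h
      }
      if (k > max_X) next
      conf <- isotope_confusability(deuterated$mz[j])
      # a 13C-isotopologue explanation shifts the pair residual by 0.00292 Da;
      # flag when that alternative also fits the tolerance (or the stated
      # resolving power cannot separate the isotopologues)
      risk <- min(abs(residual - conf$delta_da), abs(residual + conf$delta_da)) <= mass_tol_da ||
        (!is.null(resolution) && resolution < deuterated$mz[j] / conf$delta_da)
      rows[[length(rows) + 1L]] <-
        data.frame(i_normal = i, i_deut = j, mz_normal = normal$mz[i],
                   mz_deut = deuterated$mz[j], neutral_normal = mn[i],
                   neutral_deut = md[j], k = as.integer(k),
                   adduct_deut = adduct_d,
                   residual_da = residual, drt = drt[j], isotope_risk = risk)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(i_normal = integer(), i_deut = integer(),
                      mz_normal = numeric(), mz_deut = numeric(),
                      neutral_normal = numeric(), neutral_deut = numeric(),
                      k = integer(), adduct_deut = character(),
                      residual_da = numeric(), drt = numeric(),
                      isotope_risk = logical())
  # precursors of other accepted pairs inside the isolation window
  out$isolation_overlap <- logical(nrow(out))
  if (nrow(out) > 1) {
    for (r in seq_len(nrow(out))) {
      others <- out[-r, ]
      out$isolation_overlap[r] <-
        any(abs(others$mz_normal - out$mz_normal[r]) <= isolation_width / 2 |
              abs(others$mz_deut - out$mz_deut[r]) <= isolation_width / 2)
    }
    if (any(out$isolation_overlap))
      warning(sprintf("%d pair(s) have another pair's precursor inside the %.1f m/z isolation window",
                      sum(out$isolation_overlap), isolation_width))
  }
  out
}
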