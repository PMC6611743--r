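# MS/MS peak-list container and readers/writers for two-column text, MGF and
# MSP. No installed package reads these peak-list formats, so the parsers are
# deliberately small and round-trip tested.

#' MS/MS spectrum
#'
#' @param mz Numeric vector of peak m/z values (Da).
#' @param intensity Peak intensities (>= 0); if `NULL`, all peaks are given
#'   equal intensity (centroid lists without intensities degrade gracefully).
#' @param precursor_mz Precursor ion m/z (Da), or `NA`.
#' @param adduct Adduct label ("M+H", "M+D", "M-H", "M-D"), or `NA`.
#' @param mode Ion mode `"+"`/`"-"`; inferred from `adduct` when missing.
#' @param label `"normal"` or `"deuterated"`.
#' @param annotations Named list of extra metadata preserved on write.
#' @return Object of class `hdx_spectrum`; peaks sorted by m/z.
#' @export
hdx_spectrum <- function(mz, intensity = NULL, precursor_mz = NA_real_,
                         adduct = NA_character_, mode = NA_character_,
                         label = c("normal", "deuterated"),
                         annotations = list()) {
  label <- match.arg(label)
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  o <- order(mz)
  if (is.na(mode) && !is.na(adduct)) mode <- .adduct_mode(adduct)
  s <- structure(list(mz = mz[o], intensity = intensity[o],
                      precursor_mz = precursor_mz, adduct = adduct,
                      mode = mode, label = label, annotations = annotations),
                 class = "hdx_spectrum")
  if (!is.na(precursor_mz) && length(mz) && max(mz) > precursor_mz + 0.5)
    attr(s, "flag_above_precursor") <- TRUE
  s
}

#' @export
print.hdx_spectrum <- function(x, ...) {
  cat(sprintf("<hdx_spectrum (%s): %d peaks, precursor %s %s mode %s>\n",
              x$label, length(x$mz),
              if (is.na(x$precursor_mz)) "?" else sprintf("%.4f", x$precursor_mz),
              if (is.na(x$adduct)) "" else x$adduct,
              if (is.na(x$mode)) "?" else x$mode))
  invisible(x)
}

#' @export
length.hdx_spectrum <- function(x) length(x$mz)

#' Read an MS/MS peak list
#'
#' Supported formats: `"twocol"` (whitespace-separated m/z intensity, `#`
#' comments), `"mgf"` (first BEGIN IONS block; PEPMASS, CHARGE honored), and
#' `"msp"` (first record; `PrecursorMZ`, `Ion_mode` honored). Unknown header
#' fields are kept in `annotations`.
#'
#' @param path Input file.
#' @param format One of `"twocol"`, `"mgf"`, `"msp"`; default guesses from the
#'   file extension.
#' @param label Spectrum label, `"normal"` or `"deuterated"`.
#' @return An [hdx_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "twocol", "mgf", "msp"),
                          label = c("normal", "deuterated")) {
  format <- match.arg(format)
  label <- match.arg(label)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mgf") "mgf" else if (ext == "msp") "msp" else "twocol"
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)) || !any(nzchar(trimws(lines))))
    stop("empty spectrum file: ", path)
  switch(format,
         twocol = .read_twocol(lines, path, label),
         mgf = .read_mgf(lines, path, label),
         msp = .read_msp(lines, path, label))
}

.parse_peak_lines <- function(lines, path, lineno) {
  toks <- strsplit(trimws(lines), "[ \t,;]+")
  mz <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 1)))
  it <- suppressWarnings(as.numeric(vapply(toks, function(t) if (length(t) > 1) t[2] else "1", "")))
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad))
    stop(sprintf("malformed peak record in %s at line %d: '%s'",
                 path, lineno[bad[1]], lines[bad[1]]))
  list(mz = mz, intensity = it)
}

.read_twocol <- function(lines, path, label) {
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) stop("no peaks in ", path)
  p <- .parse_peak_lines(lines[keep], path, keep)
  hdx_spectrum(p$mz, p$intensity, label = label)
}

.read_mgf <- function(lines, path, label) {
  b <- which(toupper(trimws(lines)) == "BEGIN IONS")
  e <- which(toupper(trimws(lines)) == "END IONS")
  if (!length(b) || !length(e) || e[1] <= b[1]) stop("no BEGIN IONS block in ", path)
  body_idx <- (b[1] + 1):(e[1] - 1)
  body <- lines[body_idx]
  is_kv <- grepl("^[A-Za-z][A-Za-z0-9_]*=", body)
  kv <- body[is_kv]
  keys <- toupper(sub("=.*", "", kv))
  vals <- sub("^[^=]*=", "", kv)
  ann <- stats::setNames(as.list(vals), keys)
  prec <- if ("PEPMASS" %in% keys)
    as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]][1]) else NA_real_
  mode <- NA_character_
  if ("CHARGE" %in% keys) {
    ch <- vals[match("CHARGE", keys)]
    mode <- if (grepl("-", ch)) "-" else "+"
  }
  pk <- which(!is_kv & nzchar(trimws(body)))
  if (!length(pk)) stop("MGF block has no peaks in ", path)
  p <- .parse_peak_lines(body[pk], path, body_idx[pk])
  hdx_spectrum(p$mz, p$intensity, precursor_mz = prec, mode = mode,
               label = label, annotations = ann)
}

.read_msp <- function(lines, path, label) {
  is_kv <- grepl("^[A-Za-z][A-Za-z0-9_ ]*:", lines)
  kv <- lines[is_kv]
  keys <- toupper(trimws(sub(":.*", "", kv)))
  vals <- trimws(sub("^[^:]*:", "", kv))
  ann <- stats::setNames(as.list(vals), keys)
  prec <- NA_real_
  for (k in c("PRECURSORMZ", "PRECURSOR_MZ")) {
    if (k %in% keys) prec <- as.numeric(vals[match(k, keys)])
  }
  mode <- NA_character_
  if ("ION_MODE" %in% keys)
    mode <- if (grepl("^n", tolower(vals[match("ION_MODE", keys)]))) "-" else "+"
  pk <- which(!is_kv & nzchar(trimws(lines)))
  if (!length(pk)) stop("MSP record has no peaks in ", path)
  p <- .parse_peak_lines(lines[pk], path, pk)
  hdx_spectrum(p$mz, p$intensity, precursor_mz = prec, mode = mode,
               label = label, annotations = ann)
}

#' Write an MS/MS peak list
#'
#' @param spec An [hdx_spectrum()].
#' @param path Output file.
#' @param format `"twocol"`, `"mgf"`, or `"msp"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, format = c("twocol", "mgf", "msp")) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "hdx_spectrum"))
  pk <- sprintf("%.6f %.6g", spec$mz, spec$intensity)
  lines <- switch(format,
    twocol = pk,
    mgf = c("BEGIN IONS",
            if (!is.na(spec$precursor_mz)) sprintf("PEPMASS=%.6f", spec$precursor_mz),
            if (!is.na(spec$mode)) paste0("CHARGE=1", spec$mode),
            paste0("TITLE=", spec$label),
            pk, "END IONS"),
    msp = c(paste0("Name: ", spec$label),
            if (!is.na(spec$precursor_mz)) sprintf("PrecursorMZ: %.6f", spec$precursor_mz),
            if (!is.na(spec$mode)) paste0("Ion_mode: ", if (spec$mode == "-") "negative" else "positive"),
            sprintf("Num Peaks: %d", length(spec$mz)),
            pk))
  writeLines(lines, path)
  invisible(path)
}
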