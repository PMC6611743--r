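# Flat key=value run configuration for the command-line interface.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Values that parse as numbers become numeric. Unknown keys are kept so CLI
#' flags can override anything.
#'
#' @param path Config file path, or `NULL` for defaults only.
#' @return Named list of settings merged over [hdx_config()] defaults (plus
#'   `weights`, `mode`, `seed`).
#' @export
read_config <- function(path = NULL) {
  cfg <- hdx_config()
  cfg$weights <- hdx_default_weights()
  cfg$mode <- "+"
  cfg$seed <- NULL
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  for (ln in readLines(path, warn = FALSE)) {
    ln <- sub("#.*", "", ln)
    if (!grepl("=", ln)) next
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!nzchar(key) || !nzchar(val)) next
    num <- suppressWarnings(as.numeric(strsplit(val, "[, ]+")[[1]]))
    cfg[[key]] <- if (!anyNA(num)) num else val
  }
  cfg
}
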