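# Run configuration: flat TOML-style key/value text.
# Lines are `key = value` with optional [section] headers that prefix keys
# as `section.key`; `#` starts a comment. Unknown keys are rejected.

.config_schema <- function() {
  list(
    model = list(default = "A1", type = "character"),
    Q = list(default = 20, type = "numeric"),
    seed = list(default = 1, type = "numeric"),
    m = list(default = 256, type = "numeric"),
    k = list(default = 7, type = "numeric"),
    phased = list(default = TRUE, type = "logical"),
    af_cutoff = list(default = 0.25, type = "numeric"),
    s_lo = list(default = 1e-4, type = "numeric"),
    s_hi = list(default = 0.1, type = "numeric"),
    n_donor = list(default = 4, type = "numeric"),
    n_recipient = list(default = 16, type = "numeric"),
    n_outgroup = list(default = 16, type = "numeric"),
    train.epochs = list(default = 3, type = "numeric"),
    train.batch_size = list(default = 64, type = "numeric"),
    train.split = list(default = 0.9, type = "numeric"),
    calibrate.ratios = list(default = "1:0.1:0.02", type = "character"),
    calibrate.method = list(default = "beta", type = "character")
  )
}

#' Load and validate a run configuration
#'
#' @param path path to a TOML-style key/value config file.
#' @return named list with all schema keys (defaults filled in); class
#'   `introscan_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  schema <- .config_schema()
  cfg <- lapply(schema, `[[`, "default")
  section <- ""
  for (ln in readLines(path)) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    full <- if (nzchar(section)) paste0(section, ".", key) else key
    if (!full %in% names(schema)) stop("unknown config key: ", full)
    cfg[[full]] <- switch(schema[[full]]$type,
      numeric = {
        x <- suppressWarnings(as.numeric(val))
        if (is.na(x)) stop("config key ", full, " expects a number, got: ", val)
        x
      },
      logical = {
        x <- as.logical(toupper(val))
        if (is.na(x)) stop("config key ", full, " expects true/false, got: ", val)
        x
      },
      val)
  }
  # eager validation of compound values
  parse_ratios(cfg$calibrate.ratios)
  class(cfg) <- "introscan_config"
  cfg
}

#' Write a configuration back to disk
#'
#' Inverse of [load_config()]: `write_config` then `load_config` round
#' trips to an identical configuration.
#'
#' @param cfg an `introscan_config`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE)
    else as.character(v)
  }
  writeLines(vapply(names(cfg), function(k) paste(k, "=", fmt(cfg[[k]])), ""),
             path)
  invisible(path)
}

#' Parse a "neutral:sweep:ai" ratio string
#'
#' @param s string like `"1:0.1:0.02"`.
#' @return a [class_ratios()].
#' @export
parse_ratios <- function(s) {
  parts <- suppressWarnings(as.numeric(strsplit(s, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 3 || anyNA(parts)) {
    stop("bad class ratio string (want neutral:sweep:ai): ", s)
  }
  class_ratios(parts[1], parts[2], parts[3])
}
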