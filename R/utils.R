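# Internal helpers shared across modules.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Signal a classed pepzone error
#'
#' All user-facing failure modes raise conditions of class
#' `pepzone_error_<kind>` so callers can branch on the kind of failure
#' rather than on message text.
#'
#' @param kind short snake_case error kind, e.g. "overlap_conflict"
#' @param msg human-readable message
#' @param ... fields attached to the condition
#' @noRd
pz_stop <- function(kind, msg, ...) {
  stop(errorCondition(
    msg,
    ...,
    class = c(paste0("pepzone_error_", kind), "pepzone_error")
  ))
}

#' Run an expression under a fixed RNG seed, restoring global state
#' @noRd
pz_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Path to a file shipped in inst/extdata
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a character vector of file names)
#' @examples
#' pepzone_extdata()
#' pepzone_extdata("peptide_table.tsv")
#' @export
pepzone_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pepzone")))
  }
  path <- system.file("extdata", file, package = "pepzone")
  if (!nzchar(path)) pz_stop("missing_file", sprintf("no extdata file '%s'", file))
  path
}

# 32-bit FNV-1a over a character rendering of an R object; used only to stamp
# output tables with a short config fingerprint (not cryptographic).
pz_config_hash <- function(x) {
  mul32 <- function(a, b) {
    # a*b mod 2^32 in doubles without losing precision
    lo <- a %% 65536
    hi <- (a %/% 65536) %% 65536
    (lo * b + ((hi * b) %% 65536) * 65536) %% 2^32
  }
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte because b < 256
    h <- mul32(h - h %% 256 + bitwXor(h %% 256, b %% 256), 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a TSV with commented header metadata
#'
#' Output tables carry `#`-prefixed header lines recording the producing
#' package version and an optional config fingerprint, so that runs are
#' traceable; `pz_read_tsv()` skips them.
#' @noRd
pz_write_tsv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pepzone %s", as.character(utils::packageVersion("pepzone"))), con)
  if (!is.null(config)) {
    writeLines(sprintf("# config_hash: %s", pz_config_hash(config)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pz_read_tsv <- function(path, ...) {
  if (!file.exists(path)) {
    pz_stop("missing_file", sprintf("file '%s' not found", path))
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
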