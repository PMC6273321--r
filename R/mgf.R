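# Mascot generic format (MGF) input/output for centroided MS/MS spectra.

#' Read an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, optional `TITLE`
#' and `CHARGE` (`1+` positive, `1-` negative) headers and `m/z intensity`
#' peak lines. Malformed blocks raise an error naming the offending line.
#'
#' @param path MGF file.
#' @return List of [peak_list()] objects (empty list for an empty file).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  n <- length(lines)
  perr <- function(ln, msg) {
    stop("MGF parse error at line ", ln, ": ", msg, call. = FALSE)
  }
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (line != "BEGIN IONS") {
      perr(i, paste0("expected BEGIN IONS, got '", line, "'"))
    }
    block_start <- i
    i <- i + 1L
    pepmass <- NA_real_; title <- NULL; mode <- "positive"
    mz <- numeric(0); int <- numeric(0)
    closed <- FALSE
    while (i <= n) {
      line <- trimws(lines[i])
      if (line == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (!nzchar(line)) { i <- i + 1L; next }
      if (grepl("=", line, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", line))
        val <- sub("^[^=]*=", "", line)
        if (key == "PEPMASS") {
          pepmass <- suppressWarnings(as.numeric(strsplit(val, "[ \t]+")[[1]][1]))
          if (is.na(pepmass)) perr(i, "unreadable PEPMASS value")
        } else if (key == "TITLE") {
          title <- val
        } else if (key == "CHARGE") {
          if (grepl("-", val, fixed = TRUE)) mode <- "negative"
        }
      } else {
        vals <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1]]))
        if (length(vals) < 1 || any(is.na(vals))) perr(i, "unreadable peak line")
        mz <- c(mz, vals[1])
        int <- c(int, if (length(vals) >= 2) vals[2] else 1)
      }
      i <- i + 1L
    }
    if (!closed) perr(block_start, "BEGIN IONS block never closed")
    if (is.na(pepmass)) {
      perr(block_start, "block is missing a PEPMASS header")
    }
    out[[length(out) + 1L]] <- peak_list(mz, int, precursor_mz = pepmass,
                                         mode = mode, id = title)
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra A [peak_list()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly. A write/read round trip preserves precursor,
#'   mode and peaks to 1e-6.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "peak_list")) spectra <- list(spectra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "peak_list"))
    writeLines("BEGIN IONS", con)
    if (!is.null(s$id)) writeLines(paste0("TITLE=", s$id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(paste0("CHARGE=1", if (s$mode == "negative") "-" else "+"), con)
    writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
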