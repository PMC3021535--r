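#' Read PWMs from a TRANSFAC-dialect matrix file
#'
#' Parses the classic count-matrix layout: an `ID` line naming the record, a
#' `P0` (or the older `PO`) column header, one row per motif position with
#' four counts in A C G T order (an optional trailing consensus letter is
#' tolerated), and `//` terminating each record. `XX` separators and any
#' other two-letter tag lines (`BF`, `NA`, ...) are ignored.
#'
#' @param path file to read
#' @param background,pseudocount passed to [pwm()] for every record.
#' @return a named list of `pwm` objects (possibly empty).
#' @export
read_transfac <- function(path, background = rep(0.25, 4),
                          pseudocount = NULL) {
  lines <- readLines(path)
  pwms <- list()
  id <- NULL
  rows <- NULL
  flush <- function() {
    if (is.null(id)) return()
    if (is.null(rows))
      stop(sprintf("TRANSFAC record '%s' has no matrix rows", id))
    m <- do.call(rbind, rows)
    colnames(m) <- DNA_BASES
    pwms[[id]] <<- pwm(m, id = id, background = background,
                       pseudocount = pseudocount)
    id <<- NULL; rows <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || ln == "XX") next
    if (ln == "//") { flush(); next }
    tok <- strsplit(ln, "\\s+")[[1L]]
    tag <- toupper(tok[[1L]])
    if (tag == "ID") {
      flush()
      id <- if (length(tok) > 1L) tok[[2L]] else sprintf("record_%d", i)
      next
    }
    if (tag %in% c("P0", "PO")) {
      if (is.null(id)) id <- sprintf("record_%d", i)
      rows <- list()
      next
    }
    if (!is.null(rows) && grepl("^[0-9]+$", tok[[1L]])) {
      vals <- suppressWarnings(as.numeric(tok[-1L]))
      # tolerate one trailing consensus letter
      if (length(vals) >= 1L && is.na(vals[length(vals)]))
        vals <- vals[-length(vals)]
      if (length(vals) != 4L || anyNA(vals))
        stop(sprintf(
          "malformed TRANSFAC matrix row at line %d: expected 4 counts, got '%s'",
          i, ln))
      rows[[length(rows) + 1L]] <- vals
      next
    }
    # any other tag line (BF, NA, DE, ...) is metadata; skip
  }
  flush()
  pwms
}

#' Write PWMs to a TRANSFAC-dialect matrix file
#'
#' Inverse of [read_transfac()]: counts round-trip exactly (written with
#' up to 6 significant digits, exact for integer counts).
#'
#' @param pwms a `pwm` or list of `pwm` objects
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_transfac <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    stopifnot(inherits(p, "pwm"))
    writeLines(c(sprintf("ID %s", p$id), "P0      A      C      G      T"),
               con)
    for (i in seq_len(nrow(p$counts))) {
      writeLines(sprintf("%02d %s", i,
                         paste(formatC(p$counts[i, ], format = "g",
                                       digits = 6, width = 6),
                               collapse = " ")), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}
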