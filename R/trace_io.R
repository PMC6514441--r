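# Plain-text trace container: a '# key = value' metadata header followed by
# tab-separated columns time, voltage, current (and optionally g_syn). Units
# are fixed: ms, mV, pA, nS. Unknown metadata keys survive a round trip.

#' Write a trace to a delimited text file
#'
#' @param trace a \code{tspn_trace}.
#' @param path output file path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tspn_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tspn-trace v1", con)
  writeLines(sprintf("# dt = %.17g", trace$dt), con)
  writeLines("# units = ms,mV,pA,nS", con)
  meta <- trace$meta
  meta$window <- NULL
  if (!is.null(trace$meta$window))
    meta$window <- paste(trace$meta$window, collapse = ",")
  for (k in names(meta))
    writeLines(sprintf("# %s = %s", k,
                       paste(format(meta[[k]], digits = 17), collapse = ",")), con)
  df <- data.frame(time = seq_along(trace$v) * trace$dt,
                   voltage = trace$v, current = trace$i_inj)
  if (!is.null(trace$g_syn)) df$g_syn <- trace$g_syn
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read a trace written by \code{write_trace}
#'
#' Malformed headers or ragged rows raise a parse error naming the offending
#' line; unknown metadata keys are preserved verbatim in \code{meta}.
#'
#' @param path input file path.
#' @return a \code{tspn_trace}.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || !grepl("tspn-trace", lines[1]))
    stop("not a tspn trace file: ", path)
  meta <- list()
  for (i in hdr[-1]) {
    m <- regmatches(lines[i], regexec("^#\\s*([^=]+?)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3) stop("malformed header at line ", i)
    val <- m[3]
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    meta[[m[2]]] <- if (anyNA(num)) val else num
  }
  if (is.null(meta$dt)) stop("header is missing dt")
  body <- lines[-hdr]
  if (!length(body)) stop("no data rows")
  cols <- strsplit(body[1], "\t")[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nc <- length(cols)
  bad <- which(vapply(rows, length, integer(1)) != nc)
  if (length(bad))
    stop("ragged row at line ", max(hdr) + 1 + bad[1],
         ": expected ", nc, " columns")
  mat <- matrix(as.numeric(unlist(rows)), ncol = nc, byrow = TRUE,
                dimnames = list(NULL, cols))
  dt <- meta$dt
  units <- meta$units
  meta$dt <- NULL; meta$units <- NULL
  structure(list(dt = dt, v = unname(mat[, "voltage"]),
                 i_inj = unname(mat[, "current"]),
                 g_syn = if ("g_syn" %in% cols) unname(mat[, "g_syn"]) else NULL,
                 ca = NULL, gates_trace = NULL, state = NULL, meta = meta),
            class = "tspn_trace")
}
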