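.OCC_FORMAT <- "protolink-occupancy-1"

#' Write an occupancy trace to a tab-separated table
#'
#' Plain-text serialisation of one (species, pH, replicate) trace:
#' '# key=value' header lines (format version, species, pH with 2-decimal
#' formatting, replicate, seed, record interval), a column-header line
#' (frame index then site labels) and one 0/1 row per recorded state.
#'
#' @param trace an \linkS4class{OccupancyTrace}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeOccupancyTable <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# format=", .OCC_FORMAT),
    paste0("# species=", trace@species),
    sprintf("# pH=%.2f", trace@ph),
    paste0("# replicate=", trace@replicate),
    paste0("# seed=", trace@seed),
    paste0("# record_interval=", trace@recordInterval),
    paste(c("frame", trace@siteIds), collapse = "\t")), con)
  st <- trace@states
  writeLines(paste(seq_len(nrow(st)),
                   apply(st, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read an occupancy trace from a tab-separated table
#'
#' Strict parser for the format written by
#' \code{\link{writeOccupancyTable}}: malformed headers, unknown header
#' keys, non-binary cells, ragged rows, non-increasing frame indices and
#' empty data sections are each rejected with a located error rather
#' than coerced.
#'
#' @param path input file
#' @return an \linkS4class{OccupancyTrace}
#' @export
readOccupancyTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  if (!length(hdr) || !identical(hdr, seq_along(hdr)))
    stop("malformed header: '# key=value' lines must lead the file")
  kv <- sub("^# ", "", lines[hdr])
  eq <- regexpr("=", kv, fixed = TRUE)
  if (any(eq < 0)) stop("malformed header line: ", kv[which(eq < 0)[1]])
  keys <- substr(kv, 1, eq - 1)
  vals <- substr(kv, eq + 1, nchar(kv))
  known <- c("format", "species", "pH", "replicate", "seed",
             "record_interval")
  if (any(!keys %in% known))
    stop("unknown header key: ", keys[which(!keys %in% known)[1]])
  meta <- setNames(as.list(vals), keys)
  if (!identical(meta$format, .OCC_FORMAT))
    stop("unsupported format: ", meta$format)
  body <- lines[-hdr]
  if (length(body) < 1) stop("missing column header")
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (cols[1] != "frame") stop("column header must start with 'frame'")
  sids <- cols[-1]
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (!length(rows)) stop("empty data section")
  cells <- strsplit(rows, "\t", fixed = TRUE)
  len <- lengths(cells)
  if (any(len != length(cols)))
    stop("ragged row at data line ", which(len != length(cols))[1])
  m <- matrix(unlist(cells), nrow = length(rows), byrow = TRUE)
  frames <- suppressWarnings(as.integer(m[, 1]))
  if (anyNA(frames) || any(diff(frames) <= 0))
    stop("frame indices must be strictly increasing integers")
  st <- m[, -1, drop = FALSE]
  bad <- which(!(st %in% c("0", "1")))
  if (length(bad)) {
    rr <- (bad[1] - 1L) %% nrow(st) + 1L
    cc <- (bad[1] - 1L) %/% nrow(st) + 1L
    stop("non-binary cell '", st[bad[1]], "' at data row ", rr,
         ", site column '", sids[cc], "'")
  }
  states <- matrix(as.integer(st), nrow(st), ncol(st))
  colnames(states) <- sids
  new("OccupancyTrace", species = meta$species, ph = as.numeric(meta$pH),
      replicate = as.integer(meta$replicate), seed = as.integer(meta$seed),
      recordInterval = as.integer(meta$record_interval), states = states,
      siteIds = sids)
}
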