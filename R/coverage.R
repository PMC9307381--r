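
# Coverage tracks: per-chromosome run-length encoded signal with a sample id
# and role tags (group A/B, kind IP/input).  Signal is summed coverage, not
# read counts; the library size is the total summed signal and is asserted
# on load.

#' Construct a coverage track
#'
#' @param sample_id sample identifier.
#' @param values named list (by chromosome) of non-negative numeric vectors
#'   or `S4Vectors::Rle` objects of per-base signal.
#' @param group optional group tag (`"A"` or `"B"`).
#' @param kind optional kind tag (`"IP"` or `"input"`).
#' @return An object of class `coverage_track` with fields `sample_id`,
#'   `library_size`, `values`, `group`, `kind`.
#' @export
coverage_track <- function(sample_id, values, group = NA_character_,
                           kind = NA_character_) {
  stopifnot(is.list(values), !is.null(names(values)))
  values <- lapply(values, function(v) {
    r <- if (is(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
    if (any(S4Vectors::runValue(r) < 0)) stop("negative coverage values")
    r
  })
  lib <- sum(vapply(values, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                              S4Vectors::runLength(r)), 0))
  structure(list(sample_id = sample_id, library_size = lib, values = values,
                 group = group, kind = kind),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track %s [%s/%s], %d chrom(s), library %.0f>\n",
              x$sample_id, x$group, x$kind, length(x$values), x$library_size))
  invisible(x)
}

#' Read a bedGraph-style TSV into a coverage track
#'
#' Columns: chrom, start, end, value (0-based half-open).  Regions not
#' listed read as 0.
#'
#' @param path input path.
#' @param sample_id sample identifier.
#' @param group,kind optional role tags.
#' @return a `coverage_track`.
#' @export
read_bedgraph <- function(path, sample_id = basename(path),
                          group = NA_character_, kind = NA_character_) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  if (any(df$end <= df$start)) stop("bedGraph interval with end <= start")
  values <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping bedGraph intervals on ", d$chrom[1])
    v <- numeric(max(d$end))
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1):d$end[i]] <- d$value[i]
    S4Vectors::Rle(v)
  })
  coverage_track(sample_id, values, group = group, kind = kind)
}

#' Write a coverage track as bedGraph TSV
#'
#' Zero-valued runs are omitted.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$values), function(chrom) {
    r <- track$values[[chrom]]
    len <- S4Vectors::runLength(r)
    val <- as.numeric(S4Vectors::runValue(r))
    end <- cumsum(len)
    start <- end - len
    keep <- val != 0
    if (!any(keep)) return(character())
    sprintf("%s\t%d\t%d\t%s", chrom, start[keep], end[keep],
            as.character(val[keep]))
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

# Rle for a chromosome, zero-padded to at least `len` bases.
chrom_rle <- function(track, chrom, len) {
  r <- track$values[[chrom]]
  if (is.null(r)) return(S4Vectors::Rle(0, len))
  if (length(r) < len) r <- c(r, S4Vectors::Rle(0, len - length(r)))
  r
}

# Sum of a track's signal over 0-based half-open intervals on one chromosome.
interval_sums <- function(track, chrom, start, end) {
  if (!length(start)) return(numeric())
  len <- max(end)
  r <- chrom_rle(track, chrom, len)
  as.numeric(IRanges::viewSums(IRanges::Views(r, start = start + 1L, end = end)))
}
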