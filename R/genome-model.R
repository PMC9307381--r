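
# Peaks are plain data.frames with BED6-like columns (chrom, start, end,
# name, score, strand) plus an optional integer `summit` (offset from start).
# Coordinates are 0-based half-open throughout the package.

#' Construct a validated peak table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `end > start`.
#' @param name peak identifiers (unique names recommended).
#' @param score numeric ranking value (used for "top N" selection).
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param summit optional integer offset from `start`, in `[0, end - start)`.
#' @return A `data.frame` with columns chrom, start, end, name, score,
#'   strand, summit.
#' @export
peak_table <- function(chrom, start, end, name = NULL, score = 0,
                       strand = ".", summit = NA_integer_) {
  n <- length(chrom)
  if (is.null(name)) name <- if (n) sprintf("peak_%d", seq_len(n)) else character()
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(rep_len(score, n)),
    strand = as.character(rep_len(strand, n)),
    summit = as.integer(rep_len(summit, n)),
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
  df
}

validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  need <- c("chrom", "start", "end", "name", "score", "strand")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peak table lacks columns: ", paste(miss, collapse = ", "))
  if (any(peaks$start < 0)) stop("peak start < 0")
  if (any(peaks$end <= peaks$start)) stop("peak end <= start")
  if (!all(peaks$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  if ("summit" %in% names(peaks)) {
    s <- peaks$summit
    bad <- !is.na(s) & (s < 0 | s >= peaks$end - peaks$start)
    if (any(bad)) stop("summit outside [0, length) for peak(s): ",
                       paste(peaks$name[bad], collapse = ", "))
  }
  invisible(peaks)
}

#' Read a BED file into a peak table
#'
#' BED is 0-based half-open and is preserved unchanged.  Score comes from
#' column 5 when present (else 0), strand from column 6 (else `"."`).
#'
#' @param path path to a tab-separated BED file (>= 3 columns).
#' @return peak table as from [peak_table()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(peak_table(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop("malformed BED line ", lineno[which(nf < 3)[1]],
                        ": fewer than 3 columns")
  f <- function(i) vapply(fields, function(x) if (length(x) >= i) x[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) stop("malformed BED line ", lineno[which(bad)[1]],
                     ": non-integer coordinates")
  bad <- end <= start
  if (any(bad)) stop("malformed BED line ", lineno[which(bad)[1]],
                     ": end <= start")
  name <- f(4)
  name[is.na(name) | name == "."] <- sprintf("peak_%d", which(is.na(name) | name == "."))
  score <- suppressWarnings(as.numeric(f(5)))
  score[is.na(score)] <- 0
  strand <- f(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  peak_table(f(1), start, end, name, score, strand)
}

#' Write a peak table as BED6
#'
#' @param peaks peak table.
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  validate_peaks(peaks)
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   as.character(peaks$score), peaks$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

peaks_to_granges <- function(peaks) {
  validate_peaks(peaks)
  strand <- ifelse(peaks$strand == ".", "*", peaks$strand)
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = strand
  )
}

granges_to_peaks <- function(gr, name_prefix = "merged") {
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "."
  n <- length(gr)
  peak_table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (n) sprintf("%s_%05d", name_prefix, seq_len(n)) else character(),
    strand = st
  )
}

# Representative point of a peak: summit when present, else midpoint.
peak_points <- function(peaks) {
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
  s <- if ("summit" %in% names(peaks)) peaks$summit else rep(NA_integer_, nrow(peaks))
  ifelse(!is.na(s), peaks$start + s, mid)
}
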