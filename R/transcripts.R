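
# Transcript models: exon structure + CDS span + biotype.  Exons are stored
# 0-based half-open, sorted by genomic start, non-overlapping, all on one
# chromosome and strand.  Transcript offsets run 5'->3' of the transcript.

#' Construct a validated transcript model
#'
#' @param transcript_id,gene_id,gene_name identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end`
#'   (0-based half-open), sorted, non-overlapping.
#' @param cds_start,cds_end genomic bounds (0-based half-open) of the coding
#'   span, or `NA` for a lncRNA.
#' @param biotype `"mRNA"` or `"lncRNA"`; inferred from CDS presence when
#'   `NULL`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             gene_name = gene_id, biotype = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- data.frame(start = as.integer(exons$start), end = as.integer(exons$end))
  if (nrow(exons) == 0) stop("transcript ", transcript_id, " has no exons")
  if (is.unsorted(exons$start, strictly = FALSE))
    exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end <= exons$start))
    stop("transcript ", transcript_id, ": exon end <= start")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("transcript ", transcript_id, ": overlapping exons")
  has_cds <- !is.na(cds_start) && !is.na(cds_end)
  if (is.null(biotype)) biotype <- if (has_cds) "mRNA" else "lncRNA"
  t <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    chrom = chrom, strand = strand, exons = exons,
    cds_start = if (has_cds) as.integer(cds_start) else NA_integer_,
    cds_end = if (has_cds) as.integer(cds_end) else NA_integer_,
    biotype = biotype
  ), class = "transcript_model")
  if (biotype == "mRNA") {
    if (!has_cds) stop("transcript ", transcript_id, ": mRNA without CDS bounds")
    b <- cds_tx_bounds(t)
    L <- spliced_length(t)
    if (is.na(b[1]) || is.na(b[2]))
      stop("transcript ", transcript_id, ": CDS bounds not exonic")
    if (b[1] <= 0 || b[2] >= L || b[2] <= b[1])
      stop("transcript ", transcript_id,
           ": CDS must leave non-empty 5'UTR, CDS and 3'UTR")
  } else if (has_cds) {
    stop("transcript ", transcript_id, ": lncRNA must not carry CDS bounds")
  }
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%d-%d %s, %d exon(s), spliced %d nt>\n",
              x$transcript_id, x$biotype, x$chrom, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons), spliced_length(x)))
  invisible(x)
}

#' Spliced (exonic) length of a transcript
#' @param t a `transcript_model`.
#' @return integer number of exonic bases.
#' @export
spliced_length <- function(t) sum(t$exons$end - t$exons$start)

#' Map a genomic position to a transcript offset
#'
#' The offset is the number of exonic bases of `t` strictly 5' of `pos` in
#' transcript orientation (0 for the transcript's first base).  For
#' minus-strand transcripts offsets count from the 3'-most genomic
#' coordinate.  Intronic or outside positions yield `NA`.
#'
#' @param t a `transcript_model`.
#' @param pos genomic position (0-based), scalar or vector.
#' @return integer offset(s) in `[0, spliced_length)`, or `NA`.
#' @export
genomic_to_transcript <- function(t, pos) {
  ex <- t$exons
  cum <- c(0L, cumsum(ex$end - ex$start))
  out <- rep(NA_integer_, length(pos))
  idx <- findInterval(pos, ex$start)
  ok <- idx >= 1 & idx <= nrow(ex)
  ok[ok] <- pos[ok] < ex$end[idx[ok]]
  plus_off <- cum[idx[ok]] + (pos[ok] - ex$start[idx[ok]])
  out[ok] <- as.integer(plus_off)
  if (t$strand == "-") {
    L <- spliced_length(t)
    out <- ifelse(is.na(out), NA_integer_, L - 1L - out)
  }
  out
}

#' Map a transcript offset back to a genomic position
#'
#' Inverse of [genomic_to_transcript()] for exonic positions.
#'
#' @param t a `transcript_model`.
#' @param off transcript offset(s) in `[0, spliced_length)`.
#' @return genomic position(s), 0-based.
#' @export
transcript_to_genomic <- function(t, off) {
  L <- spliced_length(t)
  if (any(off < 0 | off >= L)) stop("offset outside [0, spliced_length)")
  if (t$strand == "-") off <- L - 1L - off
  ex <- t$exons
  cum <- c(0L, cumsum(ex$end - ex$start))
  idx <- findInterval(off, cum, rightmost.closed = FALSE)
  idx <- pmin(idx, nrow(ex))
  as.integer(ex$start[idx] + (off - cum[idx]))
}

# CDS bounds in transcript coordinates: c(cds_start_tx, cds_end_tx),
# half-open, with 0 <= cds_start_tx < cds_end_tx <= spliced_length.
cds_tx_bounds <- function(t) {
  if (is.na(t$cds_start)) return(c(NA_integer_, NA_integer_))
  a <- genomic_to_transcript(t, t$cds_start)
  b <- genomic_to_transcript(t, t$cds_end - 1L)
  c(min(a, b), max(a, b) + 1L)
}

#' Read a GTF file into transcript models
#'
#' GTF is 1-based closed; coordinates are converted to 0-based half-open on
#' read.  Biotype is inferred from CDS presence: a transcript with at least
#' one CDS feature is mRNA, otherwise lncRNA.  `cds_start`/`cds_end` are the
#' min/max over CDS features.
#'
#' @param path path to a GTF2.2 file with exon (and optionally CDS)
#'   features carrying `transcript_id` and `gene_id` attributes.
#' @return named list of `transcript_model` objects (by transcript_id).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) stop("malformed GTF line ", which(nf != 9)[1],
                         ": expected 9 tab-separated fields")
  m <- do.call(rbind, fields)
  feat <- m[, 3]
  sel <- feat %in% c("exon", "CDS")
  m <- m[sel, , drop = FALSE]
  attr_get <- function(attrs, key) {
    p <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
    vapply(p, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  tx <- attr_get(m[, 9], "transcript_id")
  gid <- attr_get(m[, 9], "gene_id")
  gname <- attr_get(m[, 9], "gene_name")
  if (anyNA(tx) || anyNA(gid))
    stop("GTF feature without transcript_id/gene_id attribute")
  df <- data.frame(
    chrom = m[, 1], feature = m[, 3],
    start = as.integer(m[, 4]) - 1L, end = as.integer(m[, 5]),
    strand = m[, 7], transcript_id = tx, gene_id = gid,
    gene_name = ifelse(is.na(gname), gid, gname),
    stringsAsFactors = FALSE
  )
  models <- lapply(split(df, df$transcript_id), function(d) {
    if (length(unique(d$chrom)) > 1 || length(unique(d$strand)) > 1)
      stop("transcript ", d$transcript_id[1],
           " has features on multiple chromosomes/strands")
    ex <- d[d$feature == "exon", c("start", "end")]
    cds <- d[d$feature == "CDS", ]
    transcript_model(
      transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
      gene_name = d$gene_name[1], chrom = d$chrom[1], strand = d$strand[1],
      exons = ex[order(ex$start), ],
      cds_start = if (nrow(cds)) min(cds$start) else NA_integer_,
      cds_end = if (nrow(cds)) max(cds$end) else NA_integer_
    )
  })
  models[order(names(models))]
}

#' Write transcript models as GTF
#'
#' Emits exon features for every transcript and CDS features for mRNAs,
#' converting back to GTF's 1-based closed convention.
#'
#' @param models list of `transcript_model` objects.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  rows <- lapply(models, function(t) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     t$gene_id, t$transcript_id, t$gene_name)
    ex <- sprintf("%s\tmeripr\texon\t%d\t%d\t.\t%s\t.\t%s",
                  t$chrom, t$exons$start + 1L, t$exons$end, t$strand, attrs)
    if (!is.na(t$cds_start)) {
      b <- c(t$cds_start, t$cds_end)
      cds_ex <- t$exons[t$exons$end > b[1] & t$exons$start < b[2], , drop = FALSE]
      cd <- sprintf("%s\tmeripr\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                    t$chrom, pmax(cds_ex$start, b[1]) + 1L,
                    pmin(cds_ex$end, b[2]), t$strand, attrs)
      c(ex, cd)
    } else ex
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

# GRanges of whole transcript spans, for overlap lookups.
models_span_granges <- function(models) {
  GenomicRanges::GRanges(
    seqnames = vapply(models, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(models, function(t) min(t$exons$start), 0L) + 1L,
      end = vapply(models, function(t) max(t$exons$end), 0L)
    )
  )
}

# TSS genomic position (0-based) of a transcript.
model_tss <- function(t) {
  if (t$strand == "+") min(t$exons$start) else max(t$exons$end) - 1L
}
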