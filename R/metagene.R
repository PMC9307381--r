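
# Metagene peak-frequency profiles.  Each peak is reduced to a single
# representative point (summit when present, else midpoint), mapped into
# transcript coordinates of every overlapping transcript, classified into
# 5'UTR/CDS/3'UTR (mRNA) or the spliced body (lncRNA), and expressed as a
# fraction of that region's length.  Profiles bin the fractions region by
# region and normalize to a density summing to 1.

#' Map peak representative points into transcript regions
#'
#' A peak overlapping `k` transcripts (exonically, at its representative
#' point) contributes total weight 1, split as `1/k` per transcript.
#' Intronic points yield no entry.
#'
#' @param peaks peak table.
#' @param models list of `transcript_model` objects.
#' @return data.frame with columns peak, transcript_id, kind (mRNA/lncRNA),
#'   region (`utr5`, `cds`, `utr3` or `body`), fraction (in `[0, 1)`),
#'   weight.
#' @export
peak_metagene_positions <- function(peaks, models) {
  validate_peaks(peaks)
  empty <- data.frame(peak = character(), transcript_id = character(),
                      kind = character(), region = character(),
                      fraction = numeric(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(peaks) || !length(models)) return(empty)
  pts <- peak_points(peaks)
  spans <- models_span_granges(models)
  qry <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(start = pts + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(qry, spans, ignore.strand = TRUE)
  rows <- list()
  for (i in seq_along(hits)) {
    pi <- S4Vectors::queryHits(hits)[i]
    t <- models[[S4Vectors::subjectHits(hits)[i]]]
    off <- genomic_to_transcript(t, pts[pi])
    if (is.na(off)) next
    if (t$biotype == "mRNA") {
      b <- cds_tx_bounds(t)
      L <- spliced_length(t)
      if (off < b[1]) {
        region <- "utr5"; frac <- off / b[1]
      } else if (off < b[2]) {
        region <- "cds"; frac <- (off - b[1]) / (b[2] - b[1])
      } else {
        region <- "utr3"; frac <- (off - b[2]) / (L - b[2])
      }
    } else {
      region <- "body"; frac <- off / spliced_length(t)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      peak = peaks$name[pi], transcript_id = t$transcript_id,
      kind = t$biotype, region = region, fraction = frac,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  k <- table(df$peak)
  df$weight <- 1 / as.numeric(k[df$peak])
  df
}

#' Build a metagene peak-frequency profile
#'
#' For mRNA the profile has `bins["utr5"] + bins["cds"] + bins["utr3"]` bins
#' (defaults 20/40/40); for lncRNA `n_bins` bins over the spliced body.
#' Each mapped position increments its region-local bin
#' (`floor(fraction * region_bins)`); counts are normalized to a density
#' summing to 1 whenever any peak maps.
#'
#' @param peaks peak table.
#' @param models list of `transcript_model` objects.
#' @param kind `"mRNA"` or `"lncRNA"`.
#' @param bins named integer vector `c(utr5, cds, utr3)` for mRNA.
#' @param n_bins number of lncRNA body bins.
#' @return An object of class `metagene_profile`: list with `kind` and a
#'   data.frame `table` (region, bin, global_bin, density).
#' @export
build_profile <- function(peaks, models, kind = c("mRNA", "lncRNA"),
                          bins = c(utr5 = 20L, cds = 40L, utr3 = 40L),
                          n_bins = 100L) {
  kind <- match.arg(kind)
  pos <- peak_metagene_positions(peaks, models)
  pos <- pos[pos$kind == kind, , drop = FALSE]
  if (kind == "mRNA") {
    stopifnot(all(c("utr5", "cds", "utr3") %in% names(bins)), all(bins >= 1))
    region <- rep(c("utr5", "cds", "utr3"), times = bins[c("utr5", "cds", "utr3")])
    local_bin <- unlist(lapply(bins[c("utr5", "cds", "utr3")], seq_len)) - 1L
    layout <- data.frame(region = region, bin = local_bin,
                         global_bin = seq_along(region) - 1L,
                         stringsAsFactors = FALSE)
  } else {
    stopifnot(n_bins >= 1)
    layout <- data.frame(region = "body", bin = seq_len(n_bins) - 1L,
                         global_bin = seq_len(n_bins) - 1L,
                         stringsAsFactors = FALSE)
  }
  dens <- numeric(nrow(layout))
  if (nrow(pos)) {
    nb <- if (kind == "mRNA") bins[pos$region] else rep(n_bins, nrow(pos))
    b <- pmin(floor(pos$fraction * nb), nb - 1L)
    key <- paste(pos$region, b)
    w <- tapply(pos$weight, key, sum)
    idx <- match(names(w), paste(layout$region, layout$bin))
    dens[idx] <- as.numeric(w)
    dens <- dens / sum(dens)
  }
  layout$density <- dens
  structure(list(kind = kind, table = layout), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile %s, %d bins, mass %.3f>\n", x$kind,
              nrow(x$table), sum(x$table$density)))
  invisible(x)
}

#' Write a metagene profile as TSV
#'
#' Columns: kind, region, bin_index, density.
#'
#' @param profile a `metagene_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(kind = profile$kind, region = profile$table$region,
                   bin_index = profile$table$global_bin,
                   density = sprintf("%.6f", profile$table$density))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
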