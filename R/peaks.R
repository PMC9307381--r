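
# Peak calling and merging.  The caller tiles the genome into fixed windows
# and emits maximal runs of windows whose library-normalized IP/input ratio
# clears a threshold; merging is base-wise (intersection across replicate
# sets within a group, union between groups).

#' Call peaks from IP over input enrichment
#'
#' The genome is tiled into non-overlapping windows of `window` bases.  A
#' window is enriched when
#' `(ip_w / ip_lib) / ((input_w + pseudo) / input_lib) >= min_enrichment`.
#' Maximal runs of adjacent enriched windows whose total length reaches
#' `min_length` are emitted as peaks; the score is the run's mean
#' enrichment and the summit the offset of the center of the
#' max-enrichment window.
#'
#' @param ip,input `coverage_track` objects.
#' @param window window size in bp (>= 1).
#' @param min_enrichment enrichment threshold (> 1).
#' @param min_length minimum peak length in bp.
#' @param pseudo pseudocount added to the input window sum.
#' @return peak table (strand `"."`).
#' @export
call_peaks <- function(ip, input, window = 25L, min_enrichment = 2,
                       min_length = 50L, pseudo = 1) {
  stopifnot(window >= 1, min_enrichment > 1, min_length >= 1, pseudo >= 0)
  if (ip$library_size <= 0 || input$library_size <= 0)
    stop("zero library size")
  chroms <- sort(union(names(ip$values), names(input$values)))
  out <- list()
  for (chrom in chroms) {
    L <- max(length(ip$values[[chrom]]) %||% 0L,
             length(input$values[[chrom]]) %||% 0L)
    if (L == 0) next
    starts <- seq.int(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    ip_w <- interval_sums(ip, chrom, starts, ends)
    in_w <- interval_sums(input, chrom, starts, ends)
    ratio <- (ip_w / ip$library_size) / ((in_w + pseudo) / input$library_size)
    enr <- ratio >= min_enrichment
    r <- rle(enr)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (k in which(r$values)) {
      i <- run_start[k]; j <- run_end[k]
      s <- starts[i]; e <- ends[j]
      if (e - s < min_length) next
      w_best <- i - 1L + which.max(ratio[i:j])
      summit <- (starts[w_best] + ends[w_best]) %/% 2L - s
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = e, score = mean(ratio[i:j]),
        summit = as.integer(summit), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(peak_table(character(), integer(), integer()))
  df <- do.call(rbind, out)
  peak_table(df$chrom, df$start, df$end,
             name = sprintf("peak_%05d", seq_len(nrow(df))),
             score = df$score, strand = ".", summit = df$summit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Give every GRanges in a list the union of all seqlevels, so set
# operations across sets with different chromosome namespaces are silent.
harmonize_seqlevels <- function(grl) {
  levels <- unique(unlist(lapply(grl, function(g)
    GenomeInfoDb::seqlevels(g))))
  lapply(grl, function(g) {
    GenomeInfoDb::seqlevels(g) <- levels
    g
  })
}

#' Base-wise intersection of replicate peak sets within a group
#'
#' Returns the maximal intervals covered by at least one peak in EVERY
#' replicate set (per-base AND), merged to non-overlapping form.
#'
#' @param replicate_peak_sets non-empty list of peak tables.
#' @return peak table of the common regions (strand `"."`).
#' @export
intersect_within_group <- function(replicate_peak_sets) {
  if (!is.list(replicate_peak_sets) || !length(replicate_peak_sets))
    stop("empty replicate set")
  grl <- lapply(replicate_peak_sets, function(p)
    GenomicRanges::reduce(peaks_to_granges(p), ignore.strand = TRUE))
  grl <- harmonize_seqlevels(grl)
  res <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), grl)
  granges_to_peaks(BiocGenerics::sort(res), "common")
}

#' Base-wise union of two groups' peak sets
#'
#' Returns the maximal intervals covered by at least one peak from either
#' group (per-base OR).  Group provenance is recorded as a `|A`, `|B` or
#' `|AB` suffix on the peak name and in a `groups` column.
#'
#' @param groupA_peaks,groupB_peaks peak tables (may be empty).
#' @return peak table of the union regions with a `groups` column.
#' @export
union_between_groups <- function(groupA_peaks, groupB_peaks) {
  ga <- GenomicRanges::reduce(peaks_to_granges(groupA_peaks), ignore.strand = TRUE)
  gb <- GenomicRanges::reduce(peaks_to_granges(groupB_peaks), ignore.strand = TRUE)
  h <- harmonize_seqlevels(list(ga, gb))
  ga <- h[[1]]; gb <- h[[2]]
  u <- BiocGenerics::sort(GenomicRanges::reduce(c(ga, gb), ignore.strand = TRUE))
  res <- granges_to_peaks(u, "union")
  if (nrow(res)) {
    in_a <- IRanges::overlapsAny(u, ga)
    in_b <- IRanges::overlapsAny(u, gb)
    prov <- ifelse(in_a & in_b, "AB", ifelse(in_a, "A", "B"))
    res$groups <- prov
    res$name <- paste0(res$name, "|", prov)
  } else {
    res$groups <- character()
  }
  res
}

#' Count per-sample signal over merged peaks
#'
#' Cell (i, j) is the sum of track j's signal over peak i's interval; no
#' normalization is applied at this stage.
#'
#' @param merged_peaks peak table (typically from [union_between_groups()]).
#' @param tracks list of `coverage_track` objects with group/kind tags.
#' @return An object of class `signal_matrix`: list with `peaks` (the peak
#'   table), `samples` (data.frame sample_id, group, kind, library_size)
#'   and `counts` (matrix, rows = peaks, cols = samples).
#' @export
count_signal <- function(merged_peaks, tracks) {
  validate_peaks(merged_peaks)
  stopifnot(is.list(tracks), length(tracks) >= 1)
  samples <- data.frame(
    sample_id = vapply(tracks, `[[`, "", "sample_id"),
    group = vapply(tracks, `[[`, "", "group"),
    kind = vapply(tracks, `[[`, "", "kind"),
    library_size = vapply(tracks, `[[`, 0, "library_size"),
    stringsAsFactors = FALSE
  )
  counts <- matrix(0, nrow = nrow(merged_peaks), ncol = length(tracks),
                   dimnames = list(merged_peaks$name, samples$sample_id))
  for (j in seq_along(tracks)) {
    for (chrom in unique(merged_peaks$chrom)) {
      sel <- merged_peaks$chrom == chrom
      counts[sel, j] <- interval_sums(tracks[[j]], chrom,
                                      merged_peaks$start[sel],
                                      merged_peaks$end[sel])
    }
  }
  structure(list(peaks = merged_peaks, samples = samples, counts = counts),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix %d peak(s) x %d sample(s)>\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a signal matrix as TSV
#'
#' Header carries sample role tags as `sample|group|kind`.
#'
#' @param mat a `signal_matrix`.
#' @param path output path.
#' @export
write_signal_matrix <- function(mat, path) {
  hdr <- sprintf("%s|%s|%s", mat$samples$sample_id, mat$samples$group,
                 mat$samples$kind)
  df <- data.frame(peak = rownames(mat$counts),
                   chrom = mat$peaks$chrom, start = mat$peaks$start,
                   end = mat$peaks$end, mat$counts, check.names = FALSE)
  names(df)[-(1:4)] <- hdr
  lib_line <- paste(c("#library_size", "", "", "",
                      as.character(mat$samples$library_size)), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lib_line, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
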