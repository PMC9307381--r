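
# Functional-area annotation.  Each peak's representative point is tested
# against every overlapping transcript; among all matching (transcript,
# category) pairs the highest-priority category wins.  Exon/intron ordinals
# are counted in transcript orientation (1st exon = 5'-most).

#' Default functional-category priority (highest first)
#' @export
annotation_categories <- c("five_prime_utr", "three_prime_utr", "first_exon",
                           "other_exon", "first_intron", "other_intron",
                           "distal_intergenic")

# Category of a point within one transcript, or NA when outside its span.
classify_in_transcript <- function(t, pos) {
  ex <- t$exons
  if (pos < min(ex$start) || pos >= max(ex$end)) return(NA_character_)
  off <- genomic_to_transcript(t, pos)
  n_ex <- nrow(ex)
  if (!is.na(off)) {
    if (t$biotype == "mRNA") {
      b <- cds_tx_bounds(t)
      if (off < b[1]) return("five_prime_utr")
      if (off >= b[2]) return("three_prime_utr")
    }
    j <- findInterval(pos, ex$start)           # genomic exon index
    ord <- if (t$strand == "+") j else n_ex + 1L - j
    return(if (ord == 1L) "first_exon" else "other_exon")
  }
  # intronic: between exon j and j+1 in genomic order
  j <- findInterval(pos, ex$start)
  ord <- if (t$strand == "+") j else n_ex - j
  if (ord == 1L) "first_intron" else "other_intron"
}

#' Annotate peaks with a functional category
#'
#' The representative point (summit else midpoint) of each peak is
#' classified against every overlapping transcript; the highest-priority
#' category wins.  Ties within the winning category go to the transcript
#' whose TSS is nearest.  Points overlapping no transcript are
#' `distal_intergenic` with the nearest gene recorded and `distance` the
#' signed bp to that gene's TSS (positive downstream in gene orientation);
#' genic peaks have `distance` 0.
#'
#' @param peaks peak table.
#' @param models list of `transcript_model` objects.
#' @param priority character vector ordering the seven categories, highest
#'   first.
#' @return data.frame with columns peak, category, gene_id, transcript_id,
#'   distance.
#' @export
annotate_peaks <- function(peaks, models,
                           priority = annotation_categories) {
  validate_peaks(peaks)
  stopifnot(setequal(priority, annotation_categories))
  pts <- peak_points(peaks)
  spans <- if (length(models)) models_span_granges(models) else NULL
  tss <- vapply(models, model_tss, 0L)
  strands <- vapply(models, `[[`, "", "strand")
  chroms <- vapply(models, `[[`, "", "chrom")
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    pos <- pts[i]
    cand <- which(chroms == peaks$chrom[i])
    cats <- vapply(cand, function(m) classify_in_transcript(models[[m]], pos),
                   NA_character_)
    hit <- !is.na(cats)
    if (any(hit)) {
      ranks <- match(cats[hit], priority)
      best <- min(ranks)
      winners <- cand[hit][ranks == best]
      if (length(winners) > 1) {
        d <- abs(pos - tss[winners])
        winners <- winners[order(d, names(models)[winners])]
      }
      w <- winners[1]
      out[[i]] <- data.frame(
        peak = peaks$name[i], category = priority[best],
        gene_id = models[[w]]$gene_id,
        transcript_id = models[[w]]$transcript_id,
        distance = 0L, stringsAsFactors = FALSE)
    } else {
      if (length(cand)) {
        d <- abs(pos - tss[cand])
        w <- cand[order(d, names(models)[cand])][1]
        signed <- if (strands[w] == "+") pos - tss[w] else tss[w] - pos
        gene <- models[[w]]$gene_id
        txid <- models[[w]]$transcript_id
      } else {
        signed <- NA_integer_; gene <- NA_character_; txid <- NA_character_
      }
      out[[i]] <- data.frame(
        peak = peaks$name[i], category = "distal_intergenic",
        gene_id = gene, transcript_id = txid,
        distance = as.integer(signed), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(peak = character(), category = character(),
                                      gene_id = character(),
                                      transcript_id = character(),
                                      distance = integer(),
                                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Category proportions of peak annotations
#'
#' @param annotations data.frame from [annotate_peaks()] (>= 1 row).
#' @return named numeric vector over all seven categories, summing to 1.
#' @export
category_proportions <- function(annotations) {
  if (!nrow(annotations)) stop("empty annotation set")
  tab <- table(factor(annotations$category, levels = annotation_categories))
  as.numeric(tab) / sum(tab) -> p
  names(p) <- annotation_categories
  p
}

#' Write peak annotations and proportions as TSV
#' @param annotations data.frame from [annotate_peaks()].
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @param proportions named vector from [category_proportions()].
#' @export
write_proportions <- function(proportions, path) {
  df <- data.frame(category = names(proportions),
                   fraction = sprintf("%.6f", proportions))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
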