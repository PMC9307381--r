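# Brute-force oracles and small constructed fixtures shared across tests.
# Oracles deliberately avoid the code paths they check: interval operations
# are verified per base on explicit logical vectors, coordinate maps by
# enumerating exonic bases, and Fisher tails by lchoose summation.

# ---- interval oracles (per-base, on a finite chromosome) ----

peaks_to_mask <- function(peaks, chrom, len) {
  m <- logical(len)
  sel <- peaks$chrom == chrom
  for (i in which(sel)) m[(peaks$start[i] + 1):peaks$end[i]] <- TRUE
  m
}

mask_to_intervals <- function(mask) {
  r <- rle(mask)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(start = start[r$values], end = end[r$values])
}

random_peak_set <- function(n, chrom = "chr1", len = 1000) {
  start <- sample.int(len - 20L, n, replace = TRUE) - 1L
  width <- sample.int(100L, n, replace = TRUE) + 5L
  end <- pmin(start + width, len)
  peak_table(chrom, start, end, name = sprintf("r%03d", seq_len(n)),
             score = round(runif(n) * 100, 3),
             strand = sample(c("+", "-", "."), n, replace = TRUE))
}

# ---- transcript coordinate oracle ----

# Exonic genomic positions of a transcript, ordered 5'->3'.
enumerate_exonic <- function(t) {
  g <- unlist(lapply(seq_len(nrow(t$exons)),
                     function(i) t$exons$start[i]:(t$exons$end[i] - 1L)))
  if (t$strand == "-") rev(g) else g
}

# mRNA region boundaries from the enumerated base list.
oracle_region <- function(t, pos) {
  bases <- enumerate_exonic(t)
  off <- match(pos, bases) - 1L
  if (is.na(off)) return(NULL)
  if (t$biotype == "lncRNA")
    return(list(region = "body", frac = off / length(bases)))
  cds_bases <- t$cds_start:(t$cds_end - 1L)
  in_cds <- bases %in% cds_bases
  b1 <- which(in_cds)[1] - 1L
  b2 <- max(which(in_cds))
  if (off < b1) list(region = "utr5", frac = off / b1)
  else if (off < b2) list(region = "cds", frac = (off - b1) / (b2 - b1))
  else list(region = "utr3", frac = (off - b2) / (length(bases) - b2))
}

# ---- random transcript generator for property tests ----

random_transcript <- function(id, chrom = "chr1", strand = NULL,
                              biotype = c("mRNA", "lncRNA"), origin = 0L) {
  biotype <- match.arg(biotype)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  n_ex <- sample(1:4, 1)
  widths <- sample(150:400, n_ex, replace = TRUE)
  s <- origin + sample(10:100, 1)
  ex <- data.frame(start = integer(n_ex), end = integer(n_ex))
  for (i in seq_len(n_ex)) {
    ex$start[i] <- s
    ex$end[i] <- s + widths[i]
    s <- ex$end[i] + sample(80:250, 1)
  }
  if (biotype == "mRNA") {
    t0 <- transcript_model(id, paste0("g_", id), chrom, strand, ex)
    L <- spliced_length(t0)
    u5 <- sample(30:(L %/% 4), 1)
    u3 <- sample(30:(L %/% 4), 1)
    cds_tx <- c(u5, L - u3 - 1L)
    cds_g <- range(transcript_to_genomic(t0, cds_tx))
    transcript_model(id, paste0("g_", id), chrom, strand, ex,
                     cds_start = cds_g[1], cds_end = cds_g[2] + 1L)
  } else {
    transcript_model(id, paste0("g_", id), chrom, strand, ex)
  }
}

# ---- IUPAC oracle ----

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_iupac_offsets <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  w <- length(pc)
  L <- length(sc)
  if (L < w) return(integer())
  hits <- integer()
  for (o in 0:(L - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(sc[o + j] %in% IUPAC_SETS[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, o)
  }
  hits
}

# ---- hypergeometric tail by explicit lchoose summation ----

oracle_hyper_tail <- function(k, n_pos, bg_with, n_bg) {
  m <- k + bg_with
  jmax <- min(n_pos, m)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(exp(lchoose(n_pos, j) + lchoose(n_bg, m - j) - lchoose(n_pos + n_bg, m)))
}

# ---- dinucleotide census ----

dinuc_census <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character()))
  table(paste0(ch[-length(ch)], ch[-1]))
}
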