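
# IUPAC motif enrichment with erasure.  Candidates are fixed-width IUPAC
# patterns; per round, each remaining candidate is scored by a one-sided
# Fisher's exact test on the 2x2 table of sequences with/without at least
# one unerased match (positive vs background); the minimum-E candidate is
# emitted, its matched sites are erased (lowercase-masked) in both sets,
# and the loop repeats.  E = P x number of candidate motifs tested.

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

seq_bits <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  b <- unname(c(A = 1L, C = 2L, G = 4L, T = 8L)[ch])
  b[is.na(b)] <- 0L   # lowercase (erased) and unknown bases never match
  b
}

pattern_bits <- function(pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  b <- unname(IUPAC_BITS[ch])
  if (anyNA(b)) stop("illegal IUPAC letter in pattern: ", pattern)
  b
}

#' Find IUPAC pattern matches in a sequence
#'
#' All (possibly overlapping) offsets where every pattern letter's
#' degeneracy set contains the sequence base.  Erased positions
#' (lowercase-masked) never match.
#'
#' @param seq a character string over `ACGT` (lowercase = erased).
#' @param pattern an IUPAC pattern (letters `ACGTRYSWKMBDHVN`).
#' @return data.frame with columns `offset` (0-based) and `match`.
#' @export
iupac_match_sites <- function(seq, pattern) {
  pm <- pattern_bits(pattern)
  w <- length(pm)
  L <- nchar(seq)
  if (L < w) return(data.frame(offset = integer(), match = character(),
                               stringsAsFactors = FALSE))
  sb <- seq_bits(seq)
  ok <- rep(TRUE, L - w + 1L)
  for (j in seq_len(w))
    ok <- ok & bitwAnd(sb[j:(L - w + j)], pm[j]) > 0L
  off <- which(ok) - 1L
  data.frame(offset = off,
             match = if (length(off)) substring(seq, off + 1L, off + w)
                     else character(),
             stringsAsFactors = FALSE)
}

has_iupac_match <- function(seqs, pattern) {
  pm <- pattern_bits(pattern)
  w <- length(pm)
  vapply(seqs, function(seq) {
    L <- nchar(seq)
    if (L < w) return(FALSE)
    sb <- seq_bits(seq)
    ok <- rep(TRUE, L - w + 1L)
    for (j in seq_len(w)) {
      ok <- ok & bitwAnd(sb[j:(L - w + j)], pm[j]) > 0L
      if (!any(ok)) return(FALSE)
    }
    TRUE
  }, NA, USE.NAMES = FALSE)
}

# Presence counts for many candidates at once.  Plain ACGT candidates use a
# k-mer presence scan (one pass per sequence); degenerate candidates fall
# back to bitwise matching.
candidate_presence <- function(seqs, candidates) {
  plain <- grepl("^[ACGT]+$", candidates)
  counts <- integer(length(candidates))
  widths <- nchar(candidates)
  for (w in unique(widths[plain])) {
    idx <- which(plain & widths == w)
    cand_w <- candidates[idx]
    hit <- integer(length(idx))
    for (seq in seqs) {
      L <- nchar(seq)
      if (L < w) next
      ss <- substring(seq, seq_len(L - w + 1L), w:L)
      ss <- unique(ss[!grepl("[^ACGT]", ss)])
      hit <- hit + (cand_w %in% ss)
    }
    counts[idx] <- hit
  }
  for (i in which(!plain))
    counts[i] <- sum(has_iupac_match(seqs, candidates[i]))
  counts
}

#' One-sided Fisher's exact enrichment P (hypergeometric tail)
#'
#' `P[X >= k]` for the 2x2 table with `k` positive sequences containing the
#' motif among `n_pos` positives and `bg_with` among `n_bg` backgrounds.
#'
#' @param pos_with,n_pos,bg_with,n_bg table entries.
#' @return the one-sided enrichment P value.
#' @export
fisher_enrichment_p <- function(pos_with, n_pos, bg_with, n_bg) {
  m <- pos_with + bg_with
  N <- n_pos + n_bg
  stats::phyper(pos_with - 1, m, N - m, n_pos, lower.tail = FALSE)
}

# Lowercase-mask every base covered by a match of `pattern`.
erase_sites <- function(seqs, pattern) {
  w <- nchar(pattern)
  vapply(seqs, function(seq) {
    m <- iupac_match_sites(seq, pattern)
    if (!nrow(m)) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (o in m$offset) {
      span <- (o + 1L):(o + w)
      ch[span] <- tolower(ch[span])
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Default candidate motif universe
#'
#' All 256 DNA 4-mers plus the canonical degenerate m6A consensus patterns
#' (RRAC, DRAC, RRACH, DRACH).
#'
#' @return character vector of IUPAC patterns.
#' @export
default_motif_candidates <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, stringsAsFactors = FALSE)
  kmers <- sort(apply(g[, 4:1], 1, paste, collapse = ""))
  unique(c(kmers, "RRAC", "DRAC", "RRACH", "DRACH"))
}

#' Extract sequences around the top-scoring peaks
#'
#' Peaks are sorted by score descending; the top `top_n` are selected and
#' each sequence spans `[start - flank, end + flank)`, clipped to the
#' chromosome bounds; minus-strand peaks are reverse-complemented.
#'
#' @param peaks peak table.
#' @param genome a `Biostrings::DNAStringSet` (named by chromosome) or a
#'   FASTA path.
#' @param top_n number of peaks to keep (default 5000).
#' @param flank bp added on each side (default 100).
#' @return named character vector of sequences (names = peak names).
#' @export
extract_peak_sequences <- function(peaks, genome, top_n = 5000L, flank = 100L) {
  validate_peaks(peaks)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  miss <- setdiff(unique(peaks$chrom), names(genome))
  if (length(miss)) stop("chromosome missing from FASTA: ",
                         paste(miss, collapse = ", "))
  ord <- order(-peaks$score, peaks$name)
  peaks <- peaks[head(ord, top_n), , drop = FALSE]
  out <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    L <- Biostrings::width(genome[chrom])
    s <- max(peaks$start[i] - flank, 0L)
    e <- min(peaks$end[i] + flank, L)
    sq <- Biostrings::subseq(genome[[chrom]], s + 1L, e)
    if (peaks$strand[i] == "-") sq <- Biostrings::reverseComplement(sq)
    out[i] <- as.character(sq)
  }
  names(out) <- peaks$name
  out
}

#' Discover enriched IUPAC motifs by iterative Fisher testing with erasure
#'
#' Greedy loop: score every remaining candidate by the one-sided Fisher's
#' exact P of its sequence-level presence table (positives vs background);
#' `E = P x |candidates|`.  Emit the minimum-E candidate, erase its matched
#' sites in both sets, repeat up to `max_motifs` motifs or until the best E
#' reaches 1.  `unerased_e` is the E value recomputed on the pristine
#' sequences.  When `bg_seqs` is `NULL` a dinucleotide-shuffled copy of the
#' positives is used (seeded).
#'
#' @param pos_seqs,bg_seqs character vectors of sequences.
#' @param candidates IUPAC patterns to test.
#' @param max_motifs maximum number of motifs to emit.
#' @param shuffle_seed seed for the default background shuffle.
#' @return data.frame of class `motif_results` with columns name, width,
#'   pos_with, pos_total, bg_with, bg_total, p_value, e_value, unerased_e,
#'   rank.
#' @export
discover_motifs <- function(pos_seqs, bg_seqs = NULL,
                            candidates = default_motif_candidates(),
                            max_motifs = 5L, shuffle_seed = 1L) {
  stopifnot(length(candidates) >= 1, length(pos_seqs) >= 1)
  if (is.null(bg_seqs))
    bg_seqs <- dinucleotide_shuffle(pos_seqs, seed = shuffle_seed)
  if (!length(bg_seqs)) stop("empty background sequence set")
  pos_seqs <- toupper(unname(pos_seqs))
  bg_seqs <- toupper(unname(bg_seqs))
  pristine_pos <- pos_seqs; pristine_bg <- bg_seqs
  n_cand <- length(candidates)
  n_pos <- length(pos_seqs); n_bg <- length(bg_seqs)
  remaining <- candidates
  res <- list()
  for (round in seq_len(max_motifs)) {
    if (!length(remaining)) break
    pw <- candidate_presence(pos_seqs, remaining)
    bw <- candidate_presence(bg_seqs, remaining)
    p <- fisher_enrichment_p(pw, n_pos, bw, n_bg)
    e <- p * n_cand
    best <- order(e, remaining)[1]
    if (e[best] >= 1) break
    pat <- remaining[best]
    pw0 <- sum(has_iupac_match(pristine_pos, pat))
    bw0 <- sum(has_iupac_match(pristine_bg, pat))
    unerased_e <- fisher_enrichment_p(pw0, n_pos, bw0, n_bg) * n_cand
    res[[length(res) + 1L]] <- data.frame(
      name = pat, width = nchar(pat),
      pos_with = pw[best], pos_total = n_pos,
      bg_with = bw[best], bg_total = n_bg,
      p_value = p[best], e_value = e[best],
      unerased_e = unerased_e, rank = length(res) + 1L,
      stringsAsFactors = FALSE)
    pos_seqs <- erase_sites(pos_seqs, pat)
    bg_seqs <- erase_sites(bg_seqs, pat)
    remaining <- remaining[-best]
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(name = character(), width = integer(), pos_with = integer(),
               pos_total = integer(), bg_with = integer(), bg_total = integer(),
               p_value = numeric(), e_value = numeric(), unerased_e = numeric(),
               rank = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("motif_results", "data.frame")
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: each sequence is rewritten as a random Eulerian
#' walk over its dinucleotide multigraph, preserving exact mono- and
#' dinucleotide composition.
#'
#' @param seqs character vector of sequences.
#' @param seed RNG seed.
#' @return character vector of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(seqs, seed = 1L) {
  set.seed(seed)
  vapply(seqs, function(seq) {
    ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    L <- length(ch)
    if (L < 3) return(paste(ch, collapse = ""))
    verts <- unique(ch)
    succ <- split(ch[-1], factor(ch[-L], levels = verts))
    last <- ch[L]
    repeat {
      # pick a random last edge for every vertex except the terminal one
      last_edge <- vapply(verts, function(v) {
        if (v == last || !length(succ[[v]])) NA_character_
        else sample(succ[[v]], 1)
      }, "")
      # the chosen last edges must form paths that all reach the terminal
      ok <- TRUE
      for (v in verts) {
        if (v == last || !length(succ[[v]])) next
        seen <- character(); cur <- v
        while (cur != last) {
          if (cur %in% seen || is.na(last_edge[cur])) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[cur]
        }
        if (!ok) break
      }
      if (ok) break
    }
    bags <- lapply(verts, function(v) {
      s <- succ[[v]]
      if (v != last && length(s)) {
        drop <- match(last_edge[v], s)
        s <- s[-drop]
      }
      if (length(s) > 1) s <- sample(s)
      if (v != last && !is.na(last_edge[v])) s <- c(s, last_edge[v])
      s
    })
    names(bags) <- verts
    out <- character(L)
    out[1] <- ch[1]
    cur <- ch[1]
    for (i in 2:L) {
      nxt <- bags[[cur]][1]
      bags[[cur]] <- bags[[cur]][-1]
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Write motif results as TSV
#' @param motifs `motif_results` from [discover_motifs()].
#' @param path output path.
#' @export
write_motifs <- function(motifs, path) {
  out <- motifs
  for (col in c("p_value", "e_value", "unerased_e"))
    out[[col]] <- formatC(out[[col]], digits = 6, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
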