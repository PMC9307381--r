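
# Synthetic-data generator.  Emulates a two-condition MeRIP-Seq design
# (tumor-like group B "SCC25" vs control-like group A "HAEC", one IP and
# one input sample each): a uniform-ACGT genome carrying non-overlapping
# multi-exon transcripts on both strands, m6A peaks placed near the
# CDS/3'UTR junction of mRNAs and uniformly over lncRNA bodies, a planted
# motif at every peak center, Poisson coverage with IP enrichment inside
# peaks, a planted subset of peaks with a between-group fold difference,
# and a term map with one planted enriched term.

#' Simulation configuration
#'
#' Defaults define the package's reference scenario: 200 mRNAs + 50
#' lncRNAs (one planted peak per transcript, ~250 peaks), baseline IP over
#' input enrichment 8x, 20% of peaks differential at 4-fold (half enriched
#' in group B, "up"; half in group A, "down"), peak centers drawn
#' Normal(CDS/3'UTR junction, sd = `stop_codon_bias`) on mRNAs and
#' uniformly on lncRNA bodies, planted motif GGACT, peak widths 100-200 bp
#' (the ~100 nt fragment scale), Poisson coverage noise around a flat
#' per-transcript expression of `expression` per base.
#'
#' @param seed RNG seed.
#' @param n_mrna,n_lncrna transcript counts.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param expression mean input coverage per exonic base.
#' @param peak_enrichment baseline IP/input fold inside peaks.
#' @param frac_differential fraction of peaks with a between-group
#'   difference.
#' @param diff_fold planted fold change of differential peaks.
#' @param stop_codon_bias sd (nt) of mRNA peak-center placement around the
#'   CDS/3'UTR junction.
#' @param motif planted motif sequence.
#' @param peak_width length-2 range of planted peak widths (bp).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 42L, n_mrna = 200L, n_lncrna = 50L,
                              chrom = "chr1", chrom_length = 2000000L,
                              expression = 20, peak_enrichment = 8,
                              frac_differential = 0.2, diff_fold = 4,
                              stop_codon_bias = 50, motif = "GGACT",
                              peak_width = c(100L, 200L)) {
  stopifnot(n_mrna >= 1, n_lncrna >= 0, chrom_length >= 1,
            frac_differential >= 0, frac_differential <= 1, diff_fold > 1,
            peak_enrichment > 0, expression > 0, stop_codon_bias > 0,
            grepl("^[ACGT]+$", motif), length(peak_width) == 2,
            peak_width[1] >= 10, peak_width[2] >= peak_width[1])
  structure(as.list(environment()), class = "simulation_config")
}

# Split a spliced length into n segments each >= min_len.
split_segments <- function(total, n, min_len) {
  if (n == 1) return(total)
  slack <- total - n * min_len
  cuts <- sort(sample.int(slack + 1L, n - 1L, replace = TRUE) - 1L)
  diff(c(0L, cuts, slack)) + min_len
}

#' Simulate a genome and transcript annotation with planted peaks
#'
#' Transcripts are packed left to right with random gaps on random strands;
#' mRNAs have non-empty 5'UTR/CDS/3'UTR, lncRNAs no CDS.  One peak is
#' planted per transcript (center biased to the CDS/3'UTR junction for
#' mRNAs, uniform for lncRNAs; the interval kept within one exon) and the
#' planted motif is written into the genome at every peak center.
#'
#' @param config a `simulation_config`.
#' @return list with `genome` (`DNAStringSet`), `models` (named list of
#'   `transcript_model`), `peaks` (planted-truth data.frame with
#'   differential flags and directions) and `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_tx <- config$n_mrna + config$n_lncrna
  biotypes <- sample(c(rep("mRNA", config$n_mrna),
                       rep("lncRNA", config$n_lncrna)))
  genome <- paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                         replace = TRUE), collapse = "")
  cur <- 1000L
  models <- list()
  truth <- list()
  n_diff <- ceiling(config$frac_differential * n_tx)
  diff_idx <- sample.int(n_tx, n_diff)
  direction <- rep(NA_character_, n_tx)
  direction[diff_idx] <- rep(c("up", "down"), length.out = n_diff)
  for (i in seq_len(n_tx)) {
    bt <- biotypes[i]
    strand <- sample(c("+", "-"), 1)
    if (bt == "mRNA") {
      utr5 <- sample(100:200, 1); cds <- sample(600:1200, 1)
      utr3 <- sample(400:700, 1)
      spliced <- utr5 + cds + utr3
      n_ex <- sample(2:4, 1)
    } else {
      spliced <- sample(500:2000, 1)
      n_ex <- sample(1:min(3L, spliced %/% 250L), 1)
    }
    seg <- split_segments(spliced, n_ex, 200L)
    introns <- if (n_ex > 1) sample(200:800, n_ex - 1L, replace = TRUE) else integer()
    starts <- cur + cumsum(c(0L, seg[-n_ex] + introns))
    exons <- data.frame(start = as.integer(starts),
                        end = as.integer(starts + seg))
    span <- max(exons$end) - cur
    if (max(exons$end) + 1000L > config$chrom_length)
      stop("infeasible packing: chromosome too short for requested transcripts")
    tid <- sprintf("TX%04d", i)
    gid <- sprintf("G%04d", i)
    if (bt == "mRNA") {
      t0 <- transcript_model(tid, gid, config$chrom, strand, exons)
      cds_g <- range(transcript_to_genomic(t0, c(utr5, utr5 + cds - 1L)))
      t <- transcript_model(tid, gid, config$chrom, strand, exons,
                            cds_start = cds_g[1], cds_end = cds_g[2] + 1L)
    } else {
      t <- transcript_model(tid, gid, config$chrom, strand, exons)
    }
    models[[tid]] <- t
    # planted peak
    L <- spliced_length(t)
    if (bt == "mRNA") {
      junction <- utr5 + cds
      c_tx <- round(rnorm(1, junction, config$stop_codon_bias))
      c_tx <- min(max(c_tx, 5L), L - 6L)
    } else {
      c_tx <- sample.int(L - 10L, 1) + 4L
    }
    g <- transcript_to_genomic(t, as.integer(c_tx))
    ex_i <- findInterval(g, exons$start)
    es <- exons$start[ex_i]; ee <- exons$end[ex_i]
    w <- sample(config$peak_width[1]:config$peak_width[2], 1)
    w <- min(w, ee - es)
    ps <- min(max(es, g - w %/% 2L), ee - w)
    truth[[i]] <- data.frame(
      name = sprintf("planted_%04d", i), chrom = config$chrom,
      start = as.integer(ps), end = as.integer(ps + w),
      center = as.integer(g), transcript_id = tid, gene_id = gid,
      biotype = bt, differential = i %in% diff_idx,
      direction = direction[i], stringsAsFactors = FALSE)
    cur <- max(exons$end) + sample(500:1500, 1)
  }
  peaks <- do.call(rbind, truth)
  # write the motif into the genome centered on each peak center
  motif <- config$motif
  half <- nchar(motif) %/% 2L
  for (g in peaks$center)
    substr(genome, g - half + 1L, g - half + nchar(motif)) <- motif
  dna <- Biostrings::DNAStringSet(genome)
  names(dna) <- config$chrom
  list(genome = dna, models = models[order(names(models))], peaks = peaks,
       config = config)
}

#' Simulate IP/input coverage tracks for two groups
#'
#' Input tracks are Poisson noise around a flat per-transcript expression
#' (exonic bases only); IP tracks multiply the mean by the baseline
#' enrichment inside planted peaks.  Each differential peak is additionally
#' scaled by `diff_fold` in one group: "up" peaks in group B (case), "down"
#' peaks in group A (control), planting both call directions.
#'
#' @param config a `simulation_config`.
#' @param annotation result of [simulate_annotation()].
#' @return list with `tracks` (named list of four `coverage_track`:
#'   A_IP, A_input, B_IP, B_input) and `truth` (the planted peak table).
#' @export
simulate_experiment <- function(config, annotation) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  L <- config$chrom_length
  base_lambda <- numeric(L)
  for (t in annotation$models)
    for (j in seq_len(nrow(t$exons)))
      base_lambda[(t$exons$start[j] + 1):t$exons$end[j]] <- config$expression
  pk <- annotation$peaks
  enr_for <- function(group) {
    enr <- numeric(L)   # multiplicative enrichment - 1 == 0 outside peaks
    f <- ifelse(!pk$differential, config$peak_enrichment,
                ifelse(pk$direction == "up",
                       if (group == "B") config$peak_enrichment * config$diff_fold
                       else config$peak_enrichment,
                       if (group == "A") config$peak_enrichment * config$diff_fold
                       else config$peak_enrichment))
    lam <- base_lambda
    for (i in seq_len(nrow(pk)))
      lam[(pk$start[i] + 1):pk$end[i]] <- lam[(pk$start[i] + 1):pk$end[i]] * f[i]
    lam
  }
  make_track <- function(sample_id, group, kind, lam) {
    v <- rpois(L, lam)
    vals <- list(S4Vectors::Rle(as.numeric(v)))
    names(vals) <- config$chrom
    coverage_track(sample_id, vals, group = group, kind = kind)
  }
  tracks <- list(
    A_IP = make_track("HAEC_IP", "A", "IP", enr_for("A")),
    A_input = make_track("HAEC_input", "A", "input", base_lambda),
    B_IP = make_track("SCC25_IP", "B", "IP", enr_for("B")),
    B_input = make_track("SCC25_input", "B", "input", base_lambda)
  )
  list(tracks = tracks, truth = pk)
}

#' Simulate a GMT term map with one planted enriched term
#'
#' Background terms draw members by Bernoulli sampling; the planted term's
#' members are sampled without replacement with weight `enrichment_fold`
#' for study genes and 1 otherwise.
#'
#' @param genes gene universe.
#' @param study_genes designated study genes (over-sampled in the planted
#'   term).
#' @param n_terms total number of terms.
#' @param planted_term_size size of the planted term (>= 1).
#' @param enrichment_fold over-sampling weight of study genes (1 = null).
#' @param seed RNG seed.
#' @param bg_prob Bernoulli membership probability of background terms.
#' @return list with `term_map` (a `term_map`) and `planted_term_id`.
#' @export
simulate_term_map <- function(genes, study_genes, n_terms = 50L,
                              planted_term_size = 40L, enrichment_fold = 10,
                              seed = 9L, bg_prob = 0.05) {
  stopifnot(planted_term_size >= 1, planted_term_size <= length(genes),
            n_terms >= 1, all(study_genes %in% genes))
  set.seed(seed)
  namespaces <- rep(c("BP", "MF", "CC", "pathway"), length.out = n_terms)
  terms <- vector("list", n_terms)
  planted_i <- sample.int(n_terms, 1)
  for (i in seq_len(n_terms)) {
    id <- sprintf("T%03d", i)
    if (i == planted_i) {
      w <- ifelse(genes %in% study_genes, enrichment_fold, 1)
      members <- sample(genes, planted_term_size, prob = w)
    } else {
      repeat {
        members <- genes[runif(length(genes)) < bg_prob]
        if (length(members)) break
      }
    }
    terms[[i]] <- list(term_id = id, namespace = namespaces[i],
                       term_name = sprintf("synthetic term %d", i),
                       genes = members)
  }
  names(terms) <- vapply(terms, `[[`, "", "term_id")
  list(term_map = structure(terms, class = "term_map"),
       planted_term_id = sprintf("T%03d", planted_i))
}
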