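test_that("IUPAC matching handles literal and degenerate patterns", {
  m <- iupac_match_sites("GGACT", "GGAC")
  expect_equal(m$offset, 0L)
  expect_equal(m$match, "GGAC")
  m2 <- iupac_match_sites("AGACT", "RRAC")
  expect_equal(m2$offset, 0L)
  expect_equal(m2$match, "AGAC")
  expect_equal(nrow(iupac_match_sites("AAAA", "GGAC")), 0)
  expect_error(iupac_match_sites("ACGT", "GGAX"), "illegal IUPAC letter")
  # erased (lowercase) positions never match
  expect_equal(nrow(iupac_match_sites("ggact", "GGAC")), 0)
  expect_equal(nrow(iupac_match_sites("GGAcT", "GGAC")), 0)
})

test_that("matching agrees with the per-offset set-membership oracle", {
  set.seed(13)
  letters15 <- names(IUPAC_SETS)
  for (i in 1:100) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1), TRUE),
                 collapse = "")
    pat <- paste(sample(letters15, sample(2:5, 1), TRUE), collapse = "")
    expect_equal(iupac_match_sites(seq, pat)$offset,
                 oracle_iupac_offsets(seq, pat))
  }
})

test_that("Fisher enrichment P equals the hypergeometric summation", {
  # the spec's worked table plus assorted corners
  expect_equal(fisher_enrichment_p(40, 100, 10, 100),
               oracle_hyper_tail(40, 100, 10, 100))
  for (tab in list(c(0, 10, 0, 10), c(10, 10, 0, 10), c(5, 20, 5, 30),
                   c(1, 3, 2, 4))) {
    expect_equal(fisher_enrichment_p(tab[1], tab[2], tab[3], tab[4]),
                 oracle_hyper_tail(tab[1], tab[2], tab[3], tab[4]))
  }
})

test_that("peak sequences are extracted with flanks, clipping and strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), 250), collapse = "")))
  pk <- peak_table("chr1", c(100L, 0L), c(200L, 50L),
                   name = c("hi", "lo"), score = c(10, 1))
  seqs <- extract_peak_sequences(pk, genome, top_n = 5000, flank = 100)
  expect_equal(nchar(seqs[["hi"]]), 300)   # 100 + 100 + 100
  expect_equal(nchar(seqs[["lo"]]), 150)   # clipped at chromosome start
  expect_equal(seqs[["hi"]],
               substr(as.character(genome[[1]]), 1, 300))
  # top_n keeps the highest scores, minus strand reverse-complements
  top1 <- extract_peak_sequences(pk, genome, top_n = 1, flank = 0)
  expect_equal(names(top1), "hi")
  neg <- pk; neg$strand <- "-"
  seqs_neg <- extract_peak_sequences(neg, genome, top_n = 5000, flank = 0)
  expect_equal(seqs_neg[["hi"]], as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqs[["hi"]]))[101:200]))
  expect_error(extract_peak_sequences(peak_table("chrZ", 0L, 10L), genome),
               "chrZ")
})

test_that("discovery recovers a planted motif and obeys the E relations", {
  set.seed(5)
  n <- 100
  mk <- function() paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  pos <- vapply(1:n, function(i) {
    s <- mk()
    at <- sample(1:(nchar(s) - 5), 1)
    paste0(substr(s, 1, at - 1), "GGACT", substr(s, at + 5, nchar(s)))
  }, "")
  bg <- vapply(1:n, function(i) mk(), "")
  cands <- default_motif_candidates()
  res <- discover_motifs(pos, bg, candidates = cands, max_motifs = 4)
  expect_gte(nrow(res), 1)
  # the top motif matches within the planted GGACT context
  expect_gt(nrow(iupac_match_sites("GGACT", res$name[1])), 0)
  # E = P x |candidates| exactly, for every emitted motif
  expect_equal(res$e_value, res$p_value * length(cands))
  # first motif: unerased E equals E exactly (nothing erased yet)
  expect_equal(res$unerased_e[1], res$e_value[1])
  expect_equal(res$rank, seq_len(nrow(res)))
})

test_that("erasure removes all matches of an emitted motif", {
  seqs <- c("AAGGACTT", "GGACGGAC", "TTTTTTTT")
  erased <- meripr:::erase_sites(seqs, "GGAC")
  expect_equal(sum(has_iupac_match <- vapply(
    erased, function(s) nrow(iupac_match_sites(s, "GGAC")) > 0, NA)), 0)
  expect_equal(erased[3], "TTTTTTTT")
  # non-matching bases are untouched
  expect_equal(toupper(erased), toupper(seqs))
})

test_that("no motif is emitted when positives equal the background", {
  set.seed(19)
  seqs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""), "")
  res <- discover_motifs(seqs, seqs, candidates = default_motif_candidates())
  expect_equal(nrow(res), 0)
})

test_that("dinucleotide shuffle preserves the dinucleotide census", {
  set.seed(23)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), "")
  shuf <- dinucleotide_shuffle(seqs, seed = 4)
  for (i in seq_along(seqs)) {
    expect_equal(dinuc_census(shuf[i]), dinuc_census(seqs[i]))
    expect_equal(substr(shuf[i], 1, 1), substr(seqs[i], 1, 1))
    expect_equal(substr(shuf[i], 120, 120), substr(seqs[i], 120, 120))
  }
  # shuffling is seeded and reproducible
  expect_equal(dinucleotide_shuffle(seqs, seed = 4), shuf)
})
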