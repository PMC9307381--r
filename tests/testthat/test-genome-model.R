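test_that("BED lines map to 0-based half-open peaks with defaults", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1\t13.5\t+",
               "chr2\t0\t50"), p)
  peaks <- read_bed(p)
  expect_equal(peaks$chrom, c("chr1", "chr2"))
  expect_equal(peaks$start, c(100L, 0L))
  expect_equal(peaks$end, c(200L, 50L))
  expect_equal(peaks$name[1], "p1")
  expect_equal(peaks$score, c(13.5, 0))
  expect_equal(peaks$strand, c("+", "."))
})

test_that("malformed BED lines raise errors naming the line", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tok", "chr1\t200\t100\tp1"), p)
  expect_error(read_bed(p), "line 2.*end <= start")
  writeLines(c("chr1\tabc\t200"), p)
  expect_error(read_bed(p), "line 1.*non-integer")
  writeLines("chr1\t100", p)
  expect_error(read_bed(p), "fewer than 3 columns")
})

test_that("BED writer/reader round-trip is the identity", {
  set.seed(1)
  peaks <- random_peak_set(50)
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(peaks, p)
  back <- read_bed(p)
  expect_equal(back[, 1:6], peaks[, 1:6])
})

test_that("GTF is shifted to 0-based half-open and biotype follows CDS", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\tCDS\t151\t350\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t501\t700\t.\t-\t.\tgene_id "g2"; transcript_id "t2";'
  ), p)
  models <- read_gtf(p)
  expect_named(models, c("t1", "t2"))
  expect_equal(models$t1$exons, data.frame(start = c(100L, 300L),
                                           end = c(200L, 400L)))
  expect_equal(models$t1$biotype, "mRNA")
  expect_equal(models$t1$cds_start, 150L)
  expect_equal(models$t1$cds_end, 350L)
  expect_equal(models$t2$biotype, "lncRNA")
  # a GTF exon 101..200 and a BED line "100 200" describe the same interval
  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", b)
  bed <- read_bed(b)
  expect_equal(models$t1$exons$end[1] - models$t1$exons$start[1],
               bed$end - bed$start)
})

test_that("transcripts spanning multiple chroms or strands are rejected", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr2\tx\texon\t301\t400\t.\t+\t.\tgene_id "g"; transcript_id "t";'
  ), p)
  expect_error(read_gtf(p), "multiple chromosomes")
})

test_that("overlapping exons within a transcript are rejected", {
  expect_error(transcript_model("t", "g", "chr1", "+",
                                data.frame(start = c(0L, 50L),
                                           end = c(100L, 150L))),
               "overlapping exons")
})

test_that("genomic_to_transcript handles boundaries and introns", {
  t1 <- transcript_model("t1", "g1", "chr1", "+",
                         data.frame(start = 100L, end = 200L))
  expect_equal(genomic_to_transcript(t1, 100), 0L)
  t2 <- transcript_model("t2", "g2", "chr1", "+",
                         data.frame(start = c(100L, 250L),
                                    end = c(150L, 300L)))
  expect_equal(genomic_to_transcript(t2, 250), 50L)
  expect_true(is.na(genomic_to_transcript(t2, 200)))  # intronic
  expect_true(is.na(genomic_to_transcript(t2, 50)))   # outside
})

test_that("transcript offsets equal the enumerated exonic-base index", {
  set.seed(101)
  for (rep in 1:20) {
    t <- random_transcript(sprintf("t%02d", rep),
                           biotype = sample(c("mRNA", "lncRNA"), 1))
    bases <- enumerate_exonic(t)
    pos <- sample(bases, min(10, length(bases)))
    expect_equal(genomic_to_transcript(t, pos),
                 as.integer(match(pos, bases) - 1L))
    # inverse round-trip on every sampled exonic position
    off <- genomic_to_transcript(t, pos)
    expect_equal(transcript_to_genomic(t, off), as.integer(pos))
  }
})

test_that("GTF writer/reader round-trips generator models", {
  set.seed(7)
  models <- lapply(1:5, function(i)
    random_transcript(sprintf("t%d", i), origin = i * 3000L,
                      biotype = if (i %% 2) "mRNA" else "lncRNA"))
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  p <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(models, p)
  back <- read_gtf(p)
  expect_setequal(names(back), names(models))
  for (id in names(models)) {
    expect_equal(back[[id]]$exons, models[[id]]$exons)
    expect_equal(back[[id]]$biotype, models[[id]]$biotype)
    expect_equal(back[[id]]$cds_start, models[[id]]$cds_start)
    expect_equal(back[[id]]$cds_end, models[[id]]$cds_end)
    expect_equal(back[[id]]$strand, models[[id]]$strand)
  }
})
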