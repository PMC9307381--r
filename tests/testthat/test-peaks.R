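flat_track <- function(v, sample_id = "s", chrom = "chr1", ...) {
  coverage_track(sample_id, setNames(list(v), chrom), ...)
}

test_that("identical IP and input yield no peaks", {
  v <- rep(5, 1000)
  expect_equal(nrow(call_peaks(flat_track(v, "ip"), flat_track(v, "in"),
                               window = 25, min_enrichment = 2,
                               min_length = 50)), 0)
})

test_that("a planted enriched region is recovered as one containing peak", {
  v <- rep(5, 1000)
  ip <- v
  ip[401:550] <- 40   # 8x excess over 150 bp
  peaks <- call_peaks(flat_track(ip, "ip"), flat_track(v, "in"),
                      window = 25, min_enrichment = 2, min_length = 50)
  expect_equal(nrow(peaks), 1)
  expect_lte(peaks$start, 400)
  expect_gte(peaks$end, 550)
  expect_gt(peaks$score, 2)
  expect_true(peaks$summit >= 0 && peaks$summit < peaks$end - peaks$start)
})

test_that("zero library size is an error", {
  z <- flat_track(rep(0, 100), "z")
  ok <- flat_track(rep(1, 100), "ok")
  expect_error(call_peaks(z, ok), "zero library size")
  expect_error(call_peaks(ok, z), "zero library size")
})

test_that("intersection of a single replicate set merges its peaks", {
  p <- peak_table("chr1", c(0L, 50L, 300L), c(100L, 150L, 400L))
  res <- intersect_within_group(list(p))
  expect_equal(res$start, c(0L, 300L))
  expect_equal(res$end, c(150L, 400L))
  expect_true(all(res$strand == "."))
})

test_that("two-replicate intersection gives the textbook overlap", {
  a <- peak_table("chr1", 0L, 100L)
  b <- peak_table("chr1", 50L, 150L)
  res <- intersect_within_group(list(a, b))
  expect_equal(res$start, 50L)
  expect_equal(res$end, 100L)
  expect_error(intersect_within_group(list()), "empty replicate set")
})

test_that("union covers both groups and records provenance", {
  a <- peak_table("chr1", 0L, 100L)
  b <- peak_table("chr1", 50L, 150L)
  res <- union_between_groups(a, b)
  expect_equal(res$start, 0L)
  expect_equal(res$end, 150L)
  expect_equal(res$groups, "AB")
  only_a <- union_between_groups(a, peak_table(character(), integer(), integer()))
  expect_equal(only_a$start, 0L)
  expect_equal(only_a$end, 100L)
  expect_equal(only_a$groups, "A")
})

test_that("merges match the per-base boolean oracle on random instances", {
  set.seed(7)
  for (i in 1:100) {
    a <- random_peak_set(sample(1:8, 1))
    b <- random_peak_set(sample(1:8, 1))
    ma <- peaks_to_mask(a, "chr1", 1000)
    mb <- peaks_to_mask(b, "chr1", 1000)
    got_i <- intersect_within_group(list(a, b))
    expect_equal(got_i[, c("start", "end")],
                 mask_to_intervals(ma & mb), ignore_attr = TRUE)
    got_u <- union_between_groups(a, b)
    expect_equal(got_u[, c("start", "end")],
                 mask_to_intervals(ma | mb), ignore_attr = TRUE)
    # intersect result is base-wise contained in the union result
    mi <- if (nrow(got_i)) peaks_to_mask(got_i, "chr1", 1000) else logical(1000)
    mu <- if (nrow(got_u)) peaks_to_mask(got_u, "chr1", 1000) else logical(1000)
    expect_true(all(!mi | mu))
  }
})

test_that("merge outputs are sorted, non-overlapping and idempotent", {
  set.seed(17)
  a <- random_peak_set(10)
  b <- random_peak_set(10)
  u <- union_between_groups(a, b)
  expect_false(is.unsorted(u$start))
  expect_true(all(u$start[-1] > u$end[-nrow(u)] - 1))
  again <- intersect_within_group(list(u))
  expect_equal(again[, c("chrom", "start", "end")],
               u[, c("chrom", "start", "end")], ignore_attr = TRUE)
})

test_that("count_signal sums coverage over peaks", {
  tr <- flat_track(rep(1, 500), "c", group = "A", kind = "IP")
  p <- peak_table("chr1", 100L, 180L)
  m <- count_signal(p, list(tr))
  expect_equal(unname(m$counts[1, 1]), 80)
  # additivity: disjoint peaks partitioning a region conserve total mass
  v <- runif(500)
  tr2 <- flat_track(v, "r")
  parts <- peak_table("chr1", c(0L, 200L, 350L), c(200L, 350L, 500L))
  m2 <- count_signal(parts, list(tr2))
  expect_equal(sum(m2$counts), sum(v))
})

test_that("count_signal matches the per-base summation oracle", {
  set.seed(7)
  for (i in 1:50) {
    v <- rpois(800, 3)
    tr <- flat_track(v, "t")
    p <- random_peak_set(4, len = 800)
    m <- count_signal(p, list(tr))
    manual <- vapply(seq_len(4), function(j)
      sum(v[(p$start[j] + 1):p$end[j]]), 0)
    expect_equal(unname(m$counts[, 1]), manual)
  }
})

test_that("count_signal is additive under peak splits", {
  v <- rpois(400, 5)
  tr <- flat_track(v, "t")
  whole <- peak_table("chr1", 50L, 350L)
  halves <- peak_table("chr1", c(50L, 201L - 1L), c(200L, 350L))
  expect_equal(sum(count_signal(halves, list(tr))$counts),
               sum(count_signal(whole, list(tr))$counts))
})

test_that("missing chromosomes in a track count as zero", {
  tr <- flat_track(rep(2, 100), "t")
  p <- peak_table(c("chr1", "chrX"), c(0L, 0L), c(50L, 50L))
  m <- count_signal(p, list(tr))
  expect_equal(unname(m$counts[, 1]), c(100, 0))
})

test_that("bedGraph writer/reader round-trips a coverage track", {
  set.seed(3)
  v <- rpois(300, 1)
  tr <- flat_track(v, "s1", group = "A", kind = "input")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_bedgraph(tr, p)
  back <- read_bedgraph(p, "s1", group = "A", kind = "input")
  expect_equal(as.numeric(back$values$chr1),
               as.numeric(tr$values$chr1)[1:length(back$values$chr1)])
  expect_equal(back$library_size, tr$library_size)
})
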