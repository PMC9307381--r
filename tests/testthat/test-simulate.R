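small_config <- function(seed = 42L, ...)
  simulation_config(seed = seed, n_mrna = 20L, n_lncrna = 5L,
                    chrom_length = 300000L, ...)

test_that("transcript counts and biotypes follow the configuration", {
  cfg <- simulation_config(seed = 42L, n_mrna = 5L, n_lncrna = 3L,
                           chrom_length = 100000L)
  ann <- simulate_annotation(cfg)
  expect_length(ann$models, 8)
  bt <- table(vapply(ann$models, `[[`, "", "biotype"))
  expect_equal(unname(bt[c("mRNA", "lncRNA")]), c(5L, 3L), ignore_attr = TRUE)
  expect_equal(nrow(ann$peaks), 8)
})

test_that("the same seed reproduces byte-identical FASTA and GTF", {
  cfg <- small_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    ann <- simulate_annotation(cfg)
    Biostrings::writeXStringSet(ann$genome, file.path(d, "g.fa"))
    write_gtf(ann$models, file.path(d, "a.gtf"))
  }
  expect_equal(unname(tools::md5sum(file.path(d1, "g.fa"))),
               unname(tools::md5sum(file.path(d2, "g.fa"))))
  expect_equal(unname(tools::md5sum(file.path(d1, "a.gtf"))),
               unname(tools::md5sum(file.path(d2, "a.gtf"))))
})

test_that("emitted GTF re-reads to the generator's in-memory models", {
  ann <- simulate_annotation(small_config())
  p <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann$models, p)
  back <- read_gtf(p)
  expect_setequal(names(back), names(ann$models))
  for (id in names(back)) {
    expect_equal(back[[id]]$exons, ann$models[[id]]$exons)
    expect_equal(back[[id]]$biotype, ann$models[[id]]$biotype)
    expect_equal(back[[id]]$cds_start, ann$models[[id]]$cds_start)
    expect_equal(back[[id]]$strand, ann$models[[id]]$strand)
  }
})

test_that("planted intervals are exonic and carry the planted motif", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  g <- as.character(ann$genome[[1]])
  for (i in seq_len(nrow(ann$peaks))) {
    pk <- ann$peaks[i, ]
    t <- ann$models[[pk$transcript_id]]
    covered <- any(t$exons$start <= pk$start & t$exons$end >= pk$end)
    expect_true(covered)
    ctr <- pk$center
    expect_equal(substr(g, ctr - 1, ctr + 3), cfg$motif)
  }
  expect_equal(sum(ann$peaks$differential), ceiling(0.2 * 25))
})

test_that("a null simulation (enrichment 1) calls no peaks", {
  cfg <- small_config(peak_enrichment = 1, frac_differential = 0)
  ann <- simulate_annotation(cfg)
  exp <- simulate_experiment(cfg, ann)
  pk <- call_peaks(exp$tracks$A_IP, exp$tracks$A_input,
                   window = 25, min_enrichment = 2, min_length = 50)
  expect_equal(nrow(pk), 0)
})

test_that("simulated IP/input ratio inside stable peaks tracks the fold", {
  cfg <- simulation_config(seed = 7L, n_mrna = 60L, n_lncrna = 10L,
                           chrom_length = 600000L)
  ann <- simulate_annotation(cfg)
  exp <- simulate_experiment(cfg, ann)
  stable <- exp$truth[!exp$truth$differential, ]
  expect_gte(nrow(stable), 50)
  ip_rle <- exp$tracks$A_IP$values[[1]]
  in_rle <- exp$tracks$A_input$values[[1]]
  ip <- vapply(seq_len(nrow(stable)), function(i)
    sum(as.numeric(ip_rle[(stable$start[i] + 1):stable$end[i]])), 0)
  inp <- vapply(seq_len(nrow(stable)), function(i)
    sum(as.numeric(in_rle[(stable$start[i] + 1):stable$end[i]])), 0)
  expect_lt(abs(mean(ip / inp) - cfg$peak_enrichment) / cfg$peak_enrichment,
            0.1)
})

test_that("term map plants one enriched term and round-trips as GMT", {
  genes <- sprintf("g%03d", 1:200)
  study <- genes[1:30]
  tm <- simulate_term_map(genes, study, n_terms = 20, planted_term_size = 30,
                          enrichment_fold = 10, seed = 9)
  expect_true(tm$planted_term_id %in% names(tm$term_map))
  planted <- tm$term_map[[tm$planted_term_id]]
  expect_length(planted$genes, 30)
  # planted members are drawn from the study set well above the null
  # rate of 30/200 = 0.15 (without-replacement sampling depletes the
  # 30-gene study pool, so the fraction sits below the naive 10x odds)
  expect_gt(mean(planted$genes %in% study), 2 * 30 / 200)
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(tm$term_map, p)
  back <- read_gmt(p)
  expect_equal(lapply(back, `[[`, "genes"),
               lapply(unclass(tm$term_map), `[[`, "genes"))
  expect_error(simulate_term_map(genes, study, planted_term_size = 0),
               "planted_term_size")
})

test_that("null term maps (fold 1) do not systematically top-rank the plant", {
  genes <- sprintf("g%03d", 1:200)
  study <- genes[1:30]
  ranks <- vapply(1:20, function(s) {
    tm <- simulate_term_map(genes, study, n_terms = 50, planted_term_size = 30,
                            enrichment_fold = 1, seed = 1000L + s)
    res <- fisher_enrichment(study, tm$term_map, universe = genes)
    match(tm$planted_term_id, res$term_id)
  }, 0L)
  expect_gt(median(ranks), 5)   # not in the top 10% of 50 terms
})
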