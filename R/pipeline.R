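
# End-to-end orchestration: simulate -> call -> merge -> count -> escore ->
# metagene -> annotate -> motif -> enrich.  Every stage writes its outputs
# (to a ".partial" name, renamed on stage completion) before the next stage
# starts; a manifest records file, stage and checksum, and a log records
# parameters, seed and per-stage record counts.

#' Pipeline configuration
#'
#' Bundles the simulation scenario with every stage parameter: the
#' differential thresholds (`t_mean = 6`, `t_diff = 1`), the motif-surface
#' parameters (`top_n = 5000` peaks, `flank = 100` bp), the peak caller
#' settings, metagene bins, the candidate motif universe and the FDR
#' threshold (`fdr_alpha = 0.05`).
#'
#' @param seed master seed; seeds every stage's randomness.
#' @param sim a `simulation_config` (its seed is overridden by `seed`).
#' @param window,min_enrichment,min_length,pseudo peak-caller parameters.
#' @param t_mean,t_diff differential-call thresholds.
#' @param top_n,flank motif sequence-extraction parameters.
#' @param mrna_bins,lnc_bins metagene bin layout.
#' @param candidates candidate motif patterns.
#' @param max_motifs maximum motifs to report.
#' @param n_terms,planted_term_size,enrichment_fold term-map scenario.
#' @param fdr_alpha FDR significance threshold.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42L, sim = simulation_config(seed = seed),
                            window = 25L, min_enrichment = 2,
                            min_length = 50L, pseudo = 1,
                            t_mean = 6, t_diff = 1,
                            top_n = 5000L, flank = 100L,
                            mrna_bins = c(utr5 = 20L, cds = 40L, utr3 = 40L),
                            lnc_bins = 100L,
                            candidates = default_motif_candidates(),
                            max_motifs = 5L,
                            n_terms = 50L, planted_term_size = 40L,
                            enrichment_fold = 10,
                            fdr_alpha = 0.05) {
  stopifnot(t_mean > 0, t_diff > 0, top_n >= 1, flank >= 0,
            fdr_alpha > 0, fdr_alpha <= 1)
  sim$seed <- as.integer(seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes all stages in order, writing plain-text outputs into `out_dir`:
#' genome FASTA, GTF, planted truth, per-group called/merged peaks, union
#' peaks, signal matrix, volcano table, differential BED, mRNA and lncRNA
#' metagene profiles, peak annotations and proportions, motif table, term
#' map and enrichment table, plus `manifest.tsv` (file, stage, md5) and
#' `run.log`.  Any stage failure aborts with the stage name; files of the
#' failing stage keep a `.partial` suffix.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) list with `manifest`, `out_dir` and the key
#'   in-memory results (`truth`, `records`, `profiles`, `annotations`,
#'   `motifs`, `enrichment`, `planted_term_id`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(stage, ...) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage, sprintf(...))
    writeLines(line, log_con)
    message(line)
  }
  manifest <- data.frame(file = character(), stage = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  stage_files <- function(stage, writer) {
    # writer receives a function emit(filename, write_fun); files are
    # written as .partial and renamed when the whole stage succeeds
    written <- character()
    emit <- function(filename, write_fun) {
      p <- file.path(out_dir, paste0(filename, ".partial"))
      write_fun(p)
      written <<- c(written, filename)
      invisible(p)
    }
    res <- tryCatch(writer(emit), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    for (f in written) {
      file.rename(file.path(out_dir, paste0(f, ".partial")),
                  file.path(out_dir, f))
      manifest <<- rbind(manifest, data.frame(
        file = f, stage = stage,
        md5 = unname(tools::md5sum(file.path(out_dir, f))),
        stringsAsFactors = FALSE))
    }
    res
  }

  logmsg("init", "seed=%d t_mean=%g t_diff=%g top_n=%d flank=%d",
         config$seed, config$t_mean, config$t_diff, config$top_n,
         config$flank)

  ## simulate
  sim <- stage_files("simulate", function(emit) {
    ann <- simulate_annotation(config$sim)
    exp <- simulate_experiment(config$sim, ann)
    emit("genome.fa", function(p) Biostrings::writeXStringSet(ann$genome, p))
    emit("annotation.gtf", function(p) write_gtf(ann$models, p))
    emit("truth_peaks.tsv", function(p)
      write.table(exp$truth, p, sep = "\t", quote = FALSE, row.names = FALSE))
    list(ann = ann, exp = exp)
  })
  logmsg("simulate", "%d transcripts, %d planted peaks (%d differential)",
         length(sim$ann$models), nrow(sim$exp$truth),
         sum(sim$exp$truth$differential))

  ## call peaks per group, merge within group
  tracks <- sim$exp$tracks
  merged <- stage_files("callpeaks", function(emit) {
    pa <- call_peaks(tracks$A_IP, tracks$A_input, config$window,
                     config$min_enrichment, config$min_length, config$pseudo)
    pb <- call_peaks(tracks$B_IP, tracks$B_input, config$window,
                     config$min_enrichment, config$min_length, config$pseudo)
    ma <- intersect_within_group(list(pa))
    mb <- intersect_within_group(list(pb))
    emit("peaks_groupA.bed", function(p) write_bed(ma, p))
    emit("peaks_groupB.bed", function(p) write_bed(mb, p))
    list(A = ma, B = mb)
  })
  logmsg("callpeaks", "group A: %d peaks; group B: %d peaks",
         nrow(merged$A), nrow(merged$B))

  ## union between groups
  union_peaks <- stage_files("merge", function(emit) {
    u <- union_between_groups(merged$A, merged$B)
    emit("union_peaks.bed", function(p) write_bed(u, p))
    u
  })
  logmsg("merge", "%d union peaks", nrow(union_peaks))

  ## count signal
  mat <- stage_files("count", function(emit) {
    m <- count_signal(union_peaks, tracks)
    emit("signal_matrix.tsv", function(p) write_signal_matrix(m, p))
    m
  })

  ## differential call
  records <- stage_files("diff", function(emit) {
    r <- call_differential(mat, t_mean = config$t_mean,
                           t_diff = config$t_diff, pseudo = config$pseudo)
    emit("volcano.tsv", function(p) volcano_table(r, p))
    emit("differential.bed", function(p) write_differential_bed(r, p))
    r
  })
  logmsg("diff", "%d up, %d down, %d ns", sum(records$call == "up"),
         sum(records$call == "down"), sum(records$call == "ns"))

  ## metagene
  profiles <- stage_files("metagene", function(emit) {
    pm <- build_profile(union_peaks, sim$ann$models, "mRNA",
                        bins = config$mrna_bins)
    pl <- build_profile(union_peaks, sim$ann$models, "lncRNA",
                        n_bins = config$lnc_bins)
    emit("metagene_mrna.tsv", function(p) write_profile(pm, p))
    emit("metagene_lncrna.tsv", function(p) write_profile(pl, p))
    list(mRNA = pm, lncRNA = pl)
  })

  ## annotate
  annotations <- stage_files("annotate", function(emit) {
    a <- annotate_peaks(union_peaks, sim$ann$models)
    props <- category_proportions(a)
    emit("peak_annotation.tsv", function(p) write_annotations(a, p))
    emit("category_proportions.tsv", function(p) write_proportions(props, p))
    a
  })

  ## motif
  motifs <- stage_files("motif", function(emit) {
    seqs <- extract_peak_sequences(union_peaks, sim$ann$genome,
                                   top_n = config$top_n, flank = config$flank)
    m <- discover_motifs(seqs, bg_seqs = NULL,
                         candidates = config$candidates,
                         max_motifs = config$max_motifs,
                         shuffle_seed = config$seed)
    emit("motifs.tsv", function(p) write_motifs(m, p))
    m
  })
  logmsg("motif", "%d motifs discovered%s", nrow(motifs),
         if (nrow(motifs)) paste0(" (top: ", motifs$name[1], ")") else "")

  ## enrichment
  enr <- stage_files("enrich", function(emit) {
    genes <- sort(unique(vapply(sim$ann$models, `[[`, "", "gene_id")))
    study <- sort(unique(annotations$gene_id[
      annotations$peak %in% records$peak_id[records$call != "ns"] &
        !is.na(annotations$gene_id)]))
    tm <- simulate_term_map(genes, study_genes = study,
                            n_terms = config$n_terms,
                            planted_term_size = config$planted_term_size,
                            enrichment_fold = config$enrichment_fold,
                            seed = config$seed + 2L)
    study <- intersect(study, genes)
    res <- if (length(study)) {
      fisher_enrichment(study, tm$term_map, universe = genes)
    } else {
      # no differential genes (e.g. degenerate thresholds): empty table
      structure(data.frame(term_id = character(), term_name = character(),
                           namespace = character(), k = integer(),
                           K = integer(), n = integer(), N = integer(),
                           p_value = numeric(), fdr = numeric(),
                           rich_factor = numeric(), stringsAsFactors = FALSE),
                class = c("geneset_results", "data.frame"))
    }
    emit("term_map.gmt", function(p) write_gmt(tm$term_map, p))
    emit("enrichment.tsv", function(p) write_enrichment(res, p))
    list(results = res, planted_term_id = tm$planted_term_id,
         study = study)
  })
  logmsg("enrich", "%d terms tested, %d with FDR < %g (planted %s)",
         nrow(enr$results), sum(enr$results$fdr < config$fdr_alpha),
         config$fdr_alpha, enr$planted_term_id)

  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  logmsg("done", "%d output files", nrow(manifest))

  invisible(list(manifest = manifest, out_dir = out_dir,
                 truth = sim$exp$truth, models = sim$ann$models,
                 genome = sim$ann$genome, union_peaks = union_peaks,
                 matrix = mat, records = records, profiles = profiles,
                 annotations = annotations, motifs = motifs,
                 enrichment = enr$results,
                 planted_term_id = enr$planted_term_id,
                 study_genes = enr$study))
}
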