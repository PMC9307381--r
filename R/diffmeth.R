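
# E-score differential methylation.  The E-score of a peak within a group is
# the library-normalized IP over input enrichment ratio (replicates pooled
# by summing signals before the ratio).  A peak is called differential when
# the mean E-score of the two groups clears t_mean AND the log2 ratio of
# the group E-scores clears t_diff in magnitude.

#' Compute an E-score (enrichment score)
#'
#' `((ip_signal + pseudo) / ip_lib) / ((input_signal + pseudo) / input_lib)`,
#' a library-normalized linear enrichment ratio.  Vectorized.
#'
#' @param ip_signal,input_signal summed signal over the peak interval
#'   (replicates pooled by summing).
#' @param ip_lib,input_lib library sizes (> 0).
#' @param pseudo pseudocount (> 0).
#' @return numeric E-score(s), >= 0.
#' @export
compute_escore <- function(ip_signal, input_signal, ip_lib, input_lib,
                           pseudo = 1) {
  vals <- c(ip_signal, input_signal, ip_lib, input_lib, pseudo)
  if (any(!is.finite(vals))) stop("non-finite inputs to compute_escore")
  stopifnot(all(ip_lib > 0), all(input_lib > 0), pseudo > 0)
  ((ip_signal + pseudo) / ip_lib) / ((input_signal + pseudo) / input_lib)
}

#' Call differential methylation from a signal matrix
#'
#' Per peak, group A and B E-scores are computed from pooled IP and input
#' signals; `call == "up"` iff `mean_e > t_mean` and `log2_diff > t_diff`;
#' `"down"` iff `mean_e > t_mean` and `log2_diff < -t_diff`; else `"ns"`.
#' `log2_diff = log2(e_b / e_a)` with group A the control.
#'
#' @param mat a `signal_matrix` with >= 1 IP and >= 1 input sample per group.
#' @param t_mean mean E-score gate (default 6).
#' @param t_diff log2 difference gate (default 1).
#' @param pseudo pseudocount for the E-score.
#' @param group_a,group_b group labels (default the two sorted labels in
#'   `mat$samples$group`, A = control, B = case).
#' @return data.frame of class `escore_records`, one row per peak, sorted
#'   up, down, ns and by `|log2_diff|` descending within each call.
#' @export
call_differential <- function(mat, t_mean = 6, t_diff = 1, pseudo = 1,
                              group_a = NULL, group_b = NULL) {
  stopifnot(inherits(mat, "signal_matrix"), t_mean >= 0, t_diff >= 0)
  s <- mat$samples
  groups <- sort(unique(s$group))
  if (is.null(group_a)) group_a <- groups[1]
  if (is.null(group_b)) group_b <- setdiff(groups, group_a)[1]
  pool <- function(g, k) {
    sel <- s$group == g & s$kind == k
    if (!any(sel)) stop("configuration error: group ", g, " lacks ", k,
                        " samples")
    list(signal = rowSums(mat$counts[, sel, drop = FALSE]),
         lib = sum(s$library_size[sel]))
  }
  a_ip <- pool(group_a, "IP"); a_in <- pool(group_a, "input")
  b_ip <- pool(group_b, "IP"); b_in <- pool(group_b, "input")
  e_a <- compute_escore(a_ip$signal, a_in$signal, a_ip$lib, a_in$lib, pseudo)
  e_b <- compute_escore(b_ip$signal, b_in$signal, b_ip$lib, b_in$lib, pseudo)
  mean_e <- (e_a + e_b) / 2
  log2_diff <- log2(e_b / e_a)
  call <- rep("ns", length(e_a))
  call[mean_e > t_mean & log2_diff > t_diff] <- "up"
  call[mean_e > t_mean & log2_diff < -t_diff] <- "down"
  rec <- data.frame(
    peak_id = mat$peaks$name, chrom = mat$peaks$chrom,
    start = mat$peaks$start, end = mat$peaks$end,
    e_a = e_a, e_b = e_b, mean_e = mean_e, log2_diff = log2_diff,
    call = call, stringsAsFactors = FALSE
  )
  ord <- order(match(rec$call, c("up", "down", "ns")), -abs(rec$log2_diff),
               rec$peak_id)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("escore_records", "data.frame")
  rec
}

#' Volcano table of E-score records
#'
#' Columns: `peak_id`, `mean_e`, `log2_diff`, `call`, in the ordering of
#' [call_differential()].  When `path` is given the table is written as TSV
#' with 6-decimal floats.
#'
#' @param records `escore_records` from [call_differential()].
#' @param path optional output path.
#' @return the volcano data.frame, invisibly when written.
#' @export
volcano_table <- function(records, path = NULL) {
  df <- data.frame(peak_id = records$peak_id,
                   mean_e = records$mean_e,
                   log2_diff = records$log2_diff,
                   call = records$call, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    out <- df
    out$mean_e <- sprintf("%.6f", out$mean_e)
    out$log2_diff <- sprintf("%.6f", out$log2_diff)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Write differential peaks as BED6
#'
#' Only up/down peaks are emitted; the name carries a `.up`/`.down` suffix
#' and the score is `log2_diff`.
#'
#' @param records `escore_records`.
#' @param path output path.
#' @export
write_differential_bed <- function(records, path) {
  d <- records[records$call != "ns", , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s.%s\t%.6f\t.", d$chrom, d$start, d$end,
                   d$peak_id, d$call, d$log2_diff)
  writeLines(lines, path)
  invisible(path)
}
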