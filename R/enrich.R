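
# Fisher's exact gene-set enrichment with BH-FDR and rich factor.  Term
# maps are flat GMT-style sets (no ontology DAG propagation); the universe
# defaults to all genes carrying at least one term annotation.

#' Read a GMT-style term map
#'
#' Each line: term_id, description, then tab-separated gene ids.  The
#' description may be `namespace|term_name` (namespace one of BP, MF, CC,
#' pathway); a bare namespace, or free text (then namespace defaults to
#' `pathway`).
#'
#' @param path input path.
#' @return An object of class `term_map`: list of terms, each a list with
#'   `term_id`, `namespace`, `term_name`, `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  terms <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line ", i, ": fewer than 3 fields")
    desc <- f[2]
    if (grepl("|", desc, fixed = TRUE)) {
      parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
      ns <- parts[1]; nm <- paste(parts[-1], collapse = "|")
    } else if (desc %in% c("BP", "MF", "CC", "pathway")) {
      ns <- desc; nm <- f[1]
    } else {
      ns <- "pathway"; nm <- desc
    }
    list(term_id = f[1], namespace = ns, term_name = nm,
         genes = unique(f[-(1:2)]))
  })
  names(terms) <- vapply(terms, `[[`, "", "term_id")
  structure(terms, class = "term_map")
}

#' Write a term map as GMT
#' @param term_map a `term_map`.
#' @param path output path.
#' @export
write_gmt <- function(term_map, path) {
  lines <- vapply(term_map, function(t)
    paste(c(t$term_id, paste(t$namespace, t$term_name, sep = "|"), t$genes),
          collapse = "\t"), "")
  writeLines(unname(lines), path)
  invisible(path)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort P ascending, `adj_i = min_{j >= i} p_j * m / j`,
#' capped at 1, returned in input order.
#'
#' @param p_values numeric vector of P values in `[0, 1]`.
#' @return adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values)))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Fisher's exact gene-set enrichment
#'
#' Per term, the 2x2 table in-study x in-term over the universe is scored
#' by the one-sided hypergeometric tail; BH-FDR is applied across all
#' tested terms within each namespace.  `rich_factor = k / K` (study genes
#' in the term over universe genes in the term).  Terms with no universe
#' gene are dropped.
#'
#' @param study_genes character vector, subset of the universe.
#' @param term_map a `term_map`.
#' @param universe gene universe; default all genes with >= 1 term
#'   annotation.
#' @return data.frame of class `geneset_results` with columns term_id,
#'   term_name, namespace, k, K, n, N, p_value, fdr, rich_factor, sorted by
#'   p ascending (ties by term_id).
#' @export
fisher_enrichment <- function(study_genes, term_map, universe = NULL) {
  stopifnot(inherits(term_map, "term_map"))
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(term_map, `[[`, "genes"))))
  universe <- unique(universe)
  study_genes <- unique(study_genes)
  if (!length(universe)) stop("empty universe")
  if (!length(study_genes)) stop("empty study set")
  if (!all(study_genes %in% universe))
    stop("study genes outside the universe: ",
         paste(head(setdiff(study_genes, universe), 5), collapse = ", "))
  N <- length(universe)
  n <- length(study_genes)
  rows <- lapply(term_map, function(t) {
    g <- intersect(t$genes, universe)
    K <- length(g)
    if (!K) return(NULL)
    k <- length(intersect(study_genes, g))
    data.frame(term_id = t$term_id, term_name = t$term_name,
               namespace = t$namespace, k = k, K = K, n = n, N = N,
               p_value = fisher_enrichment_p(k, n, K - k, N - n),
               rich_factor = k / K, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable terms (all empty in the universe)")
  res$fdr <- NA_real_
  for (ns in unique(res$namespace)) {
    sel <- res$namespace == ns
    res$fdr[sel] <- bh_fdr(res$p_value[sel])
  }
  res <- res[order(res$p_value, res$term_id), ,
             drop = FALSE]
  res <- res[, c("term_id", "term_name", "namespace", "k", "K", "n", "N",
                 "p_value", "fdr", "rich_factor")]
  rownames(res) <- NULL
  class(res) <- c("geneset_results", "data.frame")
  res
}

#' Top-N enrichment report tables
#'
#' Deterministic selection of the `n` smallest-P terms per namespace (ties
#' broken by term_id): a bar table (term, -log10 P) with the top `n_bar`
#' and a bubble table (term, rich factor, k, P) with the top `n_bubble`.
#'
#' @param results `geneset_results` from [fisher_enrichment()].
#' @param n_bar,n_bubble selection sizes (defaults 15 and 20).
#' @return list with data.frames `bar` and `bubble`.
#' @export
top_n_report <- function(results, n_bar = 15L, n_bubble = 20L) {
  pick <- function(n) {
    do.call(rbind, lapply(split(results, results$namespace), function(d) {
      d <- d[order(d$p_value, d$term_id), , drop = FALSE]
      head(d, n)
    })) -> out
    rownames(out) <- NULL
    out
  }
  bar <- pick(n_bar)
  bar <- data.frame(term_id = bar$term_id, term_name = bar$term_name,
                    namespace = bar$namespace,
                    minus_log10_p = -log10(bar$p_value),
                    stringsAsFactors = FALSE)
  bub <- pick(n_bubble)
  bubble <- data.frame(term_id = bub$term_id, term_name = bub$term_name,
                       namespace = bub$namespace, rich_factor = bub$rich_factor,
                       k = bub$k, p_value = bub$p_value,
                       stringsAsFactors = FALSE)
  list(bar = bar, bubble = bubble)
}

#' Write enrichment results as TSV
#' @param results `geneset_results`.
#' @param path output path.
#' @export
write_enrichment <- function(results, path) {
  out <- results
  out$p_value <- formatC(out$p_value, digits = 6, format = "g")
  out$fdr <- formatC(out$fdr, digits = 6, format = "g")
  out$rich_factor <- sprintf("%.6f", out$rich_factor)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
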