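# Filtering of a differential-expression table and association of DEG
# direction with promoter insulator occupancy groups.

#' Read a differential-expression table
#'
#' TSV with columns `gene_id`, `logFC` (log2), `PValue` (or `P`), `log10CPM`.
#'
#' @param path TSV file.
#' @return Data frame `gene_id`, `logFC`, `p_value`, `log10_cpm`.
#' @export
read_deg <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  pcol <- intersect(c("PValue", "P", "p_value"), names(tab))[1L]
  ccol <- intersect(c("log10CPM", "log10_cpm", "logCPM"), names(tab))[1L]
  if (is.na(pcol) || is.na(ccol) || !all(c("gene_id", "logFC") %in% names(tab))) {
    stop("expected columns gene_id, logFC, PValue, log10CPM in ", path)
  }
  data.frame(gene_id = tab$gene_id, logFC = tab$logFC,
             p_value = tab[[pcol]], log10_cpm = tab[[ccol]],
             stringsAsFactors = FALSE)
}

#' Filter differentially expressed genes
#'
#' Keeps genes with `p_value <= alpha` and expression of at least `min_expr`
#' log10 CPM (both thresholds as used for the BEAF-32 disruption analysis:
#' unadjusted P <= 0.05 and >= 1 log10 CPM). An optional Benjamini-Hochberg
#' correction can be switched on; it is off by default.
#'
#' @param table Data frame from [read_deg()].
#' @param alpha P-value threshold (default 0.05).
#' @param min_expr Minimum log10 CPM (default 1.0).
#' @param fdr Apply BH correction to `p_value` before thresholding
#'   (default FALSE).
#' @return The significant subset with an added `direction` column
#'   (`"up"` iff `logFC > 0`, else `"down"`).
#' @export
filter_deg <- function(table, alpha = 0.05, min_expr = 1.0, fdr = FALSE) {
  p <- if (fdr) stats::p.adjust(table$p_value, method = "BH") else table$p_value
  keep <- !is.na(p) & p <= alpha & table$log10_cpm >= min_expr
  out <- table[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Group DEGs by promoter insulator occupancy
#'
#' Each DEG annotated in the occupancy table is assigned to exactly one of
#' the `2^k` factor subsets, then rolled up to the four display groups: one
#' factor, two factors, all three, none. DEGs absent from the occupancy
#' annotation are excluded from the groups and reported separately.
#'
#' @param degs Filtered DEG data frame (from [filter_deg()]).
#' @param occupancy An `OccupancyTable` covering the factors.
#' @param factors Factor labels (default BEAF-32, dCTCF, GAF).
#' @return List with `subsets` (named counts over all factor combinations),
#'   `groups` (named list `one`/`two`/`three`/`none` of member gene ids),
#'   `membership` (data frame `gene_id`, `subset`, `group`), and
#'   `n_unannotated`.
#' @export
group_by_occupancy <- function(degs, occupancy,
                               factors = c("BEAF-32", "dCTCF", "GAF")) {
  occ <- occupancy[occupancy$factor %in% factors, , drop = FALSE]
  annotated <- degs$gene_id %in% occ$gene_id
  g <- degs$gene_id[annotated]
  subset_of <- vapply(g, function(id) {
    present <- vapply(factors, function(f) {
      any(occ$occupied[occ$gene_id == id & occ$factor == f])
    }, logical(1))
    if (!any(present)) "none" else paste(factors[present], collapse = "+")
  }, character(1))
  nfac <- vapply(strsplit(subset_of, "+", fixed = TRUE), function(x) {
    if (identical(x, "none")) 0L else length(x)
  }, integer(1))
  group <- c("none", "one", "two", "three")[nfac + 1L]
  all_names <- vapply(0:(2^length(factors) - 1), function(m) {
    present <- bitwAnd(m, 2^(seq_along(factors) - 1)) > 0
    if (!any(present)) "none" else paste(factors[present], collapse = "+")
  }, character(1))
  subsets <- stats::setNames(integer(length(all_names)), all_names)
  tb <- table(subset_of)
  subsets[names(tb)] <- as.integer(tb)
  list(subsets = subsets,
       groups = list(one = g[group == "one"], two = g[group == "two"],
                     three = g[group == "three"], none = g[group == "none"]),
       membership = data.frame(gene_id = g, subset = unname(subset_of),
                               group = group, stringsAsFactors = FALSE),
       n_unannotated = sum(!annotated))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided P as the sum of hypergeometric probabilities not exceeding the
#' observed table's probability; a table with a zero margin has P = 1.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return A `StatTestResult` list with the odds-ratio estimate as statistic.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  stopifnot(all(m >= 0), all(m == round(m)))
  ft <- stats::fisher.test(m, alternative = "two.sided")
  structure(list(statistic = unname(ft$estimate), p_value = ft$p.value,
                 method = "fisher exact (two-sided)",
                 n1 = a + b, n2 = c + d,
                 medians = c(NA_real_, NA_real_)),
            class = "StatTestResult")
}

#' Expression-change trends per occupancy group
#'
#' Summarizes each occupancy group of DEGs (size, median log fold change,
#' fraction upregulated) and tests every pair of groups for a difference in
#' up/down composition with the Fisher exact test.
#'
#' @param groups Named list of gene-id vectors (e.g. `$groups` from
#'   [group_by_occupancy()], or per-subset lists).
#' @param degs Filtered DEG data frame with `direction`.
#' @return List with `summary` (data frame `group`, `n`, `median_logFC`,
#'   `up_fraction`) and `tests` (named list of pairwise `StatTestResult`s).
#' @export
group_trends <- function(groups, degs) {
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  stats_of <- function(ids) {
    d <- degs[degs$gene_id %in% ids, , drop = FALSE]
    c(n = nrow(d), median_logFC = stats::median(d$logFC),
      up = sum(d$direction == "up"), down = sum(d$direction == "down"))
  }
  st <- vapply(groups, stats_of, numeric(4))
  summary <- data.frame(group = colnames(st), n = st["n", ],
                        median_logFC = st["median_logFC", ],
                        up_fraction = st["up", ] / pmax(st["n", ], 1),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  tests <- list()
  nms <- colnames(st)
  if (length(nms) > 1) {
    for (i in seq_len(length(nms) - 1)) {
      for (j in (i + 1):length(nms)) {
        nm <- paste(nms[i], "vs", nms[j])
        tests[[nm]] <- fisher_exact_2x2(st["up", i], st["down", i],
                                        st["up", j], st["down", j])
      }
    }
  }
  list(summary = summary, tests = tests)
}
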