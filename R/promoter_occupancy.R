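# Promoter-window construction, insulator occupancy calls, direct/indirect
# binding classification by consensus-motif scan, occupancy combinatorics and
# the group enrichment comparisons.

#' Strand-aware promoter window
#'
#' On the plus strand the window is `[tss - upstream, tss + downstream)`; on
#' the minus strand the mirror image `[tss - downstream + 1, tss + upstream + 1)`.
#' Clipped to the chromosome.
#'
#' @param tss TSS coordinate(s), 0-based.
#' @param strand `"+"` or `"-"` per gene.
#' @param upstream Bases upstream of the TSS (default 200, the promoter range
#'   used throughout).
#' @param downstream Bases downstream (default 0).
#' @param chrom_len Chromosome length(s) for clipping.
#' @return Data frame with `start`, `end` per gene.
#' @export
promoter_window <- function(tss, strand, upstream = 200, downstream = 0,
                            chrom_len) {
  strand_window(tss, strand, upstream, downstream, chrom_len)
}

#' Define a consensus motif
#'
#' @param name Factor name (e.g. `"BEAF-32"`).
#' @param consensus IUPAC DNA consensus, length >= 4 (e.g. `"CGATA"`,
#'   `"TATCGATA"`).
#' @param scan_both_strands Also match the reverse complement (default TRUE).
#' @return A `MotifSpec` list.
#' @export
motif_spec <- function(name, consensus, scan_both_strands = TRUE) {
  consensus <- toupper(consensus)
  if (nchar(consensus) < 4) stop("consensus must be at least 4 nt")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", consensus)) {
    stop("consensus must be IUPAC DNA: ", consensus)
  }
  structure(list(name = name, consensus = consensus,
                 scan_both_strands = scan_both_strands),
            class = "MotifSpec")
}

#' Scan a sequence for exact IUPAC matches of a consensus motif
#'
#' All (possibly overlapping) matches on the plus strand and, when the motif
#' scans both strands, matches of the reverse complement are reported.
#'
#' @param seq Uppercase DNA string.
#' @param motif A `MotifSpec`.
#' @return Data frame with `offset` (0-based match start on the given
#'   sequence) and `strand`.
#' @export
scan_motif <- function(seq, motif) {
  stopifnot(inherits(motif, "MotifSpec"))
  empty <- data.frame(offset = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(seq) || nchar(seq) < nchar(motif$consensus)) return(empty)
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(motif$consensus)
  fix <- c(pattern = FALSE, subject = TRUE)   # IUPAC in pattern, literal subject
  fwd <- Biostrings::matchPattern(pat, subj, fixed = fix)
  out <- data.frame(offset = Biostrings::start(fwd) - 1L,
                    strand = rep("+", length(fwd)), stringsAsFactors = FALSE)
  if (motif$scan_both_strands) {
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                    fixed = fix)
    out <- rbind(out, data.frame(offset = Biostrings::start(rev) - 1L,
                                 strand = rep("-", length(rev)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Call promoter occupancy of one factor over a gene set
#'
#' A gene is occupied when at least one peak overlaps its promoter window
#' (standard mode) or, for poorly annotated genomes, the extended
#' strand-oriented window `ext_up` upstream to `ext_down` downstream of the
#' TSS (extended mode). `peak_signal` is the maximum `signal_value` among
#' overlapping peaks and `distance_to_tss` the distance from that peak's
#' summit (midpoint when no summit is recorded) to the TSS.
#'
#' @param genes Gene data frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @param peaks A `PeakSet` for one factor.
#' @param chrom_sizes Named chromosome lengths.
#' @param upstream,downstream Promoter window extents (default 200/0).
#' @param extended Use the extended window instead (default FALSE).
#' @param ext_up,ext_down Extended window extents (default 10 kb / 2 kb).
#' @param factor Factor label stored in the result; defaults to the peak set's
#'   label.
#' @return An `OccupancyTable` data frame: `gene_id`, `factor`, `occupied`,
#'   `peak_signal`, `binding` (`NA` until [classify_binding()]),
#'   `distance_to_tss`, and the internal `peak_row` of the max-signal peak.
#' @export
call_occupancy <- function(genes, peaks, chrom_sizes,
                           upstream = 200, downstream = 0,
                           extended = FALSE, ext_up = 10000, ext_down = 2000,
                           factor = attr(peaks, "label")) {
  if (is.null(factor) || is.na(factor)) factor <- "factor"
  win <- if (extended) {
    strand_window(genes$tss, genes$strand, ext_up, ext_down,
                  chrom_sizes[genes$chrom])
  } else {
    promoter_window(genes$tss, genes$strand, upstream, downstream,
                    chrom_sizes[genes$chrom])
  }
  n <- nrow(genes)
  occ <- logical(n); sig <- rep(NA_real_, n)
  dist <- rep(NA_real_, n); prow <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hits <- which_overlaps(peaks, genes$chrom[i], win$start[i], win$end[i])
    if (!length(hits)) next
    occ[i] <- TRUE
    best <- hits[which.max(peaks$signal_value[hits])]
    sig[i] <- peaks$signal_value[best]
    pos <- if (is.na(peaks$summit_offset[best])) {
      floor((peaks$start[best] + peaks$end[best]) / 2)
    } else {
      peaks$start[best] + peaks$summit_offset[best]
    }
    dist[i] <- abs(pos - genes$tss[i])
    prow[i] <- best
  }
  out <- data.frame(gene_id = genes$gene_id, factor = factor, occupied = occ,
                    peak_signal = sig, binding = NA_character_,
                    distance_to_tss = dist, peak_row = prow,
                    stringsAsFactors = FALSE)
  out$binding[!occ] <- "absent"
  structure(out, class = c("OccupancyTable", "data.frame"))
}

#' Classify occupied promoters as direct or indirect binding
#'
#' The full genomic sequence of the best (max-signal) peak of each occupied
#' gene is scanned for the factor's consensus motif on both strands; a match
#' makes the binding direct, otherwise it is indirect.
#'
#' @param occupancy An `OccupancyTable` from [call_occupancy()].
#' @param peaks The `PeakSet` that produced it.
#' @param genome Named character vector of chromosome sequences.
#' @param motif A `MotifSpec`.
#' @return The occupancy table with `binding` filled in
#'   (`direct`/`indirect`/`absent`).
#' @export
classify_binding <- function(occupancy, peaks, genome, motif) {
  for (i in which(occupancy$occupied)) {
    p <- occupancy$peak_row[i]
    seq <- substr(genome[[peaks$chrom[p]]], peaks$start[p] + 1, peaks$end[p])
    occupancy$binding[i] <-
      if (nrow(scan_motif(seq, motif)) > 0) "direct" else "indirect"
  }
  occupancy
}

#' Count genes per combination of occupying factors
#'
#' Each gene is assigned to exactly one of the `2^k` subsets of `factors`
#' (including `"none"`), so the counts partition the gene set — the numbers
#' behind a k-set Venn diagram.
#'
#' @param occupancy An `OccupancyTable` covering one or more factors (rows are
#'   gene x factor).
#' @param factors Factor labels to combine (default the three insulators
#'   BEAF-32, GAF, dCTCF).
#' @return Named integer vector over all subsets; names are `+`-joined factor
#'   labels in the given order, with `"none"` for the empty set.
#' @export
occupancy_combinations <- function(occupancy,
                                   factors = c("BEAF-32", "GAF", "dCTCF")) {
  occ <- occupancy[occupancy$factor %in% factors, , drop = FALSE]
  genes <- unique(occupancy$gene_id)
  subset_name <- function(present) {
    if (!any(present)) "none" else paste(factors[present], collapse = "+")
  }
  all_names <- vapply(0:(2^length(factors) - 1), function(m) {
    subset_name(bitwAnd(m, 2^(seq_along(factors) - 1)) > 0)
  }, character(1))
  counts <- stats::setNames(integer(length(all_names)), all_names)
  for (g in genes) {
    present <- vapply(factors, function(f) {
      any(occ$occupied[occ$gene_id == g & occ$factor == f])
    }, logical(1))
    nm <- subset_name(present)
    counts[nm] <- counts[nm] + 1L
  }
  counts
}

#' Mann-Whitney U test for two independent samples
#'
#' The statistic is `U` of `x` relative to `y` (ties counted one half). Exact
#' mode uses the null `U` distribution when the pooled sample has no ties and
#' full enumeration of all labelings otherwise; the normal approximation uses
#' the tie-corrected variance and a continuity correction. `"auto"` picks the
#' exact route when `n1 + n2 <= 20` and there are no ties.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return A `StatTestResult` list: `statistic` (U), `p_value`, `method`,
#'   `n1`, `n2`, `medians`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (mode == "auto") mode <- if (n1 + n2 <= 20 && !ties) "exact" else "normal_approx"

  if (mode == "exact") {
    if (!ties) {
      # two-sided tail of the exact (symmetric) null U distribution
      p <- 2 * min(stats::pwilcox(U, n1, n2),
                   1 - stats::pwilcox(U - 1, n1, n2))
      method <- "mann-whitney exact"
    } else {
      if (choose(n1 + n2, n1) > 2e6) {
        stop("exact mode with ties infeasible for n1 + n2 = ", n1 + n2)
      }
      combs <- utils::combn(n1 + n2, n1)
      mu <- n1 * n2 / 2
      obs <- abs(U - mu)
      us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
      p <- mean(abs(us - mu) >= obs - 1e-9)
      method <- "mann-whitney exact (tie enumeration)"
    }
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tt <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sig2)
      z <- max(z, 0)
      p <- 2 * stats::pnorm(-z)
    }
    method <- "mann-whitney normal approximation"
  }
  structure(list(statistic = U, p_value = min(p, 1), method = method,
                 n1 = n1, n2 = n2,
                 medians = c(stats::median(x), stats::median(y))),
            class = "StatTestResult")
}

#' @export
print.StatTestResult <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", P = ", format(x$p_value, digits = 4),
      " (n = ", x$n1, "/", x$n2, ")\n", sep = "")
  invisible(x)
}

#' Compare peak enrichment between groups of occupied promoters
#'
#' Medians are computed on `peak_signal` of occupied records only; every pair
#' of groups is compared with [mann_whitney()].
#'
#' @param occupancy An `OccupancyTable` (or any data frame with `occupied` and
#'   `peak_signal`).
#' @param grouping Vector (same length as rows of `occupancy`) assigning each
#'   record to a group, e.g. the `binding` column or a location call.
#' @param mode Test mode passed to [mann_whitney()].
#' @return List with `summary` (data frame `group`, `n`, `median`) and
#'   `tests` (named list of pairwise `StatTestResult`s, names `"A vs B"`).
#' @export
compare_groups <- function(occupancy, grouping, mode = "auto") {
  keep <- occupancy$occupied & !is.na(occupancy$peak_signal)
  sig <- occupancy$peak_signal[keep]
  grp <- as.character(grouping[keep])
  groups <- sort(unique(grp))
  summary <- data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(grp == g), integer(1)),
    median = vapply(groups, function(g) stats::median(sig[grp == g]), numeric(1)),
    stringsAsFactors = FALSE
  )
  tests <- list()
  if (length(groups) > 1) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        nm <- paste(groups[i], "vs", groups[j])
        tests[[nm]] <- mann_whitney(sig[grp == groups[i]],
                                    sig[grp == groups[j]], mode = mode)
      }
    }
  }
  list(summary = summary, tests = tests)
}
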