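# Delineation of the pericentric euchromatin-heterochromatin border per
# chromosome arm from H3K9me3 (and optionally HP1a) fold enrichment, and
# construction of the active-heterochromatic-gene set.

#' Delineate the euchromatin-heterochromatin border on one arm
#'
#' The fold-enrichment track is aggregated into `window_bp` windows (mean over
#' bins), smoothed with a running median of width `smooth_k`, and scanned from
#' the telomeric end toward the pericentric end. The border is the
#' telomere-facing boundary of the outermost window at which the smoothed
#' fold enrichment first reaches `threshold` and stays at or above it for at
#' least `min_run` consecutive windows ("gradual increase" operationalized as
#' a sustained run). `NA` when no such run exists (fully euchromatic arm).
#'
#' @param fe_track A `SignalTrack` in `fold_enrichment` units.
#' @param chrom Chromosome arm to scan.
#' @param pericentric_end `"right"` (centromere at high coordinates) or
#'   `"left"`.
#' @param window_bp Aggregation window (default 10 kb).
#' @param threshold Fold-enrichment level defining heterochromatin (default 2).
#' @param min_run Minimum sustained run length in windows (default 10).
#' @param smooth_k Running-median width; odd (default 5).
#' @return Border coordinate in bp, or `NA` if absent.
#' @export
delineate_border <- function(fe_track, chrom,
                             pericentric_end = c("right", "left"),
                             window_bp = 10000, threshold = 2.0,
                             min_run = 10, smooth_k = 5) {
  pericentric_end <- match.arg(pericentric_end)
  stopifnot(inherits(fe_track, "SignalTrack"), min_run >= 1,
            smooth_k %% 2 == 1)
  if (fe_track$units != "fold_enrichment") {
    stop("delineate_border expects a fold_enrichment track, got ", fe_track$units)
  }
  v <- fe_track$values[[chrom]]
  if (is.null(v)) stop("no track for chromosome ", chrom)
  len <- fe_track$chrom_sizes[[chrom]]
  bs <- fe_track$bin_size
  bins_per_win <- window_bp / bs
  if (bins_per_win < 1 || window_bp %% bs != 0) {
    stop("window_bp must be a positive multiple of the track bin size")
  }
  win_id <- floor(((seq_along(v) - 1) * bs) / window_bp)
  w <- as.numeric(tapply(v, win_id, mean))
  nwin <- length(w)
  if (nwin < min_run) {
    warning(chrom, " has ", nwin, " windows (< min_run = ", min_run,
            "); border absent")
    return(NA_real_)
  }
  sm <- if (nwin > smooth_k) as.numeric(stats::runmed(w, smooth_k)) else w
  scan <- if (pericentric_end == "right") sm else rev(sm)
  r <- rle(scan >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= min_run)
  if (!length(hit)) return(NA_real_)
  s <- starts[hit[1L]]            # first qualifying window in scan order
  if (pericentric_end == "right") {
    (s - 1) * window_bp
  } else {
    gw <- nwin - s + 1            # genomic window index
    min(gw * window_bp, len)
  }
}

#' Combine H3K9me3 and HP1a borders into a single call
#'
#' `"outermost"` (default) keeps the most telomeric of the two borders, i.e.
#' the larger heterochromatin extent; `"innermost"` the opposite;
#' `"h3k9me3_only"` ignores the HP1a call. An absent (`NA`) border defers to
#' the other mark.
#'
#' @param h3k9me3_border,hp1a_border Border coordinates (bp) or `NA`.
#' @param policy Combination policy.
#' @param pericentric_end Arm orientation (needed to orient "outermost").
#' @return Border coordinate or `NA`.
#' @export
combine_borders <- function(h3k9me3_border, hp1a_border,
                            policy = c("outermost", "h3k9me3_only", "innermost"),
                            pericentric_end = c("right", "left")) {
  policy <- match.arg(policy)
  pericentric_end <- match.arg(pericentric_end)
  if (policy == "h3k9me3_only") return(h3k9me3_border)
  b <- c(h3k9me3_border, hp1a_border)
  b <- b[!is.na(b)]
  if (!length(b)) return(NA_real_)
  towards_telomere <- if (pericentric_end == "right") min else max
  towards_centromere <- if (pericentric_end == "right") max else min
  if (policy == "outermost") towards_telomere(b) else towards_centromere(b)
}

#' Build a chromatin domain map
#'
#' @param chrom Chromosome names.
#' @param border Border coordinate per chromosome (`NA` = none found).
#' @param pericentric_end `"right"` or `"left"` per chromosome.
#' @param whole_chrom_het Logical per chromosome; `TRUE` marks a chromosome
#'   treated as entirely heterochromatic (the dot chromosome 4 override), in
#'   which case the border must be absent.
#' @return A `ChromatinDomainMap` data frame.
#' @export
domain_map <- function(chrom, border, pericentric_end, whole_chrom_het = FALSE) {
  d <- data.frame(chrom = chrom, border = as.numeric(border),
                  pericentric_end = pericentric_end,
                  whole_chrom_het = whole_chrom_het,
                  stringsAsFactors = FALSE)
  if (any(d$whole_chrom_het & !is.na(d$border))) {
    stop("whole_chrom_het chromosomes must have an absent border")
  }
  if (!all(d$pericentric_end %in% c("right", "left"))) {
    stop("pericentric_end must be 'right' or 'left'")
  }
  structure(d, class = c("ChromatinDomainMap", "data.frame"))
}

#' Classify genes as euchromatic or heterochromatic
#'
#' A gene is heterochromatic iff its TSS lies on the pericentric side of its
#' arm's border (a TSS exactly at the border is assigned to heterochromatin —
#' fixed tie rule), or its chromosome is flagged entirely heterochromatic.
#' Arms without a border are entirely euchromatic.
#'
#' @param genes Gene data frame (`chrom`, `tss`).
#' @param domains A `ChromatinDomainMap`.
#' @return Character vector `"euchromatic"`/`"heterochromatic"` per gene.
#' @export
classify_gene_location <- function(genes, domains) {
  i <- match(genes$chrom, domains$chrom)
  if (anyNA(i)) {
    stop("no domain call for chromosome(s): ",
         paste(unique(genes$chrom[is.na(i)]), collapse = ", "))
  }
  het <- domains$whole_chrom_het[i] |
    (!is.na(domains$border[i]) &
       ifelse(domains$pericentric_end[i] == "right",
              genes$tss >= domains$border[i],
              genes$tss <= domains$border[i]))
  ifelse(het, "heterochromatic", "euchromatic")
}

#' Select active heterochromatic genes (and the active euchromatic complement)
#'
#' A gene is called active when it has at least one RNA Pol II peak
#' overlapping the strand-oriented window around its TSS (peak calls carry the
#' significance) and an expression level of at least `min_rpm` reads per
#' million. Only protein-coding genes are considered; genes missing from the
#' expression table get RPM 0.
#'
#' @param annotation A `GenomeAnnotation`.
#' @param domains A `ChromatinDomainMap`.
#' @param polII_peaks A `PeakSet` of Pol II peaks.
#' @param expr Expression table from [read_expression()].
#' @param min_rpm Activity threshold in RPM (default 10).
#' @param polII_up,polII_down Pol II search window around the TSS in bp
#'   (default 2 kb both sides).
#' @return A `GeneChromatinCalls` data frame: `gene_id`, `location`, `rpm`,
#'   `polII_hit`, `active`.
#' @export
select_active_het_genes <- function(annotation, domains, polII_peaks, expr,
                                    min_rpm = 10, polII_up = 2000,
                                    polII_down = 2000) {
  g <- annotation$genes
  g <- g[g$biotype == "protein_coding", , drop = FALSE]
  loc <- classify_gene_location(g, domains)
  rpm <- expr$rpm[match(g$gene_id, expr$gene_id)]
  rpm[is.na(rpm)] <- 0
  win <- strand_window(g$tss, g$strand, polII_up, polII_down,
                       annotation$chrom_sizes[g$chrom])
  hit <- vapply(seq_len(nrow(g)), function(i) {
    length(which_overlaps(polII_peaks, g$chrom[i], win$start[i], win$end[i])) > 0
  }, logical(1))
  out <- data.frame(gene_id = g$gene_id, location = loc, rpm = rpm,
                    polII_hit = hit, active = hit & rpm >= min_rpm,
                    stringsAsFactors = FALSE)
  structure(out, class = c("GeneChromatinCalls", "data.frame"))
}

# Strand-oriented window [tss-up, tss+down) on "+", mirrored on "-";
# clipped to [0, chrom_len). Shared by Pol II selection and extended
# occupancy mode.
strand_window <- function(tss, strand, up, down, chrom_len) {
  s <- ifelse(strand == "-", tss - down + 1, tss - up)
  e <- ifelse(strand == "-", tss + up + 1, tss + down)
  data.frame(start = pmax(0, s), end = pmin(as.numeric(chrom_len), e))
}
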