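# Input-normalized fold-enrichment tracks and TSS-anchored enrichment
# matrices (a desk-scale reimplementation of the deepTools-style computation).

#' Construct a fixed-bin signal track
#'
#' @param values Named list of per-chromosome numeric vectors.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named vector of chromosome lengths; vector lengths must
#'   equal `ceiling(length / bin_size)`.
#' @param units One of `"raw"`, `"rpm"`, `"fold_enrichment"`.
#' @return A `SignalTrack` object.
#' @export
signal_track <- function(values, bin_size, chrom_sizes,
                         units = c("raw", "rpm", "fold_enrichment")) {
  units <- match.arg(units)
  stopifnot(is.list(values), !is.null(names(values)),
            all(names(values) %in% names(chrom_sizes)))
  for (cn in names(values)) {
    v <- values[[cn]]
    if (length(v) != ceiling(chrom_sizes[[cn]] / bin_size)) {
      stop("track for ", cn, " has ", length(v), " bins, expected ",
           ceiling(chrom_sizes[[cn]] / bin_size))
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("track for ", cn, " must be finite and non-negative")
    }
  }
  structure(list(values = values, bin_size = bin_size,
                 chrom_sizes = chrom_sizes[names(values)], units = units),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat("SignalTrack (", x$units, "): ", length(x$values),
      " chromosome(s), bin ", x$bin_size, " bp\n", sep = "")
  invisible(x)
}

#' Depth-normalize a raw track to RPM
#'
#' Each bin is scaled by `1e6 / total_reads` (reads per million).
#'
#' @param track A raw `SignalTrack`.
#' @param total_reads Library size; must be positive.
#' @return The track in `rpm` units.
#' @export
normalize_rpm <- function(track, total_reads) {
  stopifnot(inherits(track, "SignalTrack"), total_reads > 0)
  track$values <- lapply(track$values, function(v) v * 1e6 / total_reads)
  track$units <- "rpm"
  track
}

#' Per-bin fold enrichment of treatment over input
#'
#' `(treat + pseudocount) / (input + pseudocount)` per bin. Refuses to run
#' without an input track: occupancy comparisons downstream are defined in
#' fold-enrichment units, so silently falling back to raw signal would change
#' their meaning.
#'
#' @param treat,input `SignalTrack`s on the same bin grid.
#' @param pseudocount Added to both numerator and denominator (default 1.0, in
#'   the tracks' units).
#' @return A `SignalTrack` in `fold_enrichment` units.
#' @export
fold_enrichment <- function(treat, input, pseudocount = 1.0) {
  if (missing(input) || is.null(input)) {
    stop("fold_enrichment requires an input track; no fallback to raw signal")
  }
  stopifnot(inherits(treat, "SignalTrack"), inherits(input, "SignalTrack"),
            pseudocount >= 0)
  if (treat$bin_size != input$bin_size ||
      !setequal(names(treat$values), names(input$values))) {
    stop("treat and input tracks are on different bin grids")
  }
  vals <- lapply(names(treat$values), function(cn) {
    a <- treat$values[[cn]]; b <- input$values[[cn]]
    if (length(a) != length(b)) stop("bin grids differ on ", cn)
    (a + pseudocount) / (b + pseudocount)
  })
  names(vals) <- names(treat$values)
  signal_track(vals, treat$bin_size, treat$chrom_sizes, units = "fold_enrichment")
}

# Bin values over a window of bin indices (0-based), 0 outside the chromosome.
extract_bins <- function(v, idx) {
  out <- numeric(length(idx))
  ok <- idx >= 0 & idx < length(v)
  out[ok] <- v[idx[ok] + 1]
  out
}

#' TSS-anchored enrichment matrix
#'
#' Row i holds the track values in a strand-oriented window around gene i's
#' TSS: columns run 5' to 3' from `-upstream` to `+downstream` relative to the
#' TSS bin, so minus-strand rows are reversed relative to genome orientation.
#' Bins outside the chromosome are 0.
#'
#' @param track A `SignalTrack`.
#' @param genes Gene data frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @param upstream,downstream Window extents in bp; multiples of the track's
#'   bin size.
#' @return Numeric matrix with `gene_id` rownames, bin-offset colnames and
#'   attribute `bin_size`.
#' @export
tss_matrix <- function(track, genes, upstream, downstream) {
  bs <- track$bin_size
  if (upstream %% bs != 0 || downstream %% bs != 0) {
    stop("upstream and downstream must be multiples of bin_size (", bs, ")")
  }
  ub <- upstream / bs; db <- downstream / bs
  n <- ub + db
  mat <- matrix(0, nrow = nrow(genes), ncol = n,
                dimnames = list(genes$gene_id,
                                seq(-upstream, downstream - bs, by = bs)))
  for (i in seq_len(nrow(genes))) {
    v <- track$values[[genes$chrom[i]]]
    if (is.null(v)) next
    tb <- floor(genes$tss[i] / bs)
    idx <- if (genes$strand[i] == "-") tb + (ub:(-db + 1)) else tb + (-ub:(db - 1))
    mat[i, ] <- extract_bins(v, idx)
  }
  attr(mat, "bin_size") <- bs
  mat
}

#' Summary statistic of a track over an interval
#'
#' @param track A `SignalTrack`.
#' @param chrom,start,end Query interval (0-based half-open).
#' @param stat `"mean"` or `"max"` over the bins overlapping the interval.
#' @return A single numeric value.
#' @export
region_score <- function(track, chrom, start, end, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  v <- track$values[[chrom]]
  if (is.null(v)) stop("no track for chromosome ", chrom)
  b0 <- floor(start / track$bin_size)
  b1 <- floor((end - 1) / track$bin_size)
  b0 <- max(b0, 0); b1 <- min(b1, length(v) - 1)
  if (b1 < b0) stop("interval [", start, ", ", end, ") overlaps no bins on ", chrom)
  x <- v[(b0:b1) + 1]
  if (stat == "mean") mean(x) else max(x)
}

#' Column-mean profile of an enrichment matrix
#'
#' @param matrix A matrix from [tss_matrix()]; rows that are entirely `NA` are
#'   ignored.
#' @return Numeric vector of column means.
#' @export
mean_profile <- function(matrix) {
  colMeans(matrix, na.rm = TRUE)
}

#' Write an enrichment matrix as TSV with a bin-offset header
#' @param mat Matrix from [tss_matrix()].
#' @param path Output file.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
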