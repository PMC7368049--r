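# Readers/writers for the standard formats the pipeline touches, plus the
# minimal interval model everything downstream operates on.
#
# All internal coordinates are 0-based half-open; GFF (1-based inclusive) is
# converted on read and on write, BED-family formats are native.

#' Construct a genomic interval
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A one-row data frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), nzchar(chrom))
  if (!(start >= 0 && start < end)) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of '+', '-', '.'")
  data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Test whether two intervals overlap by at least one base
#'
#' Half-open semantics: `[0,10)` and `[10,20)` do not overlap.
#'
#' @param a,b Intervals as returned by [interval()] (one row each).
#' @return `TRUE` iff same chromosome and the half-open ranges intersect.
#' @export
overlaps <- function(a, b) {
  identical(a$chrom, b$chrom) && a$start < b$end && b$start < a$end
}

# Vectorised overlap: indices of rows in `df` (chrom/start/end) hitting the
# query range. Internal workhorse for occupancy calls.
which_overlaps <- function(df, chrom, start, end) {
  which(df$chrom == chrom & df$start < end & start < df$end)
}

#' Read a genome annotation from GFF3/GTF
#'
#' Gene coordinates are converted from 1-based inclusive to 0-based half-open.
#' The TSS of a gene is the 5'-most transcript start across its isoforms
#' (falling back to the gene extent when no transcript features are present),
#' a deterministic convention for multi-TSS genes.
#'
#' @param path GFF3 or GTF file.
#' @param chrom_sizes Optional named vector of chromosome lengths; when absent,
#'   taken from `##sequence-region` directives or the maximal feature end.
#' @return A `GenomeAnnotation`: list with `genes` (data frame `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `biotype`) and `chrom_sizes`.
#' @export
read_gff <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1L]]
    stop("malformed GFF line ", bad, ": expected 9 tab-separated fields, got ",
         nf[which(nf != 9)[1L]])
  }
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  strand <- as.character(GenomicRanges::strand(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)

  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no 'gene' features found in ", path)
  gid <- if ("gene_id" %in% names(meta)) as.character(meta$gene_id) else
    as.character(meta$ID)
  if (anyNA(gid[is_gene])) gid[is_gene][is.na(gid[is_gene])] <-
    as.character(meta$ID[is_gene][is.na(gid[is_gene])])
  keep <- is_gene & strand %in% c("+", "-")
  if (any(is_gene & !keep)) {
    warning(sum(is_gene & !keep), " gene record(s) with unknown strand skipped")
  }
  genes <- data.frame(
    gene_id = gid[keep], chrom = chrom[keep],
    start = start0[keep], end = end0[keep], strand = strand[keep],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         genes$gene_id[anyDuplicated(genes$gene_id)])
  }
  bio <- rep("protein_coding", nrow(genes))
  for (col in c("biotype", "gene_biotype")) {
    if (col %in% names(meta)) {
      v <- as.character(meta[[col]])[keep]
      bio[!is.na(v)] <- v[!is.na(v)]
    }
  }
  genes$biotype <- bio

  # 5'-most transcript start per gene
  is_tx <- type %in% c("mRNA", "transcript", "ncRNA")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  if (any(is_tx) && "Parent" %in% names(meta)) {
    parent <- vapply(meta$Parent, function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
    tx <- data.frame(parent = parent[is_tx], start = start0[is_tx],
                     end = end0[is_tx], stringsAsFactors = FALSE)
    tx <- tx[!is.na(tx$parent) & tx$parent %in% genes$gene_id, , drop = FALSE]
    if (nrow(tx)) {
      lo <- tapply(tx$start, tx$parent, min)
      hi <- tapply(tx$end, tx$parent, max)
      i <- match(genes$gene_id, names(lo))
      has <- !is.na(i)
      tss[has] <- ifelse(genes$strand[has] == "+",
                         lo[i[has]], hi[i[has]] - 1)
    }
  }
  genes$tss <- as.numeric(tss)
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "tss", "biotype")]

  if (is.null(chrom_sizes)) {
    sr <- lines[startsWith(lines, "##sequence-region")]
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(sr)) {
      f <- strsplit(trimws(sr), "[ \t]+")
      chrom_sizes <- stats::setNames(
        vapply(f, function(x) as.numeric(x[4L]), numeric(1)),
        vapply(f, function(x) x[2L], character(1)))
    } else if (all(!is.na(sl)) && length(sl)) {
      chrom_sizes <- as.numeric(sl); names(chrom_sizes) <- names(sl)
    } else {
      chrom_sizes <- tapply(end0, chrom, max)
      chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
    }
  }
  bad <- genes$end > chrom_sizes[genes$chrom]
  if (any(bad, na.rm = TRUE)) {
    stop("gene(s) extend beyond chromosome length: ",
         paste(genes$gene_id[which(bad)], collapse = ", "))
  }
  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x$genes), "genes on",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_gff()]: internal 0-based half-open coordinates are written
#' as 1-based inclusive, one `gene` plus one spanning `mRNA` feature per gene.
#'
#' @param annotation A `GenomeAnnotation`.
#' @param path Output file.
#' @export
write_gff <- function(annotation, path) {
  g <- annotation$genes
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d",
                   names(annotation$chrom_sizes),
                   as.integer(annotation$chrom_sizes)))
  gene_ln <- sprintf("%s\thetinsul\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                     g$chrom, as.integer(g$start + 1), as.integer(g$end),
                     g$strand, g$gene_id, g$biotype)
  mrna_ln <- sprintf("%s\thetinsul\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                     g$chrom, as.integer(g$start + 1), as.integer(g$end),
                     g$strand, g$gene_id, g$gene_id)
  writeLines(c(hdr, as.vector(rbind(gene_ln, mrna_ln))), path)
  invisible(path)
}

#' Read called peaks (BED6 or ENCODE narrowPeak)
#'
#' narrowPeak column 7 becomes `signal_value` and column 10 the summit offset
#' (`-1` mapped to `NA`). For BED6 the score column doubles as `signal_value`.
#' Output is sorted by (chrom, start).
#'
#' @param path Peak file.
#' @param dialect `"narrowPeak"` (10 columns) or `"bed6"`.
#' @param label Factor name attached to the set (e.g. `"BEAF-32"`).
#' @return A `PeakSet` data frame: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal_value`, `summit_offset`.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed6"), label = NA_character_) {
  dialect <- match.arg(dialect)
  want <- if (dialect == "narrowPeak") 10L else 6L
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) {
    ps <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     name = character(), score = numeric(), strand = character(),
                     signal_value = numeric(), summit_offset = numeric(),
                     stringsAsFactors = FALSE)
    return(structure(ps, label = label, class = c("PeakSet", "data.frame")))
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != want)) {
    stop(dialect, " requires ", want, " tab-separated columns (chrom, start, ",
         "end, name, score, strand",
         if (want == 10L) ", signalValue, pValue, qValue, peak" else "",
         "); line ", which(nf != want)[1L], " has ", nf[nf != want][1L])
  }
  gr <- if (dialect == "narrowPeak") {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric", pValue = "numeric",
                                      qValue = "numeric", peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  m <- S4Vectors::mcols(gr)
  ps <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    name = if ("name" %in% names(m)) as.character(m$name) else NA_character_,
    score = if ("score" %in% names(m)) as.numeric(m$score) else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ps$strand[ps$strand == "*"] <- "."
  if (dialect == "narrowPeak") {
    ps$signal_value <- as.numeric(m$signalValue)
    ps$summit_offset <- ifelse(m$peak < 0, NA_real_, as.numeric(m$peak))
  } else {
    ps$signal_value <- ps$score
    ps$summit_offset <- NA_real_
  }
  if (any(ps$start < 0)) stop("negative peak coordinates in ", path)
  bad <- !is.na(ps$summit_offset) &
    (ps$summit_offset < 0 | ps$summit_offset >= ps$end - ps$start)
  if (any(bad)) stop("summit offset outside peak at line(s): ",
                     paste(which(bad), collapse = ", "))
  if (any(ps$signal_value < 0, na.rm = TRUE)) {
    stop("negative signalValue in ", path)
  }
  ps <- ps[order(ps$chrom, ps$start, ps$end), , drop = FALSE]
  rownames(ps) <- NULL
  structure(ps, label = label, class = c("PeakSet", "data.frame"))
}

#' Write a PeakSet in narrowPeak format
#' @param peaks A `PeakSet`.
#' @param path Output file.
#' @export
write_peaks <- function(peaks, path) {
  nm <- ifelse(is.na(peaks$name), ".", peaks$name)
  so <- ifelse(is.na(peaks$summit_offset), -1L, as.integer(peaks$summit_offset))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t-1\t-1\t%d",
                     peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                     nm, as.integer(peaks$score), peaks$strand,
                     format(peaks$signal_value, trim = TRUE, scientific = FALSE),
                     so),
             path)
  invisible(path)
}

#' Rasterize a bedGraph file onto a fixed-bin signal track
#'
#' Each bin value is the coverage-length-weighted mean of overlapping bedGraph
#' records over the full bin width; uncovered basepairs contribute zero, so an
#' uncovered bin has value 0. Records extending beyond the chromosome are
#' clipped with a warning.
#'
#' @param path bedGraph file.
#' @param bin_size Bin width in bp (default 200, the promoter-window scale).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param units Unit label stored on the track (`"raw"`, `"rpm"`,
#'   `"fold_enrichment"`).
#' @return A `SignalTrack` (see [signal_track()]).
#' @export
read_bedgraph <- function(path, bin_size = 200, chrom_sizes, units = "raw") {
  stopifnot(bin_size >= 1)
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1
  end <- as.numeric(GenomicRanges::end(gr))
  val <- as.numeric(S4Vectors::mcols(gr)$score)
  vals <- lapply(names(chrom_sizes), function(cn) {
    len <- chrom_sizes[[cn]]
    nb <- ceiling(len / bin_size)
    acc <- numeric(nb)
    sel <- which(chrom == cn)
    if (any(end[sel] > len)) {
      warning("bedGraph record(s) beyond length of ", cn, " clipped")
    }
    for (i in sel) {
      s <- max(0, start[i]); e <- min(len, end[i])
      if (e <= s) next
      b0 <- floor(s / bin_size); b1 <- floor((e - 1) / bin_size)
      if (b0 == b1) {
        acc[b0 + 1] <- acc[b0 + 1] + val[i] * (e - s)
      } else {
        bins <- b0:b1
        bp <- rep(bin_size, length(bins))
        bp[1] <- (b0 + 1) * bin_size - s
        bp[length(bins)] <- e - b1 * bin_size
        acc[bins + 1] <- acc[bins + 1] + val[i] * bp
      }
    }
    width <- pmin(bin_size, len - (seq_len(nb) - 1) * bin_size)
    acc / width
  })
  names(vals) <- names(chrom_sizes)
  signal_track(vals, bin_size = bin_size, chrom_sizes = chrom_sizes, units = units)
}

#' Write a SignalTrack as bedGraph
#' @param track A `SignalTrack`.
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    len <- track$chrom_sizes[[cn]]
    s <- (seq_along(v) - 1) * track$bin_size
    e <- pmin(s + track$bin_size, len)
    keep <- v != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", cn, as.integer(s[keep]),
                         as.integer(e[keep]),
                         format(v[keep], trim = TRUE, scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}

#' Read DNA sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences over `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(ss))) {
    stop("duplicate record names in ", path)
  }
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences as FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a per-gene expression table and compute RPM
#'
#' Input is a TSV with columns `gene_id` and `count`. RPM (reads per million)
#' is `count / library_size * 1e6`.
#'
#' @param path TSV file.
#' @param library_size Total mapped reads; defaults to `sum(count)`.
#' @return Data frame `gene_id`, `count`, `rpm` with attribute `library_size`.
#' @export
read_expression <- function(path, library_size = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "count") %in% names(tab)))
  if (any(tab$count < 0)) stop("negative counts in ", path)
  if (is.null(library_size)) library_size <- sum(tab$count)
  stopifnot(library_size > 0)
  tab$rpm <- tab$count / library_size * 1e6
  attr(tab, "library_size") <- library_size
  tab
}

#' Write a table as TSV (no quoting, no row names)
#' @param records Data frame.
#' @param path Output file.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
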