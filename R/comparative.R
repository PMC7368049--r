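# Ortholog-locus reconstruction from tabular alignment hits, TSS inference,
# cross-species promoter motif maps, Tamura-Nei 93 distances and
# Nei-Gojobori 86 dN/dS.

#' Read a 12-column tabular alignment hit file (BLAST outfmt 6 dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Subject coordinates with `send < sstart` denote the
#' minus strand; all coordinates are converted to 0-based half-open.
#'
#' @param path Hit file.
#' @return Data frame of `HitRecord`s: `query_id`, `subject_chrom`,
#'   `subject_start`, `subject_end`, `strand`, `qstart`, `qend`, `pident`,
#'   `evalue`, `bitscore`.
#' @export
read_hits <- function(path) {
  cols <- c("query_id", "subject_chrom", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = cols)
  hits <- data.frame(
    query_id = tab$query_id,
    subject_chrom = tab$subject_chrom,
    subject_start = pmin(tab$sstart, tab$send) - 1,
    subject_end = pmax(tab$sstart, tab$send),
    strand = ifelse(tab$send >= tab$sstart, "+", "-"),
    qstart = tab$qstart, qend = tab$qend,
    pident = tab$pident, evalue = tab$evalue, bitscore = tab$bitscore,
    stringsAsFactors = FALSE
  )
  if (any(hits$evalue < 0)) stop("negative E-value in ", path)
  hits
}

#' Chain alignment hits into candidate ortholog loci
#'
#' Hits at least as significant as `evalue_max` are grouped into chains of
#' exon blocks: same subject chromosome, same strand, collinear in query
#' order, separated by at most `max_intron` (the sequence between mapped
#' blocks is treated as intronic). Chains are broken at strand or chromosome
#' changes, query-order violations, subject overlaps, or oversized gaps.
#'
#' @param hits Hit data frame from [read_hits()].
#' @param evalue_max Significance cutoff (default 1e-80; "more significant
#'   than" reading of the validity rule).
#' @param max_intron Maximum allowed gap between consecutive blocks in bp
#'   (default 50 kb).
#' @return List of `OrthologLocus` lists: `query_id`, `chrom`, `strand`,
#'   `blocks` (data frame `start`, `end` ordered by genomic position),
#'   `reciprocal_ok` (`NA` until checked).
#' @export
chain_hits <- function(hits, evalue_max = 1e-80, max_intron = 50000) {
  h <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (!nrow(h)) return(list())
  loci <- list()
  for (key in unique(paste(h$query_id, h$subject_chrom, h$strand, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    g <- h[h$query_id == parts[1L] & h$subject_chrom == parts[2L] &
             h$strand == parts[3L], , drop = FALSE]
    g <- g[order(g$subject_start), , drop = FALSE]
    chain_id <- integer(nrow(g))
    cur <- 1L
    chain_id[1L] <- cur
    if (nrow(g) > 1) for (i in 2:nrow(g)) {
      gap <- g$subject_start[i] - g$subject_end[i - 1]
      collinear <- if (parts[3L] == "+") g$qstart[i] > g$qstart[i - 1]
        else g$qstart[i] < g$qstart[i - 1]
      if (gap < 0 || gap > max_intron || !collinear) cur <- cur + 1L
      chain_id[i] <- cur
    }
    for (cid in unique(chain_id)) {
      b <- g[chain_id == cid, , drop = FALSE]
      loci[[length(loci) + 1L]] <- structure(
        list(query_id = parts[1L], chrom = parts[2L], strand = parts[3L],
             blocks = data.frame(start = b$subject_start, end = b$subject_end),
             reciprocal_ok = NA),
        class = "OrthologLocus")
    }
  }
  loci
}

#' Reconstruct the coding sequence of an ortholog locus
#'
#' Exon-block sequences are concatenated in genomic order; minus-strand loci
#' are reverse-complemented (blocks reversed) so the result reads 5' to 3'.
#'
#' @param locus An `OrthologLocus`.
#' @param genome Named character vector of chromosome sequences.
#' @return DNA string.
#' @export
reconstruct_cds <- function(locus, genome) {
  seq <- genome[[locus$chrom]]
  if (is.null(seq)) stop("no sequence for ", locus$chrom)
  parts <- substring(seq, locus$blocks$start + 1, locus$blocks$end)
  out <- paste(parts, collapse = "")
  if (locus$strand == "-") out <- revcomp(out)
  out
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Reciprocal best-hit check for an ortholog locus
#'
#' The locus is accepted when the top back-alignment hit (highest bitscore,
#' ties broken by E-value) overlaps the original query gene's locus.
#'
#' @param locus An `OrthologLocus` (used for bookkeeping only).
#' @param back_hits Hit data frame of the locus sequence aligned back to the
#'   original genome.
#' @param original One-row interval (`chrom`, `start`, `end`) of the original
#'   query gene.
#' @return `TRUE`/`FALSE`.
#' @export
reciprocal_check <- function(locus, back_hits, original) {
  if (!nrow(back_hits)) return(FALSE)
  ord <- order(-back_hits$bitscore, back_hits$evalue)
  top <- back_hits[ord[1L], ]
  top$subject_chrom == original$chrom &&
    top$subject_start < original$end && original$start < top$subject_end
}

#' Infer a TSS from 5'UTR alignment hits
#'
#' Among hits at least as significant as `evalue_max`, on the gene's strand,
#' whose 3' end lies within `max_dist` of the annotated CDS start (hits
#' slightly overlapping the CDS count as distance 0), the TSS is the 5'-most
#' mapped nucleotide. `NA` when no hit qualifies.
#'
#' @param utr_hits Hit data frame (subject coordinates on the target genome).
#' @param cds_start Strand-aware genomic coordinate of the CDS's 5'-most base
#'   (0-based).
#' @param strand Gene strand on the target genome.
#' @param evalue_max Significance cutoff (default 1e-60).
#' @param max_dist Maximum gap between hit and CDS in nt (default 600).
#' @return TSS coordinate (0-based) or `NA`.
#' @export
infer_tss <- function(utr_hits, cds_start, strand, evalue_max = 1e-60,
                      max_dist = 600) {
  h <- utr_hits[utr_hits$evalue <= evalue_max & utr_hits$strand == strand, ,
                drop = FALSE]
  if (!nrow(h)) return(NA_real_)
  gap <- if (strand == "+") cds_start - h$subject_end
         else h$subject_start - cds_start - 1
  len <- h$subject_end - h$subject_start
  ok <- gap <= max_dist & gap > -len   # upstream of (or abutting/overlapping) CDS
  h <- h[ok, , drop = FALSE]
  if (!nrow(h)) return(NA_real_)
  if (strand == "+") min(h$subject_start) else max(h$subject_end) - 1
}

#' Map motif occurrences across species promoters, anchored at the TSS
#'
#' Promoter sequences must be oriented so that the TSS is at the right end;
#' offsets are then measured upstream from the TSS (a motif ending at the
#' sequence end has offset 0), which makes them invariant under padding on
#' the distal side.
#'
#' @param promoter_seqs Named character vector (or list), one promoter
#'   sequence per species.
#' @param motifs List of `MotifSpec`s.
#' @return Data frame `species`, `motif`, `offset_from_tss`, `strand`;
#'   species lacking a motif contribute no rows.
#' @export
motif_occurrence_map <- function(promoter_seqs, motifs) {
  out <- list()
  for (sp in names(promoter_seqs)) {
    seq <- promoter_seqs[[sp]]
    for (m in motifs) {
      hits <- scan_motif(seq, m)
      if (nrow(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          species = sp, motif = m$name,
          offset_from_tss = nchar(seq) - (hits$offset + nchar(m$consensus)),
          strand = hits$strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(species = character(), motif = character(),
                      offset_from_tss = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Translate a gapless CDS with the standard code; "X" for codons containing N.
translate_cds <- function(cds) {
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(cds),
                          if.fuzzy.codon = "solve")))
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Every protein must equal the conceptual translation of its coding sequence
#' (standard genetic code; a terminal stop codon on the CDS is allowed and
#' dropped). Protein alignment gaps expand to `---` codon gaps, so the result
#' is exactly three times the protein alignment length.
#'
#' @param protein_aln Named character vector of aligned (gapped) protein
#'   sequences, equal lengths.
#' @param cds_seqs Named character vector of the corresponding ungapped CDS.
#' @return A `CodonAlignment`: named character vector of gap-padded coding
#'   sequences, length a multiple of 3.
#' @export
back_translate <- function(protein_aln, cds_seqs) {
  if (length(unique(nchar(protein_aln))) != 1) {
    stop("aligned proteins must all have the same length")
  }
  out <- character(length(protein_aln))
  names(out) <- names(protein_aln)
  for (nm in names(protein_aln)) {
    prot <- toupper(protein_aln[[nm]])
    cds <- toupper(cds_seqs[[nm]])
    if (is.null(cds) || is.na(cds)) stop("no CDS for ", nm)
    res <- gsub("-", "", prot, fixed = TRUE)
    if (nchar(cds) == 3 * (nchar(res) + 1) &&
        translate_cds(substr(cds, nchar(cds) - 2, nchar(cds))) == "*") {
      cds <- substr(cds, 1, nchar(cds) - 3)
    }
    if (nchar(cds) != 3 * nchar(res)) {
      stop("CDS length of ", nm, " (", nchar(cds),
           ") does not match protein length (", nchar(res), " aa)")
    }
    tr <- translate_cds(cds)
    mism <- which(strsplit(tr, "")[[1L]] != strsplit(res, "")[[1L]] &
                    strsplit(tr, "")[[1L]] != "X")
    if (length(mism)) {
      stop("translation mismatch for ", nm, " at protein position ", mism[1L],
           ": CDS gives '", substr(tr, mism[1L], mism[1L]), "', protein has '",
           substr(res, mism[1L], mism[1L]), "'")
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- strsplit(prot, "")[[1L]]
    cod_out <- character(length(aa))
    j <- 0L
    for (k in seq_along(aa)) {
      if (aa[k] == "-") {
        cod_out[k] <- "---"
      } else {
        j <- j + 1L
        cod_out[k] <- codons[j]
      }
    }
    out[nm] <- paste(cod_out, collapse = "")
  }
  structure(out, class = "CodonAlignment")
}

# ---- Tamura-Nei 1993 distance --------------------------------------------

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Closed-form TN93 distance with optional gamma rate-variation correction.
#' Alignment columns containing anything other than A, C, G, T in either
#' sequence are removed first (complete deletion). Base frequencies are the
#' empirical frequencies of the retained columns, pooled over both sequences.
#' Saturated comparisons (log-domain violation) are flagged infinite.
#'
#' @param s1,s2 Aligned DNA strings of equal length (gaps allowed; removed).
#' @param gamma_shape Gamma shape parameter for among-site rate variation
#'   (default 1); `NULL` for the uncorrected distance.
#' @return A `DistanceResult` list: `distance`, `gamma_shape`, `sites_used`,
#'   and the observed proportions `P1` (purine transitions), `P2` (pyrimidine
#'   transitions), `Q` (transversions).
#' @export
tn93_distance <- function(s1, s2, gamma_shape = 1) {
  stopifnot(nchar(s1) == nchar(s2))
  a <- strsplit(toupper(s1), "")[[1L]]
  b <- strsplit(toupper(s2), "")[[1L]]
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 1) stop("no ungapped columns left after complete deletion")
  pi <- (table(factor(a, levels = c("A", "C", "G", "T"))) +
           table(factor(b, levels = c("A", "C", "G", "T")))) / (2 * n)
  pi <- as.numeric(pi); names(pi) <- c("A", "C", "G", "T")
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  if (piR <= 0 || piY <= 0) stop("degenerate base composition (no purines or no pyrimidines)")
  diff <- a != b
  pair <- paste0(pmin(a, b), pmax(a, b))
  P1 <- sum(diff & pair == "AG") / n          # purine transitions
  P2 <- sum(diff & pair == "CT") / n          # pyrimidine transitions
  Q <- sum(diff) / n - P1 - P2                # transversions
  k1 <- 2 * pi["A"] * pi["G"] / piR
  k2 <- 2 * pi["C"] * pi["T"] / piY
  c3 <- 2 * (piR * piY - pi["A"] * pi["G"] * piY / piR -
               pi["C"] * pi["T"] * piR / piY)
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * piR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * piY) else 1
  w3 <- 1 - Q / (2 * piR * piY)
  f <- if (is.null(gamma_shape)) {
    function(w) -log(w)
  } else {
    function(w) gamma_shape * (w^(-1 / gamma_shape) - 1)
  }
  d <- if (w1 <= 0 || w2 <= 0 || w3 <= 0 ||
           (k1 == 0 && P1 > 0) || (k2 == 0 && P2 > 0)) {
    Inf
  } else {
    unname(k1 * f(w1) + k2 * f(w2) + c3 * f(w3))
  }
  structure(list(distance = d,
                 gamma_shape = if (is.null(gamma_shape)) NA_real_ else gamma_shape,
                 sites_used = n, P1 = unname(P1), P2 = unname(P2),
                 Q = unname(Q)),
            class = "DistanceResult")
}

# ---- Nei-Gojobori 1986 dN/dS ---------------------------------------------

# Synonymous/nonsynonymous site fractions of one codon: for each position the
# fraction of the three single-nucleotide changes that preserve the amino
# acid. Changes creating a stop codon count as nonsynonymous.
ng86_codon_sites <- function(codon) {
  aa <- GENCODE[[codon]]
  s <- 0
  nts <- c("A", "C", "G", "T")
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    for (nt in nts[nts != ref]) {
      mut <- codon
      substr(mut, p, p) <- nt
      if (!is.null(GENCODE[[mut]]) && GENCODE[[mut]] != "*" &&
          GENCODE[[mut]] == aa) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# Average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways; pathways through premature stop codons are
# excluded (falling back to all pathways when every one is blocked).
ng86_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1) list(pos) else
    if (length(pos) == 2) list(pos, rev(pos)) else
      list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
           pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  walk <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GENCODE[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (GENCODE[[nxt]] == GENCODE[[cur]] && GENCODE[[nxt]] != "*") {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk, numeric(3))
  open <- res["blocked", ] == 0
  if (!any(open)) open <- rep(TRUE, ncol(res))
  c(sd = mean(res["sd", open]), nd = mean(res["nd", open]))
}

#' Nei-Gojobori (1986) dN/dS between two coding sequences
#'
#' Codon pairs containing gaps or ambiguous bases in either sequence are
#' removed (codon-level complete deletion). Synonymous and nonsynonymous site
#' counts are averaged over the two sequences; differences in multi-hit
#' codons are averaged over all minimal mutational pathways (pathways through
#' premature stop codons excluded). Proportions are corrected with
#' Jukes-Cantor, `d = -3/4 log(1 - 4p/3)`; `p >= 3/4` is flagged infinite.
#'
#' @param s1,s2 Aligned coding sequences (equal length, frame-aligned).
#' @return A `SelectionResult` list: `dN`, `dS`, `ratio` (`NA` when `dS` is
#'   0), `N_sites`, `S_sites`, `N_diffs`, `S_diffs`, `codons_used`.
#' @export
ng86_dnds <- function(s1, s2) {
  stopifnot(nchar(s1) == nchar(s2), nchar(s1) %% 3 == 0)
  s1 <- toupper(s1); s2 <- toupper(s2)
  starts <- seq(1, nchar(s1), by = 3)
  c1 <- substring(s1, starts, starts + 2)
  c2 <- substring(s2, starts, starts + 2)
  ok <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  ok <- ok & vapply(c1, function(x) is.null(GENCODE[[x]]) || GENCODE[[x]] != "*",
                    logical(1), USE.NAMES = FALSE) &
    vapply(c2, function(x) is.null(GENCODE[[x]]) || GENCODE[[x]] != "*",
           logical(1), USE.NAMES = FALSE)
  c1 <- c1[ok]; c2 <- c2[ok]
  if (!length(c1)) stop("no comparable codons after complete deletion")
  S <- (sum(vapply(c1, ng86_codon_sites, numeric(1))) +
          sum(vapply(c2, ng86_codon_sites, numeric(1)))) / 2
  N <- 3 * length(c1) - S
  dd <- vapply(seq_along(c1), function(i) ng86_codon_diffs(c1[i], c2[i]),
               numeric(2))
  Sd <- sum(dd["sd", ]); Nd <- sum(dd["nd", ])
  jc <- function(p) {
    if (p >= 3 / 4) return(Inf)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- if (S > 0) jc(Sd / S) else NA_real_
  dN <- if (N > 0) jc(Nd / N) else NA_real_
  ratio <- if (!is.na(dS) && is.finite(dS) && dS > 0) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, ratio = ratio,
                 N_sites = N, S_sites = S, N_diffs = Nd, S_diffs = Sd,
                 codons_used = length(c1)),
            class = "SelectionResult")
}

# Standard genetic code as a plain environment-free list (from Biostrings).
GENCODE <- as.list(Biostrings::GENETIC_CODE)

# ---- TN93 sequence evolution (for recovery experiments) -------------------

#' Evolve a sequence pair under the TN93 substitution model
#'
#' An ancestor is drawn from the stationary base frequencies and a descendant
#' evolved along a branch of expected length `distance` substitutions/site
#' using the closed-form TN93 transition probabilities. Among-site rate
#' variation is gamma-distributed with the given shape (mean 1), matching the
#' gamma-corrected estimator.
#'
#' @param n_sites Sequence length.
#' @param distance Expected substitutions per site between the two sequences.
#' @param base_freq Stationary frequencies, named `A`, `C`, `G`, `T`.
#' @param kappa1,kappa2 Purine / pyrimidine transition-transversion rate
#'   ratios (alpha1/beta, alpha2/beta; defaults 4).
#' @param gamma_shape Gamma shape for site rates (default 1); `NULL` for
#'   rate-homogeneous sites.
#' @return List with `ancestor` and `derived` DNA strings.
#' @export
simulate_tn93_pair <- function(n_sites, distance,
                               base_freq = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                               kappa1 = 4, kappa2 = 4, gamma_shape = 1) {
  stopifnot(abs(sum(base_freq) - 1) < 1e-8, distance >= 0)
  pi <- base_freq[c("A", "C", "G", "T")]
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  beta <- 1
  a1 <- kappa1 * beta; a2 <- kappa2 * beta
  mu <- 2 * pi["A"] * pi["G"] * a1 + 2 * pi["C"] * pi["T"] * a2 +
    2 * piR * piY * beta
  a1 <- a1 / mu; a2 <- a2 / mu; beta <- beta / mu   # mean rate 1
  nts <- c("A", "C", "G", "T")
  anc <- sample(nts, n_sites, replace = TRUE, prob = pi)
  r <- if (is.null(gamma_shape)) rep(1, n_sites) else
    stats::rgamma(n_sites, shape = gamma_shape, rate = gamma_shape)
  tim <- distance * r
  e2 <- exp(-beta * tim)
  e3R <- exp(-(piR * a1 + piY * beta) * tim)
  e3Y <- exp(-(piY * a2 + piR * beta) * tim)
  pmat <- function(i, j) {
    # P(i -> j | t) vectorised over sites
    if (i == j) {
      if (j %in% c("A", "G")) {
        pi[j] + pi[j] * (piY / piR) * e2 + ((piR - pi[j]) / piR) * e3R
      } else {
        pi[j] + pi[j] * (piR / piY) * e2 + ((piY - pi[j]) / piY) * e3Y
      }
    } else if (i %in% c("A", "G") && j %in% c("A", "G")) {
      pi[j] + pi[j] * (piY / piR) * e2 - (pi[j] / piR) * e3R
    } else if (i %in% c("C", "T") && j %in% c("C", "T")) {
      pi[j] + pi[j] * (piR / piY) * e2 - (pi[j] / piY) * e3Y
    } else {
      pi[j] * (1 - e2)
    }
  }
  der <- character(n_sites)
  u <- stats::runif(n_sites)
  for (b in nts) {
    sel <- anc == b
    if (!any(sel)) next
    probs <- vapply(nts, function(j) {
      p <- pmat(b, j)
      if (length(p) == 1) rep(p, n_sites) else p
    }, numeric(n_sites))
    cum <- t(apply(probs[sel, , drop = FALSE], 1, cumsum))
    pick <- max.col(u[sel] <= cum, ties.method = "first")
    der[sel] <- nts[pick]
  }
  list(ancestor = paste(anc, collapse = ""),
       derived = paste(der, collapse = ""))
}
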