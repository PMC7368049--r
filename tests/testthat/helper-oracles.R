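# Independent oracles, coded separately from the package implementations:
# brute-force enumeration or naive loops only. These define expected values
# for the exact-method tests and must stay free of package internals.

# Two-sided Mann-Whitney P by full enumeration of all C(n1+n2, n1) labelings.
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher exact P by hypergeometric enumeration over all tables
# with the observed margins.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  xs <- max(0, k - r2):min(r1, k)
  probs <- stats::dhyper(xs, r1, r2, k)
  p_obs <- stats::dhyper(a, r1, r2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Codon table for the oracles, built once from the standard code.
.aa_of <- as.character(Biostrings::GENETIC_CODE)
names(.aa_of) <- names(Biostrings::GENETIC_CODE)

# NG86 synonymous site fraction of one codon, naive triple loop. Changes to
# stop codons count as nonsynonymous.
ng86_sites_oracle <- function(codon) {
  s <- 0
  for (p in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (nt == substr(codon, p, p)) next
      mut <- paste0(substr(codon, 1, p - 1), nt, substr(codon, p + 1, 3))
      if (.aa_of[mut] != "*" && .aa_of[mut] == .aa_of[codon]) s <- s + 1 / 3
    }
  }
  s
}

# NG86 pathway differences by recursive depth-first enumeration of all
# orders of the differing positions; pathways through premature stop codons
# are dropped, falling back to all pathways when none survive.
ng86_diffs_oracle <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  paths <- list()
  dfs <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1]] <<- c(sd, nd, blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(c2, p, p),
                    substr(cur, p + 1, 3))
      syn <- .aa_of[nxt] != "*" && .aa_of[nxt] == .aa_of[cur]
      dfs(nxt, setdiff(remaining, p),
          sd + as.numeric(syn), nd + as.numeric(!syn),
          blocked || (.aa_of[nxt] == "*" && nxt != c2))
    }
  }
  dfs(c1, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(mean(m[keep, 1]), mean(m[keep, 2]))
}

# TN93 distance formula coded independently (count-matrix form).
tn93_oracle <- function(s1, s2, shape = 1) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  f <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  for (i in seq_len(n)) f[a[i], b[i]] <- f[a[i], b[i]] + 1
  f <- f / n
  g <- (rowSums(f) + colSums(f)) / 2
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  P1 <- f["A", "G"] + f["G", "A"]
  P2 <- f["C", "T"] + f["T", "C"]
  Q <- f["A", "C"] + f["C", "A"] + f["A", "T"] + f["T", "A"] +
    f["G", "C"] + f["C", "G"] + f["G", "T"] + f["T", "G"]
  k1 <- 2 * g["A"] * g["G"] / gR
  k2 <- 2 * g["C"] * g["T"] / gY
  k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["C"] * g["T"] * gR / gY)
  corr <- function(w) shape * (w^(-1 / shape) - 1)
  unname(k1 * corr(1 - P1 / k1 - Q / (2 * gR)) +
           k2 * corr(1 - P2 / k2 - Q / (2 * gY)) +
           k3 * corr(1 - Q / (2 * gR * gY)))
}

# bedGraph rasterization oracle: per-basepair accumulation, then bin means
# over the full bin width.
raster_oracle <- function(records, bin_size, chrom_len) {
  bp <- numeric(chrom_len)
  for (i in seq_len(nrow(records))) {
    s <- max(0, records$start[i]); e <- min(chrom_len, records$end[i])
    if (e > s) bp[(s + 1):e] <- bp[(s + 1):e] + records$value[i]
  }
  nb <- ceiling(chrom_len / bin_size)
  vapply(seq_len(nb), function(b) {
    lo <- (b - 1) * bin_size + 1
    hi <- min(b * bin_size, chrom_len)
    sum(bp[lo:hi]) / (hi - lo + 1)
  }, numeric(1))
}

# Border-scan oracle: naive loop over window positions in scan order.
border_scan_oracle <- function(bin_vals, bin_size, chrom_len, pericentric_end,
                               window_bp, threshold, min_run, smooth_k) {
  nwin <- ceiling(chrom_len / window_bp)
  w <- vapply(seq_len(nwin), function(k) {
    lo <- (k - 1) * window_bp
    idx <- which((seq_along(bin_vals) - 1) * bin_size >= lo &
                   (seq_along(bin_vals) - 1) * bin_size < lo + window_bp)
    mean(bin_vals[idx])
  }, numeric(1))
  sm <- if (nwin > smooth_k) as.numeric(stats::runmed(w, smooth_k)) else w
  order <- if (pericentric_end == "right") seq_len(nwin) else rev(seq_len(nwin))
  for (pos in seq_len(nwin - min_run + 1)) {
    run <- order[pos:(pos + min_run - 1)]
    if (all(sm[run] >= threshold)) {
      gw <- order[pos]
      return(if (pericentric_end == "right") (gw - 1) * window_bp
             else min(gw * window_bp, chrom_len))
    }
  }
  NA_real_
}

# Small, fast simulation configuration for unit tests (same structure as
# the default stated world, scaled down).
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed, n_genes = 60,
    arms = data.frame(chrom = c("chrA", "chrB"), length = c(3e5, 3e5),
                      pericentric_end = c("right", "left"),
                      border = c(1.8e5, 1.2e5), stringsAsFactors = FALSE),
    chr4 = list(chrom = "chr4", length = 6e4),
    ...)
}

# A tiny hand-built annotation for unit tests.
toy_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000, 5000, 2000), end = c(3000, 7000, 4000),
    strand = c("+", "-", "+"),
    tss = c(1000, 6999, 2000),
    biotype = "protein_coding", stringsAsFactors = FALSE)
}

toy_peakset <- function(rows, label = "BEAF-32") {
  df <- data.frame(chrom = rows$chrom, start = rows$start, end = rows$end,
                   name = NA_character_, score = 0, strand = ".",
                   signal_value = rows$signal_value,
                   summit_offset = if ("summit_offset" %in% names(rows))
                     rows$summit_offset else NA_real_,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), ]
  structure(df, label = label, class = c("PeakSet", "data.frame"))
}
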