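# Seeded generator of a toy genome and all pipeline inputs with planted
# ground truth: chromosome arms with a pericentric block of elevated
# H3K9me3/HP1a fold enrichment, genes on both sides of the border, insulator
# peaks overlapping promoter windows with or without a planted consensus
# motif, per-gene read counts with an above/below 10 RPM split, and a
# differential-expression table with planted direction effects.

#' Simulation configuration with the package's stated-world defaults
#'
#' Defaults emulate the structure of the real analyses: two 1-Mb chromosome
#' arms whose pericentric halves carry ~4-fold H3K9me3/HP1a enrichment
#' (euchromatin ~1-fold), a small entirely heterochromatic dot chromosome,
#' 200 genes, BEAF-32 on ~90% of heterochromatic promoters with ~84% direct
#' binding, GAF on ~half of promoters either side, direct-peak signal median
#' 11 versus 5 for indirect, and a 10-RPM active/inactive expression split.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_genes Total gene count (default 200).
#' @param fe_noise_sd Gaussian noise s.d. on per-bin fold enrichment
#'   (default 0.5).
#' @param ... Overrides for any other element of the returned list.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1, n_genes = 200, fe_noise_sd = 0.5, ...) {
  cfg <- list(
    seed = seed,
    arms = data.frame(
      chrom = c("chrA", "chrB"), length = c(1e6, 1e6),
      pericentric_end = c("right", "left"), border = c(6e5, 4e5),
      stringsAsFactors = FALSE),
    chr4 = list(chrom = "chr4", length = 1.2e5),
    n_genes = n_genes,
    gene_length = 2000,
    gene_spacing = 4000,          # placement grid step
    border_buffer = 15000,        # no gene starts this close to a border
    frac_expressed = 0.8,
    polii_prob = c(expressed = 0.9, silent = 0.05),
    rpm_expressed = c(15, 300),   # log-uniform range, all above the 10 RPM cut
    rpm_silent = c(0, 5),
    library_size = 5e6,
    bin_size = 200,
    fe_eu = 1.0, fe_het = 4.0, fe_hp1a_het = 3.5,
    fe_noise_sd = fe_noise_sd,
    input_level = 9,              # flat input; pseudocount 1 makes FE exact
    occupancy_prob = list(
      `BEAF-32` = c(heterochromatic = 0.90, euchromatic = 0.35),
      GAF = c(heterochromatic = 0.50, euchromatic = 0.49),
      dCTCF = c(heterochromatic = 0.50, euchromatic = 0.25)),
    dref_given_beaf = 0.40,
    direct_prob = c(`BEAF-32` = 0.84, Dref = 0.50),
    signal_meanlog = c(direct = log(11), indirect = log(5),
                       GAF = log(8), dCTCF = log(8), Dref = log(5),
                       PolII = log(10)),
    signal_sdlog = 0.35,
    deg_frac = 0.30,
    deg_up_prob = c(beaf_only = 0.85, gaf_only = 0.15, none = 0.20,
                    other = 0.50),
    deg_logfc = c(0.8, 3.0)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "SimConfig")
}

# Scrub every occurrence of `pattern` (plus-strand literal and its reverse
# complement) inside [start, end) of `seq`, mutating position `break_at`
# (1-based within the match) to a random different base. Re-scans until clean.
scrub_motif <- function(seq, start, end, pattern, break_at = 1L) {
  sub <- substr(seq, start + 1, end)
  pats <- unique(c(pattern, revcomp(pattern)))
  for (iter in 1:50) {
    hit <- NULL
    for (p in pats) {
      m <- gregexpr(p, sub, fixed = TRUE)[[1L]]
      if (m[1L] != -1) { hit <- c(pos = m[1L], len = nchar(p)); break }
    }
    if (is.null(hit)) break
    at <- hit["pos"] + break_at - 1L
    old <- substr(sub, at, at)
    substr(sub, at, at) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  substr(seq, start + 1, end) <- sub
  seq
}

#' Simulate a complete input bundle with planted ground truth
#'
#' Writes FASTA, GFF3, narrowPeak files (BEAF-32, GAF, dCTCF, Dref, PolII),
#' treat+input bedGraph pairs (H3K9me3, HP1a, ATAC), an expression table, a
#' differential-expression table, a `params.json` echo and a `truth.json`
#' ground-truth file into `out_dir`. Deterministic for a fixed seed. Direct
#' peaks have the consensus motif physically written into the genome
#' sequence inside the peak; indirect peaks are scrubbed of chance matches.
#'
#' @param config A `SimConfig` from [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `truth` and `config`.
#' @export
simulate_bundle <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "SimConfig"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(config$seed)
  nts <- c("A", "C", "G", "T")

  chroms <- c(config$arms$chrom, config$chr4$chrom)
  chrom_sizes <- stats::setNames(c(config$arms$length, config$chr4$length), chroms)

  ## -- genes ---------------------------------------------------------------
  gl <- config$gene_length
  place <- function(chrom, len, n, border = NA, buffer = 0) {
    grid <- seq(5000, len - gl - 5000, by = config$gene_spacing)
    if (!is.na(border)) grid <- grid[abs(grid - border) > buffer]
    if (n > length(grid)) stop("cannot place ", n, " genes on ", chrom)
    starts <- sort(sample(grid, n))
    data.frame(chrom = chrom, start = starts, end = starts + gl,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  n_arm <- floor(0.45 * config$n_genes)
  n_chr4 <- config$n_genes - 2 * n_arm
  genes <- rbind(
    place(config$arms$chrom[1], config$arms$length[1], n_arm,
          config$arms$border[1], config$border_buffer),
    place(config$arms$chrom[2], config$arms$length[2], n_arm,
          config$arms$border[2], config$border_buffer),
    place(config$chr4$chrom, config$chr4$length, n_chr4)
  )
  genes$gene_id <- sprintf("%s_g%03d", genes$chrom,
                           stats::ave(seq_len(nrow(genes)), genes$chrom,
                                      FUN = seq_along))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$biotype <- "protein_coding"
  ng <- nrow(genes)

  domains <- domain_map(
    chrom = chroms,
    border = c(config$arms$border, NA),
    pericentric_end = c(config$arms$pericentric_end, "right"),
    whole_chrom_het = c(FALSE, FALSE, TRUE))
  genes$location <- classify_gene_location(genes, domains)

  ## -- expression ----------------------------------------------------------
  expressed <- stats::runif(ng) < config$frac_expressed
  rpm <- ifelse(expressed,
                exp(stats::runif(ng, log(config$rpm_expressed[1]),
                                 log(config$rpm_expressed[2]))),
                stats::runif(ng, config$rpm_silent[1], config$rpm_silent[2]))
  count <- round(rpm * config$library_size / 1e6)
  rpm <- count / config$library_size * 1e6
  polii <- stats::runif(ng) < ifelse(expressed, config$polii_prob["expressed"],
                                     config$polii_prob["silent"])

  ## -- insulator occupancy and binding truth -------------------------------
  fac3 <- names(config$occupancy_prob)
  occ <- list()
  for (f in fac3) {
    p <- config$occupancy_prob[[f]][genes$location]
    occ[[f]] <- stats::runif(ng) < p
  }
  occ[["Dref"]] <- occ[["BEAF-32"]] & stats::runif(ng) < config$dref_given_beaf
  direct <- list(
    `BEAF-32` = occ[["BEAF-32"]] & stats::runif(ng) < config$direct_prob["BEAF-32"],
    Dref = occ[["Dref"]] & stats::runif(ng) < config$direct_prob["Dref"])
  # shared core motif: a direct Dref site implies a direct BEAF-32 site
  direct[["BEAF-32"]] <- direct[["BEAF-32"]] | direct[["Dref"]]

  ## -- peaks ---------------------------------------------------------------
  factors <- c(fac3, "Dref", "PolII")
  peak_rows <- list()
  upstream_off <- function(o, strand, tss) ifelse(strand == "+", tss - o, tss + o)
  for (f in factors) {
    sel <- if (f == "PolII") polii else occ[[f]]
    idx <- which(sel)
    if (!length(idx)) next
    if (f == "PolII") {
      center <- genes$tss[idx]
      hw <- rep(300, length(idx))
      meanlog <- config$signal_meanlog["PolII"]
    } else {
      o <- 100 + round(stats::runif(length(idx), -40, 40))
      center <- upstream_off(o, genes$strand[idx], genes$tss[idx])
      hw <- 125 + round(stats::runif(length(idx), 0, 25))
      meanlog <- if (f == "BEAF-32") {
        ifelse(direct[["BEAF-32"]][idx], config$signal_meanlog["direct"],
               config$signal_meanlog["indirect"])
      } else rep(config$signal_meanlog[f], length(idx))
    }
    start <- pmax(0, center - hw)
    end <- pmin(chrom_sizes[genes$chrom[idx]], center + hw)
    peak_rows[[f]] <- data.frame(
      chrom = genes$chrom[idx], start = start, end = end,
      name = sprintf("%s_%s", gsub("-", "", f), genes$gene_id[idx]),
      score = 0, strand = ".",
      signal_value = round(stats::rlnorm(length(idx), meanlog,
                                         config$signal_sdlog), 3),
      summit_offset = center - start,
      gene_id = genes$gene_id[idx], stringsAsFactors = FALSE)
  }

  # activity truth derives from the emitted Pol II peaks under the same
  # +/-2 kb window rule the classifier applies (a neighbour's peak counts)
  pol <- peak_rows[["PolII"]]
  polii_hit <- vapply(seq_len(ng), function(i) {
    w <- strand_window(genes$tss[i], genes$strand[i], 2000, 2000,
                       chrom_sizes[genes$chrom[i]])
    !is.null(pol) && length(which_overlaps(pol, genes$chrom[i],
                                           w$start, w$end)) > 0
  }, logical(1))
  active <- polii_hit & rpm >= 10

  ## -- genome sequence with planted / scrubbed motifs ----------------------
  genome <- vapply(chroms, function(cn) {
    paste(sample(nts, chrom_sizes[[cn]], replace = TRUE), collapse = "")
  }, character(1))
  plant <- function(gene_i, motif) {
    b <- peak_rows[["BEAF-32"]]
    bi <- which(b$gene_id == genes$gene_id[gene_i])
    lo <- b$start[bi]; hi <- b$end[bi]
    if (motif == "TATCGATA") {
      d <- peak_rows[["Dref"]]
      di <- which(d$gene_id == genes$gene_id[gene_i])
      lo <- max(lo, d$start[di]); hi <- min(hi, d$end[di])
    }
    pos <- floor((lo + hi) / 2) - floor(nchar(motif) / 2)
    cn <- genes$chrom[gene_i]
    s <- genome[[cn]]
    substr(s, pos + 1, pos + nchar(motif)) <- motif
    genome[[cn]] <<- s
    pos
  }
  motif_at <- rep(NA_real_, ng)
  for (i in which(direct[["Dref"]])) motif_at[i] <- plant(i, "TATCGATA")
  for (i in which(direct[["BEAF-32"]] & !direct[["Dref"]])) {
    motif_at[i] <- plant(i, "CGATA")
  }
  # scrub chance matches out of indirect peaks
  for (i in which(occ[["BEAF-32"]] & !direct[["BEAF-32"]])) {
    b <- peak_rows[["BEAF-32"]]
    bi <- which(b$gene_id == genes$gene_id[i])
    genome[[genes$chrom[i]]] <- scrub_motif(genome[[genes$chrom[i]]],
                                            b$start[bi], b$end[bi],
                                            "CGATA", break_at = 3L)
  }
  for (i in which(occ[["Dref"]] & !direct[["Dref"]])) {
    d <- peak_rows[["Dref"]]
    di <- which(d$gene_id == genes$gene_id[i])
    genome[[genes$chrom[i]]] <- scrub_motif(genome[[genes$chrom[i]]],
                                            d$start[di], d$end[di],
                                            "TATCGATA", break_at = 1L)
  }

  ## -- chromatin tracks ----------------------------------------------------
  bs <- config$bin_size
  fe_target <- function(cn) {
    nb <- ceiling(chrom_sizes[[cn]] / bs)
    pos <- (seq_len(nb) - 1) * bs
    if (cn == config$chr4$chrom) return(rep(config$fe_het, nb))
    a <- config$arms[config$arms$chrom == cn, ]
    if (a$pericentric_end == "right") {
      ifelse(pos >= a$border, config$fe_het, config$fe_eu)
    } else {
      ifelse(pos < a$border, config$fe_het, config$fe_eu)
    }
  }
  emit_track_pair <- function(stem, level_by_chrom) {
    tr <- list(); inp <- list()
    for (cn in chroms) {
      fe <- level_by_chrom[[cn]]
      fe_noisy <- pmax(0, fe + stats::rnorm(length(fe), 0, config$fe_noise_sd))
      inp[[cn]] <- rep(config$input_level, length(fe))
      tr[[cn]] <- pmax(0, round((config$input_level + 1) * fe_noisy - 1, 4))
    }
    treat <- signal_track(tr, bs, chrom_sizes, units = "rpm")
    input <- signal_track(inp, bs, chrom_sizes, units = "rpm")
    write_bedgraph(treat, file.path(out_dir, paste0(stem, "_treat.bedgraph")))
    write_bedgraph(input, file.path(out_dir, paste0(stem, "_input.bedgraph")))
  }
  h3 <- lapply(stats::setNames(chroms, chroms), fe_target)
  hp1 <- lapply(h3, function(v) {
    v[v == config$fe_het] <- config$fe_hp1a_het
    v
  })
  atac <- lapply(stats::setNames(chroms, chroms), function(cn) {
    nb <- ceiling(chrom_sizes[[cn]] / bs)
    v <- rep(1, nb)
    for (i in which(active & genes$chrom == cn)) {
      b0 <- max(0, floor((genes$tss[i] - 200) / bs))
      b1 <- min(nb - 1, floor((genes$tss[i] + 200) / bs))
      v[(b0:b1) + 1] <- 6
    }
    v
  })
  emit_track_pair("h3k9me3", h3)
  emit_track_pair("hp1a", hp1)
  emit_track_pair("atac", atac)

  ## -- write remaining files ----------------------------------------------
  write_fasta(genome, file.path(out_dir, "genome.fa"))
  ann <- structure(list(genes = genes[, c("gene_id", "chrom", "start", "end",
                                          "strand", "tss", "biotype")],
                        chrom_sizes = chrom_sizes),
                   class = "GenomeAnnotation")
  write_gff(ann, file.path(out_dir, "annotation.gff3"))
  for (f in factors) {
    pr <- peak_rows[[f]]
    if (is.null(pr)) {
      pr <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                       name = character(), score = numeric(),
                       strand = character(), signal_value = numeric(),
                       summit_offset = numeric(), stringsAsFactors = FALSE)
    }
    pr <- pr[order(pr$chrom, pr$start), , drop = FALSE]
    write_peaks(pr, file.path(out_dir, paste0(gsub("-", "", f), ".narrowPeak")))
  }
  write_table(data.frame(gene_id = genes$gene_id, count = count),
              file.path(out_dir, "expression.tsv"))

  ## -- differential expression ---------------------------------------------
  subset_of <- vapply(seq_len(ng), function(i) {
    present <- c(occ[["BEAF-32"]][i], occ[["dCTCF"]][i], occ[["GAF"]][i])
    if (!any(present)) "none" else
      paste(c("BEAF-32", "dCTCF", "GAF")[present], collapse = "+")
  }, character(1))
  eligible <- log10(pmax(rpm, 0.05)) >= 1
  sig <- eligible & stats::runif(ng) < config$deg_frac
  up_p <- ifelse(subset_of == "BEAF-32", config$deg_up_prob["beaf_only"],
          ifelse(subset_of == "GAF", config$deg_up_prob["gaf_only"],
          ifelse(subset_of == "none", config$deg_up_prob["none"],
                 config$deg_up_prob["other"])))
  dir_up <- stats::runif(ng) < up_p
  logfc <- ifelse(sig,
                  ifelse(dir_up, 1, -1) *
                    stats::runif(ng, config$deg_logfc[1], config$deg_logfc[2]),
                  stats::rnorm(ng, 0, 0.2))
  pval <- ifelse(sig, stats::runif(ng, 1e-6, 0.05), stats::runif(ng, 0.1, 1))
  write_table(data.frame(gene_id = genes$gene_id,
                         logFC = round(logfc, 4),
                         PValue = signif(pval, 4),
                         log10CPM = round(log10(pmax(rpm, 0.05)), 4)),
              file.path(out_dir, "deg.tsv"))

  ## -- truth and params ------------------------------------------------------
  occ_truth <- do.call(rbind, lapply(factors[factors != "PolII"], function(f) {
    data.frame(gene_id = genes$gene_id, factor = f, occupied = occ[[f]],
               binding = if (f %in% names(direct)) {
                 ifelse(!occ[[f]], "absent",
                        ifelse(direct[[f]], "direct", "indirect"))
               } else ifelse(occ[[f]], "unclassified", "absent"),
               stringsAsFactors = FALSE)
  }))
  truth <- list(
    borders = data.frame(chrom = chroms,
                         border = c(config$arms$border, NA),
                         pericentric_end = c(config$arms$pericentric_end, "right"),
                         whole_chrom_het = c(FALSE, FALSE, TRUE),
                         stringsAsFactors = FALSE),
    genes = data.frame(genes[, c("gene_id", "chrom", "strand", "tss",
                                 "location")],
                       rpm = round(rpm, 4), polII_hit = polii_hit, active = active,
                       stringsAsFactors = FALSE),
    occupancy = occ_truth,
    motif_at = data.frame(gene_id = genes$gene_id, offset = motif_at,
                          stringsAsFactors = FALSE),
    deg = data.frame(gene_id = genes$gene_id, significant = sig,
                     direction = ifelse(sig, ifelse(dir_up, "up", "down"),
                                        NA_character_),
                     subset = subset_of, stringsAsFactors = FALSE)
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  params <- list(
    seed = config$seed, library_size = config$library_size,
    bin_size = config$bin_size,
    arms = data.frame(chrom = chroms,
                      pericentric_end = c(config$arms$pericentric_end, "right"),
                      whole_chrom_het = c(FALSE, FALSE, TRUE),
                      stringsAsFactors = FALSE))
  jsonlite::write_json(params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, truth = truth, config = config))
}

#' Read the ground truth of a simulated bundle
#' @param dir Bundle directory.
#' @return The truth list written by [simulate_bundle()].
#' @export
read_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
}

#' Audit a simulated bundle against its own ground truth
#'
#' Re-reads the emitted files with the package's readers and verifies the
#' planted invariants: every direct peak really contains its consensus motif
#' and every indirect peak lacks it; active genes have >= 10 RPM and a Pol II
#' peak at the TSS; occupied genes have a peak overlapping the promoter
#' window. Fails loudly (naming the offending gene/peak) on any mismatch.
#'
#' @param dir Bundle directory.
#' @return Invisibly `TRUE` when every check passes.
#' @export
audit_bundle <- function(dir) {
  truth <- read_truth(dir)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  ann <- read_gff(file.path(dir, "annotation.gff3"),
                  chrom_sizes = stats::setNames(nchar(genome), names(genome)))
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          library_size = params$library_size)
  motifs <- list(`BEAF-32` = motif_spec("BEAF-32", "CGATA"),
                 Dref = motif_spec("Dref", "TATCGATA"))
  fail <- function(...) stop("bundle audit failed: ", ..., call. = FALSE)

  for (f in c("BEAF-32", "Dref")) {
    peaks <- read_peaks(file.path(dir, paste0(gsub("-", "", f), ".narrowPeak")),
                        "narrowPeak", label = f)
    tocc <- truth$occupancy[truth$occupancy$factor == f, ]
    occ <- call_occupancy(ann$genes, peaks, ann$chrom_sizes, factor = f)
    occ <- classify_binding(occ, peaks, genome, motifs[[f]])
    m <- merge(tocc, occ, by = "gene_id", suffixes = c(".truth", ""))
    bad <- which(m$occupied.truth != m$occupied)
    if (length(bad)) fail(f, " occupancy mismatch for gene ", m$gene_id[bad[1L]])
    bad <- which(m$occupied.truth & m$binding.truth != m$binding)
    if (length(bad)) {
      fail(f, " peak of gene ", m$gene_id[bad[1L]], " classified ",
           m$binding[bad[1L]], " but planted ", m$binding.truth[bad[1L]])
    }
  }
  polii <- read_peaks(file.path(dir, "PolII.narrowPeak"), "narrowPeak",
                      label = "PolII")
  m <- merge(truth$genes, expr, by = "gene_id")
  if (any(abs(m$rpm.x - m$rpm.y) > 1e-3)) {
    fail("expression table RPM disagrees with truth for gene ",
         m$gene_id[which(abs(m$rpm.x - m$rpm.y) > 1e-3)[1L]])
  }
  hit <- vapply(seq_len(nrow(ann$genes)), function(i) {
    w <- strand_window(ann$genes$tss[i], ann$genes$strand[i], 2000, 2000,
                       ann$chrom_sizes[ann$genes$chrom[i]])
    length(which_overlaps(polii, ann$genes$chrom[i], w$start, w$end)) > 0
  }, logical(1))
  tg <- truth$genes[match(ann$genes$gene_id, truth$genes$gene_id), ]
  bad <- which(tg$active != (hit & expr$rpm[match(ann$genes$gene_id,
                                                  expr$gene_id)] >= 10))
  if (length(bad)) fail("activity split wrong for gene ", tg$gene_id[bad[1L]])
  invisible(TRUE)
}
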