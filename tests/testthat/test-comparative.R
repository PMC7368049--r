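# Ortholog hit chaining, TSS inference, codon alignments, TN93 and NG86.

hit_row <- function(chrom = "scf1", s = 0, e = 100, strand = "+", ev = 1e-100,
                    q = "prot1", qs = 1, qe = 30, bits = 200) {
  data.frame(query_id = q, subject_chrom = chrom, subject_start = s,
             subject_end = e, strand = strand, qstart = qs, qend = qe,
             pident = 95, evalue = ev, bitscore = bits,
             stringsAsFactors = FALSE)
}

test_that("hit files parse with minus-strand coordinates normalized", {
  f <- tempfile()
  writeLines(c("p1\tscf1\t95.0\t50\t2\t0\t1\t50\t1001\t1150\t1e-90\t180",
               "p1\tscf1\t90.0\t40\t4\t0\t60\t99\t2300\t2181\t1e-85\t150"), f)
  h <- read_hits(f)
  expect_equal(h$subject_start, c(1000, 2180))
  expect_equal(h$subject_end, c(1150, 2300))
  expect_equal(h$strand, c("+", "-"))
})

test_that("hit chaining applies the significance, strand and adjacency rules", {
  # two collinear plus-strand hits 2 kb apart -> one locus with two exons
  h <- rbind(hit_row(s = 1000, e = 1300, qs = 1, qe = 100),
             hit_row(s = 3300, e = 3600, qs = 101, qe = 200))
  loci <- chain_hits(h)
  expect_length(loci, 1)
  expect_equal(nrow(loci[[1]]$blocks), 2)
  expect_equal(loci[[1]]$blocks$start, c(1000, 3300))
  # opposite strands -> two chains
  h2 <- rbind(hit_row(s = 1000, e = 1300), hit_row(s = 3300, e = 3600,
                                                   strand = "-"))
  expect_length(chain_hits(h2), 2)
  # weak E-value excluded entirely
  h3 <- rbind(hit_row(ev = 1e-50))
  expect_length(chain_hits(h3), 0)
  # oversized gap breaks the chain
  h4 <- rbind(hit_row(s = 1000, e = 1300, qs = 1),
              hit_row(s = 90000, e = 90300, qs = 101))
  expect_length(chain_hits(h4), 2)
  # non-collinear query order breaks the chain
  h5 <- rbind(hit_row(s = 1000, e = 1300, qs = 101),
              hit_row(s = 3300, e = 3600, qs = 1))
  expect_length(chain_hits(h5), 2)
})

test_that("CDS reconstruction concatenates exons 5' to 3'", {
  genome <- c(scf1 = paste0("NNNN", "ATGAAA", "gggg", "TTTTAA"))
  genome <- toupper(genome)
  locus <- structure(list(query_id = "q", chrom = "scf1", strand = "+",
                          blocks = data.frame(start = c(4, 14),
                                              end = c(10, 20))),
                     class = "OrthologLocus")
  expect_equal(reconstruct_cds(locus, genome), "ATGAAATTTTAA")
  locus$strand <- "-"
  expect_equal(reconstruct_cds(locus, genome),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("ATGAAATTTTAA"))))
})

test_that("reciprocal best-hit check needs the top back-hit on the origin", {
  locus <- structure(list(query_id = "q", chrom = "scf1", strand = "+",
                          blocks = data.frame(start = 0, end = 10)),
                     class = "OrthologLocus")
  orig <- list(chrom = "chrX", start = 5000, end = 8000)
  back_good <- hit_row(chrom = "chrX", s = 6000, e = 6500, bits = 300)
  back_bad <- hit_row(chrom = "chrX", s = 20000, e = 20500, bits = 500)
  expect_true(reciprocal_check(locus, back_good, orig))
  expect_false(reciprocal_check(locus, back_bad, orig))
  expect_false(reciprocal_check(locus, rbind(back_good, back_bad), orig))
  expect_true(reciprocal_check(locus, rbind(back_good[, ],
                                            transform(back_bad, bitscore = 100)),
                               orig))
  expect_false(reciprocal_check(locus, back_good[0, ], orig))
})

test_that("TSS inference follows the E-value and 600-nt adjacency rules", {
  # plus strand, CDS 5' base at 10000
  ok <- hit_row(s = 9500, e = 9700, ev = 1e-70)       # 300 nt from CDS
  expect_equal(infer_tss(ok, 10000, "+"), 9500)
  expect_true(is.na(infer_tss(hit_row(s = 9500, e = 9700, ev = 1e-50),
                              10000, "+")))           # too weak
  expect_true(is.na(infer_tss(hit_row(s = 9100, e = 9300, ev = 1e-70),
                              10000, "+")))           # 700 nt away
  expect_true(is.na(infer_tss(ok, 10000, "-")))       # wrong strand
  # several qualifying hits: 5'-most mapped nucleotide wins
  two <- rbind(hit_row(s = 9500, e = 9700, ev = 1e-70),
               hit_row(s = 9400, e = 9650, ev = 1e-65))
  expect_equal(infer_tss(two, 10000, "+"), 9400)
  # minus strand mirror: CDS 5' base at 10000, UTR hit just downstream
  mh <- hit_row(s = 10101, e = 10400, strand = "-", ev = 1e-70)
  expect_equal(infer_tss(mh, 10000, "-"), 10399)
})

test_that("motif occurrence maps anchor offsets at the TSS (right end)", {
  motifs <- list(motif_spec("BEAF-32", "CGATA"))
  seqs <- c(sp1 = paste0(strrep("T", 95), "CGATA"),
            sp2 = paste0(strrep("T", 40), "CGATA", strrep("T", 55)),
            sp3 = strrep("T", 100))
  m <- motif_occurrence_map(seqs, motifs)
  expect_equal(m$offset_from_tss[m$species == "sp1"], 0)
  expect_equal(m$offset_from_tss[m$species == "sp2"], 55)
  expect_equal(sum(m$species == "sp3"), 0)
  # padding on the distal side leaves offsets unchanged
  m2 <- motif_occurrence_map(c(sp2 = paste0(strrep("A", 30),
                                            unname(seqs["sp2"]))), motifs)
  expect_equal(m2$offset_from_tss, 55)
})

test_that("back-translation expands protein gaps to codon gaps and validates", {
  aln <- c(a = "MK-F", b = "MKQF")
  cds <- c(a = "ATGAAATTT", b = "ATGAAACAATTT")
  cod <- back_translate(aln, cds)
  expect_equal(unname(cod["a"]), "ATGAAA---TTT")
  expect_equal(unname(cod["b"]), "ATGAAACAATTT")
  expect_equal(unique(nchar(cod)), 3 * nchar(aln[["a"]]))
  # terminal stop codon tolerated
  cod2 <- back_translate(aln, c(a = "ATGAAATTTTAA", b = "ATGAAACAATTT"))
  expect_equal(unname(cod2["a"]), "ATGAAA---TTT")
  # mismatching CDS rejected with a position
  expect_error(back_translate(aln, c(a = "ATGAAAGGG", b = "ATGAAACAATTT")),
               "position 3")
})

test_that("TN93 distance matches the formula oracle and handles deletion", {
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT")$distance, 0)
  # complete deletion drops gapped columns before computation
  r <- tn93_distance("ACGTAC-T", "ACGTACGT")
  expect_equal(r$sites_used, 7)
  expect_equal(r$distance, 0)
  set.seed(31)
  for (rep in 1:10) {
    pr <- simulate_tn93_pair(2000, stats::runif(1, 0.05, 0.6))
    expect_equal(tn93_distance(pr$ancestor, pr$derived, gamma_shape = 1)$distance,
                 tn93_oracle(pr$ancestor, pr$derived, 1), tolerance = 1e-9)
    # symmetry
    expect_equal(tn93_distance(pr$ancestor, pr$derived)$distance,
                 tn93_distance(pr$derived, pr$ancestor)$distance)
  }
})

test_that("TN93 agrees with an established independent implementation", {
  skip_if_not_installed("ape")
  set.seed(32)
  pr <- simulate_tn93_pair(3000, 0.25)
  bin <- ape::as.DNAbin(rbind(strsplit(tolower(pr$ancestor), "")[[1]],
                              strsplit(tolower(pr$derived), "")[[1]]))
  expect_equal(tn93_distance(pr$ancestor, pr$derived, gamma_shape = 1)$distance,
               as.numeric(ape::dist.dna(bin, model = "TN93", gamma = 1)),
               tolerance = 1e-9)
  expect_equal(tn93_distance(pr$ancestor, pr$derived, gamma_shape = NULL)$distance,
               as.numeric(ape::dist.dna(bin, model = "TN93")),
               tolerance = 1e-9)
})

test_that("closed-form TN93 transition probabilities match the rate matrix", {
  skip_if_not_installed("Matrix")
  # compare a one-site evolution distribution against expm of the generator
  pi <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  k <- 4; beta <- 1; a1 <- k; a2 <- k
  mu <- 2 * pi["A"] * pi["G"] * a1 + 2 * pi["C"] * pi["T"] * a2 +
    2 * piR * piY * beta
  a1 <- a1 / mu; a2 <- a2 / mu; beta <- beta / mu
  rate <- function(i, j) {
    ts <- (i %in% c("A", "G") && j %in% c("A", "G")) ||
      (i %in% c("C", "T") && j %in% c("C", "T"))
    unname(pi[j] * if (ts) (if (i %in% c("A", "G")) a1 else a2) else beta)
  }
  nts <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(nts, nts))
  for (i in nts) for (j in nts) if (i != j) Q[i, j] <- rate(i, j)
  diag(Q) <- -rowSums(Q)
  P <- as.matrix(Matrix::expm(Q * 0.3))
  # empirical transition frequencies from the generator at d = 0.3
  set.seed(33)
  pr <- simulate_tn93_pair(2e5, 0.3, base_freq = pi, gamma_shape = NULL)
  a <- strsplit(pr$ancestor, "")[[1]]; b <- strsplit(pr$derived, "")[[1]]
  emp <- prop.table(table(factor(a, nts), factor(b, nts)), 1)
  expect_lt(max(abs(emp - P)), 0.01)
})

test_that("NG86 counting matches spec examples and is symmetric", {
  r <- ng86_dnds("GATTTT", "GACTTT")   # GAT->GAC is Asp->Asp
  expect_equal(r$S_diffs, 1)
  expect_equal(r$N_diffs, 0)
  expect_equal(r$N_sites + r$S_sites, 3 * r$codons_used)
  ident <- ng86_dnds("ATGGCT", "ATGGCT")
  expect_equal(ident$dN, 0)
  expect_equal(ident$dS, 0)
  expect_true(is.na(ident$ratio))      # dS = 0 -> undefined, never 0/0
  # symmetry under sequence swap
  set.seed(41)
  nts <- c("A", "C", "G", "T")
  for (rep in 1:5) {
    repeat {
      s1 <- paste(sample(nts, 30, TRUE), collapse = "")
      s2 <- paste(sample(nts, 30, TRUE), collapse = "")
      ok <- !grepl("TAA|TAG|TGA", substring(s1, seq(1, 28, 3), seq(3, 30, 3)))
      if (all(ok)) break
    }
    a <- ng86_dnds(s1, s2); b <- ng86_dnds(s2, s1)
    expect_equal(a$S_diffs, b$S_diffs)
    expect_equal(a$N_diffs, b$N_diffs)
    expect_equal(a$S_sites, b$S_sites)
  }
  # gapped codons removed at codon level
  g <- ng86_dnds("ATG---TTT", "ATGGCTTTT")
  expect_equal(g$codons_used, 2)
})

test_that("simulated TN93 evolution is recovered by the distance estimator", {
  set.seed(51)
  d_true <- 0.2
  est <- replicate(10, {
    pr <- simulate_tn93_pair(5000, d_true)
    tn93_distance(pr$ancestor, pr$derived)$distance
  })
  expect_lt(sqrt(mean((est / d_true - 1)^2)), 0.1)
})
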