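# Promoter windows, motif scanning, occupancy calls, direct/indirect
# classification, combinatorics and the group tests.

test_that("promoter windows are strand-aware, 200 nt upstream, clipped", {
  w <- promoter_window(1000, "+", 200, 0, 10000)
  expect_equal(c(w$start, w$end), c(800, 1000))
  w <- promoter_window(1999, "-", 200, 0, 10000)
  expect_equal(c(w$start, w$end), c(2000, 2200))
  w <- promoter_window(50, "+", 200, 0, 10000)
  expect_equal(c(w$start, w$end), c(0, 50))
  # per-gene configurable length (100-bp promoter variant)
  w <- promoter_window(1000, "+", 100, 0, 10000)
  expect_equal(c(w$start, w$end), c(900, 1000))
})

test_that("IUPAC motif scan reports all matches on both strands", {
  beaf <- motif_spec("BEAF-32", "CGATA")
  # the BEAF-32 core is contained in the Dref consensus
  m <- scan_motif("TATCGATA", beaf)
  expect_true(any(m$offset == 3 & m$strand == "+"))
  # reverse-complement match
  m <- scan_motif("TATCG", beaf)
  expect_equal(nrow(m), 1)
  expect_equal(m$offset, 0)
  expect_equal(m$strand, "-")
  expect_equal(nrow(scan_motif("", beaf)), 0)
  expect_equal(nrow(scan_motif("AAAAAAA", beaf)), 0)
  # the Dref consensus is its own reverse complement: two strands, one locus
  dref <- motif_spec("Dref", "TATCGATA")
  m <- scan_motif("TATCGATA", dref)
  expect_equal(m$offset, c(0, 0))
  expect_setequal(m$strand, c("+", "-"))
  # IUPAC degeneracy
  m <- scan_motif("GACGTC", motif_spec("x", "GACRTC", scan_both_strands = FALSE))
  expect_equal(m$offset, 0)
  # overlapping matches all reported
  m <- scan_motif("CGATACGATA", motif_spec("x", "CGATA", FALSE))
  expect_equal(m$offset, c(0, 5))
  expect_error(motif_spec("x", "CGA"))
})

test_that("occupancy is >=1 bp window overlap with max-signal peak summary", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = "+", tss = c(1000, 5000))
  peaks <- toy_peakset(data.frame(
    chrom = "chr1", start = c(850, 900, 12000), end = c(950, 980, 12500),
    signal_value = c(5, 9, 3), summit_offset = c(50, 40, NA)))
  occ <- call_occupancy(genes, peaks, c(chr1 = 2e4))
  expect_true(occ$occupied[1])
  expect_equal(occ$peak_signal[1], 9)                  # max rule
  expect_equal(occ$distance_to_tss[1], 1000 - 940)     # summit of best peak
  expect_false(occ$occupied[2])
  expect_identical(occ$binding[2], "absent")

  # extended mode: 10 kb upstream reaches a distal peak, 12 kb does not
  genes3 <- data.frame(gene_id = "g3", chrom = "chr1", strand = "+", tss = 14000)
  expect_false(call_occupancy(genes3, toy_peakset(data.frame(
    chrom = "chr1", start = 1000, end = 1500, signal_value = 2)),
    c(chr1 = 2e4), extended = TRUE)$occupied)
  expect_true(call_occupancy(genes3, toy_peakset(data.frame(
    chrom = "chr1", start = 4500, end = 5000, signal_value = 2)),
    c(chr1 = 2e4), extended = TRUE)$occupied)
})

test_that("binding is direct iff the peak sequence carries the motif", {
  genome <- c(chr1 = paste0(strrep("A", 860), "TTCGATATT", strrep("A", 200)))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 1000)
  peaks <- toy_peakset(data.frame(chrom = "chr1", start = 850, end = 950,
                                  signal_value = 5))
  occ <- call_occupancy(genes, peaks, c(chr1 = unname(nchar(genome))))
  occ <- classify_binding(occ, peaks, genome, motif_spec("BEAF-32", "CGATA"))
  expect_identical(occ$binding, "direct")
  # all-A peak -> indirect
  genome2 <- c(chr1 = strrep("A", 1200))
  occ2 <- classify_binding(call_occupancy(genes, peaks, c(chr1 = 1200)),
                           peaks, genome2, motif_spec("BEAF-32", "CGATA"))
  expect_identical(occ2$binding, "indirect")
  # motif only as reverse complement (TATCG) is still direct
  genome3 <- c(chr1 = paste0(strrep("A", 880), "TATCG", strrep("A", 300)))
  occ3 <- classify_binding(call_occupancy(genes, peaks,
                                          c(chr1 = unname(nchar(genome3)))),
                           peaks, genome3, motif_spec("BEAF-32", "CGATA"))
  expect_identical(occ3$binding, "direct")
})

test_that("occupancy combinations partition the gene set", {
  occ <- rbind(
    data.frame(gene_id = "g1", factor = c("BEAF-32", "GAF", "dCTCF"),
               occupied = c(TRUE, FALSE, FALSE)),
    data.frame(gene_id = "g2", factor = c("BEAF-32", "GAF", "dCTCF"),
               occupied = c(TRUE, TRUE, TRUE)),
    data.frame(gene_id = "g3", factor = c("BEAF-32", "GAF", "dCTCF"),
               occupied = c(FALSE, FALSE, FALSE)))
  v <- occupancy_combinations(occ)
  expect_equal(unname(v["BEAF-32"]), 1)
  expect_equal(unname(v["BEAF-32+GAF+dCTCF"]), 1)
  expect_equal(unname(v["none"]), 1)
  expect_equal(sum(v), 3)
  expect_equal(length(v), 8)
  occ$occupied <- TRUE
  v2 <- occupancy_combinations(occ)
  expect_equal(unname(v2["BEAF-32+GAF+dCTCF"]), 3)
  expect_equal(sum(v2), 3)
})

test_that("Mann-Whitney exact and approximate modes are well calibrated", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 labelings as extreme
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3), mode = "exact")$p_value, 1)
  # exact equals enumeration oracle on random no-tie draws
  set.seed(9)
  for (rep in 1:10) {
    x <- stats::rnorm(sample(2:6, 1)); y <- stats::rnorm(sample(2:6, 1))
    expect_equal(mann_whitney(x, y, "exact")$p_value, mw_enum_oracle(x, y))
  }
  # normal approximation close to exact at n1 = n2 = 30, and to wilcox.test
  set.seed(10)
  x <- stats::rnorm(30); y <- stats::rnorm(30, 0.4)
  pe <- mann_whitney(x, y, "exact")$p_value
  pa <- mann_whitney(x, y, "normal_approx")$p_value
  expect_lt(abs(pe - pa), 0.05)
  expect_equal(pa, stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
  # tie-corrected approximation also matches wilcox.test
  xt <- c(1, 1, 2, 3, 3, 4); yt <- c(2, 2, 3, 4, 4, 5)
  expect_equal(mann_whitney(xt, yt, "normal_approx")$p_value,
               stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
  # degenerate all-equal input
  expect_equal(mann_whitney(c(2, 2), c(2, 2), "normal_approx")$p_value, 1)
})

test_that("group comparison uses occupied records and planted shifts are detected", {
  set.seed(12)
  n <- 40
  occ <- data.frame(
    gene_id = sprintf("g%02d", 1:n), factor = "BEAF-32",
    occupied = rep(c(TRUE, TRUE, FALSE), length.out = n),
    peak_signal = NA_real_,
    binding = NA_character_)
  occ$binding[occ$occupied] <- rep(c("direct", "indirect"),
                                   length.out = sum(occ$occupied))
  occ$peak_signal[occ$occupied] <-
    ifelse(occ$binding[occ$occupied] == "direct",
           stats::rlnorm(sum(occ$occupied), log(11), 0.3),
           stats::rlnorm(sum(occ$occupied), log(5), 0.3))
  res <- compare_groups(occ, occ$binding)
  s <- res$summary
  expect_gt(s$median[s$group == "direct"], s$median[s$group == "indirect"])
  expect_lt(res$tests[["direct vs indirect"]]$p_value, 0.01)
  # two identical groups -> equal medians, P = 1 in exact mode
  occ2 <- occ[occ$occupied, ][1:8, ]
  occ2$peak_signal <- rep(c(3, 7, 11, 15), 2)
  grp <- rep(c("a", "b"), each = 4)
  occ2$peak_signal[grp == "b"] <- c(3, 7, 11, 15)
  res2 <- compare_groups(occ2, grp, mode = "exact")
  expect_equal(res2$summary$median[1], res2$summary$median[2])
  expect_equal(res2$tests[[1]]$p_value, 1)
  # single group -> no tests
  expect_length(compare_groups(occ[occ$binding %in% "direct", ],
                               rep("direct", sum(occ$binding %in% "direct")))$tests,
                0)
})
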