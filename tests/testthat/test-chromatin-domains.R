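# Border delineation, border combination, gene location calls and the
# active-gene filter.

fe_track <- function(v, bin = 2000, chrom = "chrA") {
  vals <- list(v); names(vals) <- chrom
  cs <- stats::setNames(length(v) * bin, chrom)
  signal_track(vals, bin, cs, units = "fold_enrichment")
}

test_that("border lands at the start of the sustained high-enrichment run", {
  # windows 0-99 at FE 1, 100-199 at FE 4 (window_bp = 10 kb, bin 2 kb)
  v <- rep(c(1, 4), each = 500)
  tr <- fe_track(v)
  expect_equal(delineate_border(tr, "chrA", "right", window_bp = 10000), 1e6)
  # fully heterochromatic arm -> border at 0; fully euchromatic -> absent
  expect_equal(delineate_border(fe_track(rep(4, 1000)), "chrA", "right",
                                window_bp = 10000), 0)
  expect_true(is.na(delineate_border(fe_track(rep(1, 1000)), "chrA", "right",
                                     window_bp = 10000)))
  # mirrored arm: pericentric end left
  vl <- rep(c(4, 1), each = 500)
  expect_equal(delineate_border(fe_track(vl), "chrA", "left",
                                window_bp = 10000), 1e6)
})

test_that("border scan matches the naive loop oracle on noisy tracks", {
  set.seed(21)
  for (rep in 1:20) {
    true_border_win <- sample(20:80, 1)
    end <- sample(c("right", "left"), 1)
    nwin <- 100
    fe_w <- rep(1, nwin)
    het <- if (end == "right") true_border_win:nwin else 1:true_border_win
    fe_w[het] <- 4
    v <- pmax(0, rep(fe_w, each = 5) + stats::rnorm(nwin * 5, 0, 0.5))
    tr <- fe_track(v, bin = 2000)
    got <- delineate_border(tr, "chrA", end, window_bp = 10000)
    want <- border_scan_oracle(v, 2000, 1e6, end, 10000, 2, 10, 5)
    expect_equal(got, want)
  }
})

test_that("border is monotone in the threshold (heterochromatin shrinks)", {
  set.seed(5)
  v <- pmax(0, rep(c(1, 2.5, 4), times = c(400, 100, 500)) +
              stats::rnorm(1000, 0, 0.3))
  tr <- fe_track(v)
  bords <- vapply(c(1.5, 2, 2.5, 3),
                  function(th) delineate_border(tr, "chrA", "right",
                                                window_bp = 10000,
                                                threshold = th),
                  numeric(1))
  expect_true(all(diff(bords) >= 0))  # border never moves toward telomere
})

test_that("synthetic two-domain recovery within one window at noise 0.5", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    bwin <- 60
    v <- pmax(0, rep(c(1, 4), times = c((bwin - 1) * 5, (100 - bwin + 1) * 5)) +
                stats::rnorm(500, 0, 0.5))
    b <- delineate_border(fe_track(v), "chrA", "right", window_bp = 10000)
    if (!is.na(b) && abs(b - (bwin - 1) * 10000) <= 10000) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("short arms yield an absent border with a warning", {
  expect_warning(b <- delineate_border(fe_track(rep(4, 20)), "chrA", "right",
                                       window_bp = 10000), "min_run")
  expect_true(is.na(b))
})

test_that("combine_borders follows the policy definitions", {
  expect_equal(combine_borders(1e6, 1e6, "outermost", "right"), 1e6)
  expect_equal(combine_borders(1e6, 1.2e6, "outermost", "right"), 1e6)
  expect_equal(combine_borders(1e6, 1.2e6, "innermost", "right"), 1.2e6)
  expect_equal(combine_borders(1e6, 1.2e6, "outermost", "left"), 1.2e6)
  expect_equal(combine_borders(1e6, NA, "outermost", "right"), 1e6)
  expect_equal(combine_borders(1e6, 1.2e6, "h3k9me3_only", "right"), 1e6)
  expect_true(is.na(combine_borders(NA, NA, "outermost", "right")))
})

test_that("gene location is a partition with the fixed tie rule and chr4 override", {
  dm <- domain_map(c("chrA", "chrB", "chr4"), c(5e5, 3e5, NA),
                   c("right", "left", "right"), c(FALSE, FALSE, TRUE))
  genes <- data.frame(
    gene_id = letters[1:6],
    chrom = c("chrA", "chrA", "chrA", "chrB", "chr4", "chrB"),
    tss = c(499999, 500000, 500001, 300000, 10, 300001))
  loc <- classify_gene_location(genes, dm)
  expect_equal(loc, c("euchromatic", "heterochromatic", "heterochromatic",
                      "heterochromatic", "heterochromatic", "euchromatic"))
  expect_true(all(loc %in% c("euchromatic", "heterochromatic")))
  expect_error(classify_gene_location(
    data.frame(gene_id = "x", chrom = "chrZ", tss = 1), dm), "chrZ")
  expect_error(domain_map("chr4", 100, "right", TRUE))  # invariant
})

test_that("active-gene selection needs a Pol II peak and >= 10 RPM", {
  ann <- structure(list(genes = toy_genes(),
                        chrom_sizes = c(chr1 = 10000, chr2 = 10000)),
                   class = "GenomeAnnotation")
  dm <- domain_map(c("chr1", "chr2"), c(0, NA), c("right", "right"),
                   c(FALSE, FALSE))  # chr1 fully het, chr2 eu
  pol <- toy_peakset(data.frame(chrom = c("chr1", "chr2"),
                                start = c(900, 1900), end = c(1100, 2100),
                                signal_value = c(5, 5)), label = "PolII")
  expr <- data.frame(gene_id = c("gA", "gB", "gC"), count = 0,
                     rpm = c(12, 50, 5))
  calls <- select_active_het_genes(ann, dm, pol, expr)
  expect_equal(calls$active[calls$gene_id == "gA"], TRUE)   # peak + 12 RPM
  expect_equal(calls$active[calls$gene_id == "gB"], FALSE)  # 50 RPM, no peak
  expect_equal(calls$active[calls$gene_id == "gC"], FALSE)  # peak, 5 RPM
  expect_equal(calls$location, c("heterochromatic", "heterochromatic",
                                 "euchromatic"))
  # missing expression rows -> 0 RPM
  calls2 <- select_active_het_genes(ann, dm, pol, expr[1, , drop = FALSE])
  expect_equal(calls2$rpm[calls2$gene_id == "gB"], 0)
})
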