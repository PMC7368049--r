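# End-to-end orchestration: ingest -> enrichment -> boundary -> classify ->
# occupancy -> deg-assoc, with a machine-readable summary report.

#' Default pipeline parameters
#'
#' All thresholds of the analysis in one list: 200-nt promoter window, 10 RPM
#' activity cut, DEG thresholds P <= 0.05 at >= 1 log10 CPM, border knobs
#' (10-kb windows, fold-enrichment threshold 2 sustained over 10 windows,
#' running median 5), BEAF-32/Dref consensus motifs, extended-mode windows
#' (10 kb upstream / 2 kb downstream).
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(
    bin_size = 200,
    window_bp = 10000, border_threshold = 2.0, min_run = 10, smooth_k = 5,
    border_policy = "outermost",
    promoter_upstream = 200, promoter_downstream = 0,
    min_rpm = 10, polII_up = 2000, polII_down = 2000,
    alpha = 0.05, min_expr = 1.0,
    pseudocount = 1.0,
    extended = FALSE, ext_up = 10000, ext_down = 2000,
    motifs = list(`BEAF-32` = "CGATA", Dref = "TATCGATA"),
    venn_factors = c("BEAF-32", "GAF", "dCTCF"),
    deg_factors = c("BEAF-32", "dCTCF", "GAF")
  )
}

#' Build a pipeline configuration for a simulated bundle directory
#'
#' @param dir Directory written by [simulate_bundle()].
#' @param params Parameter overrides merged over [default_params()].
#' @return A `PipelineConfig` list (`paths`, `arms`, `params`,
#'   `library_size`).
#' @export
bundle_config <- function(dir, params = list()) {
  meta <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  p <- default_params()
  p[names(params)] <- params
  p$bin_size <- meta$bin_size
  structure(list(
    paths = list(
      gff = file.path(dir, "annotation.gff3"),
      fasta = file.path(dir, "genome.fa"),
      expression = file.path(dir, "expression.tsv"),
      deg = file.path(dir, "deg.tsv"),
      peaks = list(`BEAF-32` = file.path(dir, "BEAF32.narrowPeak"),
                   GAF = file.path(dir, "GAF.narrowPeak"),
                   dCTCF = file.path(dir, "dCTCF.narrowPeak"),
                   Dref = file.path(dir, "Dref.narrowPeak"),
                   PolII = file.path(dir, "PolII.narrowPeak")),
      tracks = list(
        h3k9me3 = list(treat = file.path(dir, "h3k9me3_treat.bedgraph"),
                       input = file.path(dir, "h3k9me3_input.bedgraph")),
        hp1a = list(treat = file.path(dir, "hp1a_treat.bedgraph"),
                    input = file.path(dir, "hp1a_input.bedgraph")))),
    arms = meta$arms,
    library_size = meta$library_size,
    params = p), class = "PipelineConfig")
}

#' Run the whole analysis pipeline
#'
#' Stages run in dependency order: ingest, input-normalized enrichment,
#' border delineation per arm, gene location/activity classification,
#' promoter insulator occupancy with direct/indirect calls and group
#' comparisons, and DEG-occupancy association. Every threshold is echoed
#' into the report for provenance. The run is deterministic: identical
#' inputs and configuration give an identical report.
#'
#' @param config A `PipelineConfig` (see [bundle_config()]).
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @param quiet Suppress stage messages (default TRUE).
#' @return A `SummaryReport` list.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  p <- config$params
  say <- function(...) if (!quiet) message("[hetinsul] ", ...)
  missing <- Filter(function(f) !file.exists(f),
                    c(unlist(config$paths[c("gff", "fasta", "expression", "deg")]),
                      unlist(config$paths$peaks), unlist(config$paths$tracks)))
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }

  say("ingest")
  genome <- read_fasta(config$paths$fasta)
  chrom_sizes <- stats::setNames(nchar(genome), names(genome))
  ann <- read_gff(config$paths$gff, chrom_sizes = chrom_sizes)
  expr <- read_expression(config$paths$expression,
                          library_size = config$library_size)
  deg_tab <- read_deg(config$paths$deg)
  peaks <- lapply(names(config$paths$peaks), function(f) {
    read_peaks(config$paths$peaks[[f]], "narrowPeak", label = f)
  })
  names(peaks) <- names(config$paths$peaks)

  say("enrichment")
  fe <- lapply(config$paths$tracks, function(tp) {
    fold_enrichment(
      read_bedgraph(tp$treat, p$bin_size, chrom_sizes, units = "rpm"),
      read_bedgraph(tp$input, p$bin_size, chrom_sizes, units = "rpm"),
      pseudocount = p$pseudocount)
  })

  say("boundary")
  arms <- config$arms
  borders <- vapply(seq_len(nrow(arms)), function(i) {
    if (isTRUE(arms$whole_chrom_het[i])) return(NA_real_)
    b_marks <- vapply(fe, function(tr) {
      delineate_border(tr, arms$chrom[i], arms$pericentric_end[i],
                       window_bp = p$window_bp, threshold = p$border_threshold,
                       min_run = p$min_run, smooth_k = p$smooth_k)
    }, numeric(1))
    combine_borders(b_marks[["h3k9me3"]],
                    if ("hp1a" %in% names(b_marks)) b_marks[["hp1a"]] else NA,
                    policy = p$border_policy,
                    pericentric_end = arms$pericentric_end[i])
  }, numeric(1))
  domains <- domain_map(arms$chrom, borders, arms$pericentric_end,
                        arms$whole_chrom_het)

  say("classify-genes")
  calls <- select_active_het_genes(ann, domains, peaks$PolII, expr,
                                   min_rpm = p$min_rpm, polII_up = p$polII_up,
                                   polII_down = p$polII_down)
  het_active <- calls$gene_id[calls$location == "heterochromatic" & calls$active]
  eu_active <- calls$gene_id[calls$location == "euchromatic" & calls$active]

  say("occupancy")
  insulators <- setdiff(names(peaks), "PolII")
  occ_list <- lapply(insulators, function(f) {
    oc <- call_occupancy(ann$genes, peaks[[f]], chrom_sizes,
                         upstream = p$promoter_upstream,
                         downstream = p$promoter_downstream,
                         extended = p$extended, ext_up = p$ext_up,
                         ext_down = p$ext_down, factor = f)
    if (f %in% names(p$motifs)) {
      oc <- classify_binding(oc, peaks[[f]], genome,
                             motif_spec(f, p$motifs[[f]]))
    }
    oc
  })
  occupancy <- do.call(rbind, occ_list)
  het_occ <- occupancy[occupancy$gene_id %in% het_active, ]
  venn <- occupancy_combinations(het_occ, factors = p$venn_factors)

  beaf_het <- het_occ[het_occ$factor == "BEAF-32", ]
  beaf_all <- occupancy[occupancy$factor == "BEAF-32", ]
  direct_vs_indirect <- if (sum(beaf_het$binding == "direct", na.rm = TRUE) &&
                            sum(beaf_het$binding == "indirect", na.rm = TRUE)) {
    compare_groups(beaf_het[beaf_het$occupied, ],
                   beaf_het$binding[beaf_het$occupied])
  } else NULL
  loc_of <- calls$location[match(beaf_all$gene_id, calls$gene_id)]
  act <- calls$active[match(beaf_all$gene_id, calls$gene_id)]
  het_vs_eu <- {
    sel <- beaf_all$occupied & act
    if (length(unique(loc_of[sel])) == 2) {
      compare_groups(beaf_all[sel, ], loc_of[sel])
    } else NULL
  }
  occ_frac <- vapply(insulators, function(f) {
    of <- occupancy[occupancy$factor == f, ]
    c(het = mean(of$occupied[of$gene_id %in% het_active]),
      eu = mean(of$occupied[of$gene_id %in% eu_active]))
  }, numeric(2))
  dref_het <- het_occ[het_occ$factor == "Dref", ]
  dref_beaf_overlap <- sum(dref_het$occupied &
                             beaf_het$occupied[match(dref_het$gene_id,
                                                     beaf_het$gene_id)])
  dref_motifless <- sum(dref_het$occupied & dref_het$binding == "indirect",
                        na.rm = TRUE)

  say("deg-assoc")
  degs <- filter_deg(deg_tab, alpha = p$alpha, min_expr = p$min_expr)
  grp <- group_by_occupancy(degs, occupancy, factors = p$deg_factors)
  single <- lapply(stats::setNames(p$deg_factors, p$deg_factors), function(f) {
    grp$membership$gene_id[grp$membership$subset == f]
  })
  names(single) <- paste0(names(single), " only")
  trend_groups <- c(single, grp$groups[c("two", "three", "none")])
  trends <- group_trends(trend_groups, degs)

  report <- structure(list(
    params = p,
    n_genes = nrow(ann$genes),
    borders = data.frame(chrom = arms$chrom, border = borders,
                         pericentric_end = arms$pericentric_end,
                         whole_chrom_het = arms$whole_chrom_het,
                         stringsAsFactors = FALSE),
    n_heterochromatic = sum(calls$location == "heterochromatic"),
    n_euchromatic = sum(calls$location == "euchromatic"),
    n_het_active = length(het_active),
    n_eu_active = length(eu_active),
    venn = venn,
    occupancy_fraction = occ_frac,
    beaf_direct_n = sum(beaf_het$binding == "direct", na.rm = TRUE),
    beaf_occupied_het_n = sum(beaf_het$occupied),
    direct_vs_indirect = direct_vs_indirect,
    het_vs_eu_signal = het_vs_eu,
    dref_occupied_het_n = sum(dref_het$occupied),
    dref_beaf_overlap_n = dref_beaf_overlap,
    dref_motifless_n = dref_motifless,
    n_deg = nrow(degs),
    n_deg_grouped = nrow(grp$membership),
    n_deg_unannotated = grp$n_unannotated,
    deg_subsets = grp$subsets,
    deg_trends = trends,
    gene_calls = calls,
    occupancy = occupancy,
    degs = degs
  ), class = "SummaryReport")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_table(calls, file.path(out_dir, "gene_calls.tsv"))
    write_table(occupancy[, setdiff(names(occupancy), "peak_row")],
                file.path(out_dir, "occupancy.tsv"))
    write_table(degs, file.path(out_dir, "deg_filtered.tsv"))
    jsonlite::write_json(list(venn = as.list(venn),
                              deg_subsets = as.list(grp$subsets)),
                         file.path(out_dir, "venn.json"), auto_unbox = TRUE)
    jsonlite::write_json(summarize_report(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

# Flat, JSON-friendly view of a report (scalars and small tables only).
summarize_report <- function(report) {
  tst <- function(t) if (is.null(t)) NULL else
    list(medians = t$summary$median, groups = t$summary$group,
         n = t$summary$n,
         p = vapply(t$tests, function(x) x$p_value, numeric(1)))
  list(
    params = report$params[setdiff(names(report$params), "motifs")],
    motifs = report$params$motifs,
    n_genes = report$n_genes,
    borders = report$borders,
    n_heterochromatic = report$n_heterochromatic,
    n_euchromatic = report$n_euchromatic,
    n_het_active = report$n_het_active,
    n_eu_active = report$n_eu_active,
    venn = as.list(report$venn),
    beaf_direct_n = report$beaf_direct_n,
    beaf_occupied_het_n = report$beaf_occupied_het_n,
    direct_vs_indirect = tst(report$direct_vs_indirect),
    het_vs_eu_signal = tst(report$het_vs_eu_signal),
    dref = list(occupied = report$dref_occupied_het_n,
                beaf_overlap = report$dref_beaf_overlap_n,
                motifless = report$dref_motifless_n),
    n_deg = report$n_deg,
    n_deg_grouped = report$n_deg_grouped,
    n_deg_unannotated = report$n_deg_unannotated,
    deg_subsets = as.list(report$deg_subsets),
    deg_trends = list(summary = report$deg_trends$summary,
                      p = vapply(report$deg_trends$tests,
                                 function(x) x$p_value, numeric(1)))
  )
}

#' @export
print.SummaryReport <- function(x, ...) {
  cat("hetinsul pipeline report\n")
  cat("  genes: ", x$n_genes, " (", x$n_heterochromatic, " het / ",
      x$n_euchromatic, " eu); active het: ", x$n_het_active, "\n", sep = "")
  cat("  BEAF-32 on active het promoters: ", x$beaf_occupied_het_n, " (",
      x$beaf_direct_n, " direct)\n", sep = "")
  if (!is.null(x$direct_vs_indirect)) {
    s <- x$direct_vs_indirect$summary
    cat("  direct vs indirect medians: ",
        paste(sprintf("%s=%g", s$group, s$median), collapse = ", "),
        "; P = ", format(x$direct_vs_indirect$tests[[1]]$p_value, digits = 3),
        "\n", sep = "")
  }
  cat("  DEG: ", x$n_deg, " significant (", x$n_deg_grouped, " grouped + ",
      x$n_deg_unannotated, " unannotated)\n", sep = "")
  invisible(x)
}

#' Score pipeline recovery against a simulated bundle's ground truth
#'
#' Runs the pipeline on a bundle and compares against the planted truth:
#' maximal border error in windows, eu/het location accuracy, promoter
#' occupancy accuracy over all insulator factors, direct/indirect binding
#' accuracy over classified occupied promoters, and the Mann-Whitney P for
#' the planted direct-versus-indirect signal shift.
#'
#' @param dir Bundle directory from [simulate_bundle()].
#' @param params Optional parameter overrides.
#' @return List: `border_err_windows`, `location_accuracy`,
#'   `occupancy_accuracy`, `binding_accuracy`, `direct_vs_indirect_p`,
#'   `report`.
#' @export
evaluate_recovery <- function(dir, params = list()) {
  truth <- read_truth(dir)
  report <- run_pipeline(bundle_config(dir, params))
  p <- report$params

  b <- merge(report$borders, truth$borders, by = "chrom",
             suffixes = c("", ".true"))
  b <- b[!b$whole_chrom_het, ]
  border_err <- max(abs(b$border - b$border.true) / p$window_bp)

  g <- merge(report$gene_calls, truth$genes, by = "gene_id",
             suffixes = c("", ".true"))
  loc_acc <- mean(g$location == g$location.true)

  occ <- merge(report$occupancy, truth$occupancy, by = c("gene_id", "factor"),
               suffixes = c("", ".true"))
  occ_acc <- mean(occ$occupied == occ$occupied.true)
  cls <- occ[occ$factor %in% c("BEAF-32", "Dref") & occ$occupied &
               occ$occupied.true, ]
  bind_acc <- if (nrow(cls)) mean(cls$binding == cls$binding.true) else NA_real_
  dvi_p <- if (!is.null(report$direct_vs_indirect)) {
    report$direct_vs_indirect$tests[[1]]$p_value
  } else NA_real_
  list(border_err_windows = border_err, location_accuracy = loc_acc,
       occupancy_accuracy = occ_acc, binding_accuracy = bind_acc,
       direct_vs_indirect_p = dvi_p, report = report)
}
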