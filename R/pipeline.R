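#' Run the full two-pool association pipeline
#'
#' Orchestrates the stages end-to-end: read the pooled VCF, fit the ED
#' genome scan per variant class, call associated regions per class,
#' intersect the SNP- and InDel-derived region sets, annotate the
#' intersection with genes, and overlap it with the filtered
#' differential-expression results.  All intermediate tables are written
#' to `out_dir` (if given) together with a machine-readable JSON report;
#' identical inputs and parameters give byte-identical outputs.
#'
#' @param vcf,gff,de_table Paths to the pooled VCF, GFF3 gene models and
#'   DE results table.
#' @param out_dir Output directory; `NULL` skips file output.
#' @param pool_ms,pool_217 VCF sample names of the two pools.
#' @param min_pool_depth Site filter of [read_pooled_vcf()].
#' @param power_k,bandwidth,kernel,multiplier,robust,on_frequencies
#'   Scan parameters, see [ed_scan()].
#' @param merge_gap,min_markers,bin_bp Region-calling parameters, see
#'   [call_regions()].
#' @param fc_threshold,padj_max DEG filter parameters, see
#'   [filter_degs()].
#' @return Object of class `"bsa_report"`: retained site counts per
#'   class, per-class thresholds and region sets, intersection regions
#'   with sizes (Mb) and gene counts, the DEG direction summary and
#'   inside/outside counts, the full parameter set and its hash.
#' @examples
#' \donttest{
#' cfg <- simulation_config(chromosomes = c(A09 = 5e6),
#'   causal_regions = data.frame(chrom = "A09", start = 2e6, end = 3e6),
#'   n_genes = 500, n_degs = 30)
#' d <- simulate_bsa_dataset(cfg, tempfile("bsa"))
#' rep <- run_pipeline(d$vcf, d$gff3, d$deg, bandwidth = 5e5)
#' rep
#' }
#' @export
run_pipeline <- function(vcf, gff, de_table, out_dir = NULL,
                         pool_ms = "zws_ms", pool_217 = "zws_217",
                         min_pool_depth = 4,
                         power_k = 5, bandwidth = 1e6, kernel = "tricube",
                         multiplier = 3, robust = TRUE,
                         on_frequencies = TRUE,
                         merge_gap = 2e5, min_markers = 10, bin_bp = 1e4,
                         fc_threshold = 4, padj_max = 0.01) {
  params <- list(pool_ms = pool_ms, pool_217 = pool_217,
                 min_pool_depth = min_pool_depth, power_k = power_k,
                 bandwidth = bandwidth, kernel = kernel,
                 multiplier = multiplier, robust = robust,
                 on_frequencies = on_frequencies, merge_gap = merge_gap,
                 min_markers = min_markers, bin_bp = bin_bp,
                 fc_threshold = fc_threshold, padj_max = padj_max)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sites <- stage("variant_io",
                 read_pooled_vcf(vcf, pool_ms, pool_217, min_pool_depth))
  if (nrow(sites) == 0L) stop("pipeline stage 'variant_io' failed: no usable sites")

  fit <- stage("ed_association",
               ed_scan(sites, power_k = power_k, bandwidth = bandwidth,
                       kernel = kernel, multiplier = multiplier,
                       robust = robust, on_frequencies = on_frequencies))

  classes <- intersect(c("SNP", "InDel"), unique(fit$sites$class))
  regions <- stage("region_calling", {
    r <- lapply(classes, function(cl)
      call_regions(fit, class = cl, merge_gap = merge_gap,
                   min_markers = min_markers, bin_bp = bin_bp))
    names(r) <- classes
    r
  })

  intersection <- stage("intersection", {
    if (length(classes) == 2L)
      intersect_region_sets(regions[["SNP"]], regions[["InDel"]])
    else new_regions()
  })

  annotation <- stage("annotation", {
    genes <- read_gene_models(gff)
    annotate_regions_with_genes(intersection, genes)
  })

  deg <- stage("deg_overlap", {
    all_degs <- read_deg_table(de_table)
    kept <- filter_degs(all_degs, fc_threshold, padj_max)
    ov <- overlap_degs_with_regions(kept, intersection)
    list(kept = kept, inside = ov$inside, outside = ov$outside,
         summary = summarize_direction(kept))
  })

  report <- structure(list(
    n_sites = vapply(classes, function(cl) sum(sites$class == cl),
                     integer(1)),
    n_dropped = attr(sites, "n_dropped"),
    thresholds = lapply(fit$thresholds, function(t) t$threshold),
    regions = regions,
    intersection = annotation,
    intersection_sizes_mb = region_size_mb(annotation),
    total_intersection_mb = sum(region_size_mb(annotation)),
    n_genes_per_region = annotation$n_genes,
    n_genes_total = sum(annotation$n_genes),
    deg = list(n_total = deg$summary$n_total, n_up = deg$summary$n_up,
               n_down = deg$summary$n_down,
               pct_up = deg$summary$pct_up,
               pct_down = deg$summary$pct_down,
               n_inside = nrow(deg$inside), n_outside = nrow(deg$outside)),
    params = params,
    out_dir = out_dir), class = "bsa_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    params_path <- file.path(out_dir, "params.json")
    jsonlite::write_json(params, params_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    report$config_hash <- unname(tools::md5sum(params_path))
    write_site_table(fit, file.path(out_dir, "sites.tsv"))
    for (cl in classes)
      write_regions_bed(regions[[cl]],
                        file.path(out_dir, sprintf("regions_%s.bed", cl)))
    write_regions_bed(intersection,
                      file.path(out_dir, "regions_intersection.bed"))
    ann_tab <- data.frame(chrom = annotation$chrom,
                          start = annotation$start, end = annotation$end,
                          size_mb = region_size_mb(annotation),
                          n_genes = annotation$n_genes,
                          gene_ids = vapply(annotation$gene_ids, paste,
                                            "", collapse = ","))
    con <- file(file.path(out_dir, "region_genes.tsv"), "w")
    writeLines(paste0("#", paste(names(ann_tab), collapse = "\t")), con)
    utils::write.table(ann_tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    write_deg_table(deg$inside, file.path(out_dir, "degs_inside.tsv"))
    write_deg_table(deg$outside, file.path(out_dir, "degs_outside.tsv"))
    json_report <- report
    json_report$out_dir <- NULL   # keep reports location-independent
    json_report$regions <- lapply(json_report$regions, as.data.frame)
    json_report$intersection <-
      as.data.frame(json_report$intersection[
        setdiff(names(json_report$intersection), "gene_ids")])
    jsonlite::write_json(unclass(json_report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.bsa_report <- function(x, ...) {
  cat("Two-pool ED association pipeline report\n")
  cat(sprintf("  retained sites: %s (dropped %d)\n",
              paste(sprintf("%s %d", names(x$n_sites), x$n_sites),
                    collapse = ", "), x$n_dropped))
  for (cl in names(x$thresholds))
    cat(sprintf("  %-6s threshold %.6g, %d region(s)\n", cl,
                x$thresholds[[cl]],
                if (cl %in% names(x$regions)) nrow(x$regions[[cl]]) else 0L))
  cat(sprintf("  intersection: %d region(s), %.4g Mb, %d gene(s)\n",
              nrow(x$intersection), x$total_intersection_mb,
              x$n_genes_total))
  for (i in seq_len(nrow(x$intersection)))
    cat(sprintf("    %s %d-%d  %.4g Mb  %d genes\n",
                x$intersection$chrom[i], x$intersection$start[i],
                x$intersection$end[i], x$intersection_sizes_mb[i],
                x$n_genes_per_region[i]))
  d <- x$deg
  if (d$n_total > 0L) {
    cat(sprintf("  DEGs: %d (%d up %.2f%%, %d down %.2f%%), %d inside / %d outside regions\n",
                d$n_total, d$n_up, d$pct_up, d$n_down, d$pct_down,
                d$n_inside, d$n_outside))
  } else {
    cat("  DEGs: none passing filters\n")
  }
  invisible(x)
}
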