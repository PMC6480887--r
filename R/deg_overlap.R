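#' Read a differential-expression results table
#'
#' Tab-separated input with columns `gene_id`, `chrom`, `start`, `end`,
#' `log2fc`, `padj` (commented header lines starting with `#` allowed,
#' as written by [write_deg_table()]).
#'
#' @param path Path to the table.
#' @return `data.frame` with those columns.
#' @export
read_deg_table <- function(path) {
  first <- readLines(path, n = 1L)
  cols <- c("gene_id", "chrom", "start", "end", "log2fc", "padj")
  if (grepl("^#", first)) {
    header <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1L]]
    d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    names(d) <- header
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(cols, names(d))
  if (length(missing) > 0L)
    stop("DE table lacks column(s): ", paste(missing, collapse = ", "))
  d[cols]
}

#' Filter differential-expression results
#'
#' Keeps genes with an absolute fold change of at least `fc_threshold`
#' (i.e. `|log2FC| >= log2(fc_threshold)`) and an adjusted p-value at most
#' `padj_max`, the usual "4-fold and adjusted p <= 0.01" rule.  Rows with a
#' missing adjusted p-value are dropped and counted.
#'
#' @param table DE results with columns `log2fc` and `padj` (and
#'   typically `gene_id`, `chrom`, `start`, `end`).
#' @param fc_threshold Linear-scale fold-change threshold (default 4).
#' @param padj_max Adjusted p-value ceiling (default 0.01).
#' @return The kept rows with a `direction` column (`"up"`/`"down"` by the
#'   sign of `log2fc`); number of rows dropped for missing `padj` attached
#'   as attribute `"n_dropped"`.
#' @export
filter_degs <- function(table, fc_threshold = 4, padj_max = 0.01) {
  stopifnot(all(c("log2fc", "padj") %in% names(table)),
            fc_threshold > 0, padj_max >= 0, padj_max <= 1)
  ok <- !is.na(table$padj)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(n_dropped, " row(s) dropped for missing adjusted p-value")
  d <- table[ok, , drop = FALSE]
  keep <- abs(d$log2fc) >= log2(fc_threshold) & d$padj <= padj_max
  d <- d[keep, , drop = FALSE]
  d$direction <- ifelse(d$log2fc > 0, "up", "down")
  rownames(d) <- NULL
  attr(d, "n_dropped") <- n_dropped
  d
}

#' Split DEGs by overlap with a region set
#'
#' A gene is "inside" iff its (1-based inclusive) interval overlaps any
#' region of the (half-open) set by at least 1 bp.  `inside` and `outside`
#' partition the input.
#'
#' @param degs Filtered DEG table with `chrom`, `start`, `end`.
#' @param regions Sorted, non-overlapping region `data.frame` (typically
#'   the SNP/InDel intersection regions).
#' @return List with elements `inside` and `outside`.
#' @export
overlap_degs_with_regions <- function(degs, regions) {
  validate_regions(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(degs)))
  inside <- rep(FALSE, nrow(degs))
  for (i in seq_len(nrow(regions))) {
    inside <- inside |
      (degs$chrom == regions$chrom[i] &
         degs$start < regions$end[i] &
         degs$end >= regions$start[i])
  }
  list(inside = degs[inside, , drop = FALSE],
       outside = degs[!inside, , drop = FALSE])
}

#' Summarize DEG regulation direction
#'
#' Counts up- and downregulated genes and their percentages (2 decimals).
#' With no genes, percentages are `NA` ("not applicable"), not 0.
#'
#' @param degs DEG table with a `direction` column, or with `log2fc` from
#'   which direction is derived.
#' @return Object of class `"deg_direction_summary"`: list with `n_total`,
#'   `n_up`, `n_down`, `pct_up`, `pct_down`.
#' @export
summarize_direction <- function(degs) {
  dir <- if ("direction" %in% names(degs)) degs$direction
         else ifelse(degs$log2fc > 0, "up", "down")
  n <- length(dir)
  n_up <- sum(dir == "up")
  n_down <- sum(dir == "down")
  structure(
    list(n_total = n, n_up = n_up, n_down = n_down,
         pct_up = if (n > 0L) round(100 * n_up / n, 2) else NA_real_,
         pct_down = if (n > 0L) round(100 * n_down / n, 2) else NA_real_),
    class = "deg_direction_summary")
}

#' @export
print.deg_direction_summary <- function(x, ...) {
  if (x$n_total == 0L) {
    cat("0 DEGs (direction percentages not applicable)\n")
  } else {
    cat(sprintf("%d DEGs: %d upregulated (%.2f%%), %d downregulated (%.2f%%)\n",
                x$n_total, x$n_up, x$pct_up, x$n_down, x$pct_down))
  }
  invisible(x)
}

#' Write a DE results table
#'
#' @param degs DE table.
#' @param path Output path.
#' @export
write_deg_table <- function(degs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(degs), collapse = "\t")), con)
  utils::write.table(degs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
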