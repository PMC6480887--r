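#' Construct a region table
#'
#' Regions are half-open intervals `[start, end)` in bp on a named
#' chromosome, carrying the number of supporting markers, the peak fitted
#' value inside, and a provenance label (`"SNP"`, `"InDel"` or
#' `"intersection"`).  The half-open convention makes the size of a region
#' exactly `end - start` and matches BED output verbatim.
#'
#' @param chrom,start,end,n_markers,peak_fitted,provenance Region fields,
#'   recycled to a common length.
#' @return `data.frame` of class `c("genomic_regions", "data.frame")`.
#' @export
new_regions <- function(chrom = character(), start = numeric(),
                        end = numeric(), n_markers = integer(),
                        peak_fitted = numeric(), provenance = character()) {
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end),
                    n_markers = as.integer(n_markers),
                    peak_fitted = as.numeric(peak_fitted),
                    provenance = as.character(provenance),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0L && any(out$start > out$end))
    stop("region with start > end")
  class(out) <- c("genomic_regions", "data.frame")
  out
}

#' Validate that a region set is sorted and non-overlapping
#'
#' @param regions Region `data.frame`.
#' @return The input, invisibly; errors otherwise.
#' @keywords internal
#' @export
validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end", "provenance") %in% names(regions)))
  if (nrow(regions) > 1L) {
    o <- order(regions$chrom, regions$start)
    if (!identical(o, seq_len(nrow(regions))))
      stop("region set is not sorted by (chrom, start)")
    same <- regions$chrom[-1L] == regions$chrom[-nrow(regions)]
    if (any(same & regions$start[-1L] < regions$end[-nrow(regions)]))
      stop("region set contains overlapping regions")
  }
  invisible(regions)
}

#' Call associated regions from a fitted ED profile
#'
#' Maximal runs of consecutive markers whose fitted value is at or above
#' the threshold become candidate regions spanning the first to the last
#' supporting marker.  Runs on the same chromosome separated by at most
#' `merge_gap` bp are merged, regions supported by fewer than
#' `min_markers` markers are discarded, and region boundaries are snapped
#' outward to `bin_bp` bins (the round coordinates typical of published
#' candidate regions; `bin_bp = 0` disables snapping).
#'
#' @param x An [ed_scan()] fit, or a `data.frame` with columns `chrom`,
#'   `pos`, `fitted`.
#' @param class For the `ed_scan` method: variant class to call
#'   (`"SNP"` or `"InDel"`).
#' @param threshold Threshold on the fitted scale.  For the `ed_scan`
#'   method it defaults to the scan's own threshold for that class.
#' @param merge_gap Maximum bp gap between runs to merge (default 2e5).
#' @param min_markers Minimum supporting markers per region (default 10;
#'   use 1 to allow single-marker spikes).
#' @param bin_bp Boundary snap bin in bp (default 1e4).
#' @param ... Passed between methods.
#' @return A sorted, non-overlapping region `data.frame`
#'   (see [new_regions()]).
#' @export
call_regions <- function(x, ...) UseMethod("call_regions")

#' @rdname call_regions
#' @export
call_regions.ed_scan <- function(x, class = "SNP", threshold = NULL,
                                 merge_gap = 2e5, min_markers = 10,
                                 bin_bp = 1e4, ...) {
  s <- x$sites[x$sites$class == class, , drop = FALSE]
  if (nrow(s) == 0L) return(new_regions())
  if (is.null(threshold)) {
    th <- x$thresholds[[class]]
    if (is.null(th)) stop("no threshold for class ", class)
    threshold <- th$threshold
  }
  call_regions.data.frame(s, threshold = threshold, merge_gap = merge_gap,
                          min_markers = min_markers, bin_bp = bin_bp,
                          provenance = class)
}

#' @rdname call_regions
#' @param provenance Provenance label for the `data.frame` method.
#' @export
call_regions.data.frame <- function(x, threshold, merge_gap = 2e5,
                                    min_markers = 10, bin_bp = 1e4,
                                    provenance = "SNP", ...) {
  stopifnot(all(c("chrom", "pos", "fitted") %in% names(x)),
            is.finite(threshold))
  out <- new_regions()
  for (ch in unique(x$chrom)) {
    d <- x[x$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    above <- d$fitted >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(first = starts[r$values], last = ends[r$values])
    # runs -> half-open regions spanning first to last supporting marker
    reg <- data.frame(start = d$pos[runs$first],
                      end = d$pos[runs$last] + 1,
                      n = runs$last - runs$first + 1L,
                      peak = vapply(seq_len(nrow(runs)), function(i)
                        max(d$fitted[runs$first[i]:runs$last[i]]),
                        numeric(1)))
    reg <- .merge_runs(reg, merge_gap)
    reg <- reg[reg$n >= min_markers, , drop = FALSE]
    if (nrow(reg) == 0L) next
    if (bin_bp > 0) {
      reg$start <- floor(reg$start / bin_bp) * bin_bp
      reg$end <- ceiling(reg$end / bin_bp) * bin_bp
      reg <- .merge_runs(reg, 0)   # snapping may make neighbours touch
    }
    out <- rbind(out, new_regions(chrom = ch, start = reg$start,
                                  end = reg$end, n_markers = reg$n,
                                  peak_fitted = reg$peak,
                                  provenance = provenance))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_regions", "data.frame")
  out
}

# merge intervals on one chromosome whose gap is <= merge_gap
.merge_runs <- function(reg, merge_gap) {
  if (nrow(reg) <= 1L) return(reg)
  reg <- reg[order(reg$start), , drop = FALSE]
  keep <- reg[1L, , drop = FALSE]
  for (i in 2L:nrow(reg)) {
    j <- nrow(keep)
    if (reg$start[i] - keep$end[j] <= merge_gap) {
      keep$end[j] <- max(keep$end[j], reg$end[i])
      keep$n[j] <- keep$n[j] + reg$n[i]
      keep$peak[j] <- max(keep$peak[j], reg$peak[i])
    } else {
      keep <- rbind(keep, reg[i, , drop = FALSE])
    }
  }
  keep
}

#' Intersect two region sets
#'
#' Standard per-chromosome interval intersection of two sorted,
#' non-overlapping region sets, e.g. the SNP-derived and InDel-derived
#' associated regions.  Every output interval is contained in one interval
#' of each input; the operation is commutative and idempotent.
#'
#' @param set_a,set_b Region `data.frame`s (sorted, non-overlapping).
#' @return Region `data.frame` with provenance `"intersection"`
#'   (`n_markers` and `peak_fitted` are `NA`: marker support is not defined
#'   for a derived interval).
#' @export
intersect_region_sets <- function(set_a, set_b) {
  validate_regions(set_a)
  validate_regions(set_b)
  out <- new_regions()
  for (ch in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    a <- set_a[set_a$chrom == ch, , drop = FALSE]
    b <- set_b[set_b$chrom == ch, , drop = FALSE]
    i <- 1L; j <- 1L
    while (i <= nrow(a) && j <= nrow(b)) {
      s <- max(a$start[i], b$start[j])
      e <- min(a$end[i], b$end[j])
      if (s < e)
        out <- rbind(out, new_regions(chrom = ch, start = s, end = e,
                                      n_markers = NA_integer_,
                                      peak_fitted = NA_real_,
                                      provenance = "intersection"))
      if (a$end[i] <= b$end[j]) i <- i + 1L else j <- j + 1L
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_regions", "data.frame")
  out
}

#' Region size in megabases
#'
#' Under the half-open convention the size of a region is simply
#' `(end - start) / 1e6`: e.g. a region printed as 28,990,000-33,790,000
#' spans 4.8 Mb.
#'
#' @param regions Region `data.frame` (or any data frame with `start`,
#'   `end`).
#' @return Numeric vector of sizes in Mb.
#' @export
region_size_mb <- function(regions) {
  (regions$end - regions$start) / 1e6
}

#' Annotate regions with overlapping genes
#'
#' A gene is assigned to a region iff its (1-based inclusive) interval
#' overlaps the half-open region interval by at least 1 bp.  Overlap is
#' strand-agnostic.
#'
#' @param regions Region `data.frame`.
#' @param genes Gene models as from [read_gene_models()].
#' @return The region table with list column `gene_ids` and integer column
#'   `n_genes` added.
#' @export
annotate_regions_with_genes <- function(regions, genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  ids <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] &
      genes$end >= regions$start[i]
    ids[[i]] <- genes$gene_id[hit]
  }
  out <- regions
  out$gene_ids <- I(ids)
  out$n_genes <- lengths(ids)
  out
}

#' @export
print.genomic_regions <- function(x, ...) {
  cat(sprintf("%d region(s)", nrow(x)))
  if (nrow(x) > 0L)
    cat(sprintf(", total %.4g Mb", sum(region_size_mb(x))))
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}
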