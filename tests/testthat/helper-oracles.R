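# Independent brute-force oracles, deliberately naive.

# O(n^2) direct-summation kernel regression over all sites
brute_fit_profile <- function(positions, values, bandwidth,
                              kernel = "tricube") {
  vapply(seq_along(positions), function(i) {
    d <- abs(positions - positions[i])
    inside <- d <= bandwidth
    u <- d / bandwidth
    w <- switch(kernel,
                tricube = (1 - u^3)^3,
                triangular = 1 - u,
                uniform = rep(1, length(u)))
    w[!inside] <- 0
    sum(w * values) / sum(w)
  }, numeric(1))
}

# two-pass sample mean / sd threshold
brute_threshold <- function(x, multiplier = 3) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  m + multiplier * s
}

# per-base membership intersection of half-open region sets on small
# integer chromosomes
brute_intersect <- function(a, b, chrom_len) {
  out <- list()
  for (ch in names(chrom_len)) {
    mask_of <- function(r) {
      m <- logical(chrom_len[[ch]])
      r <- r[r$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(r)))
        if (r$end[i] > r$start[i])
          m[(r$start[i] + 1):r$end[i]] <- TRUE  # base k covers [k-1, k)
      m
    }
    m <- mask_of(a) & mask_of(b)
    if (!any(m)) next
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out[[ch]] <- data.frame(chrom = ch,
                            start = starts[r$values] - 1L,
                            end = ends[r$values])
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  d <- do.call(rbind, out)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# does a 1-based inclusive interval overlap any half-open region by >= 1 bp,
# checked base by base
brute_overlaps_any <- function(chrom, start, end, regions) {
  for (i in seq_len(nrow(regions))) {
    if (regions$chrom[i] != chrom) next
    region_bases <- seq(regions$start[i], regions$end[i] - 1)
    if (any(seq(start, end) %in% region_bases)) return(TRUE)
  }
  FALSE
}

# random sorted non-overlapping half-open region set on one chromosome
random_region_set <- function(n, chrom = "chr1", chrom_len = 10000,
                              provenance = "SNP") {
  bounds <- sort(sample.int(chrom_len, 2 * n))
  new_regions(chrom = chrom,
              start = bounds[seq(1, 2 * n, 2)],
              end = bounds[seq(2, 2 * n, 2)],
              n_markers = sample.int(50, n, replace = TRUE),
              peak_fitted = runif(n), provenance = provenance)
}
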