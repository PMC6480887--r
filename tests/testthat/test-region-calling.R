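profile_df <- function(pos, fitted, chrom = "A09") {
  data.frame(chrom = chrom, pos = pos, fitted = fitted)
}

test_that("no regions are called when the profile stays below threshold", {
  p <- profile_df(seq(1e4, 3e5, by = 1e4), runif(30, 0, 0.5))
  expect_equal(nrow(call_regions(p, threshold = 1)), 0L)
})

test_that("a single above-threshold run spans its supporting markers", {
  pos <- seq(1e4, 3e5, by = 1e4)          # 30 markers at 10 kb
  fitted <- rep(0, 30)
  fitted[10:20] <- 1
  r <- call_regions(profile_df(pos, fitted), threshold = 0.5,
                    merge_gap = 0, min_markers = 1, bin_bp = 0)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, pos[10])
  expect_equal(r$end, pos[20] + 1)
  expect_equal(r$n_markers, 11L)
  expect_equal(r$peak_fitted, 1)
})

test_that("nearby runs merge iff their gap is within merge_gap", {
  # two 5-marker runs whose gap is 150 kb, interrupted by cold markers
  pos <- c(seq(1e4, 5e4, by = 1e4), 1e5, 1.4e5,
           seq(2e5, 2.4e5, by = 1e4))
  fitted <- c(rep(1, 5), 0, 0, rep(1, 5))
  one <- call_regions(profile_df(pos, fitted), threshold = 0.5,
                      merge_gap = 2e5, min_markers = 1, bin_bp = 0)
  two <- call_regions(profile_df(pos, fitted), threshold = 0.5,
                      merge_gap = 1e5, min_markers = 1, bin_bp = 0)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_markers, 10L)
  expect_equal(nrow(two), 2L)
  expect_equal(two$n_markers, c(5L, 5L))
})

test_that("marker-support and bin-snapping rules apply", {
  pos <- seq(1e4, 3e5, by = 1e4)
  fitted <- rep(0, 30)
  fitted[12:15] <- 1                       # 4 supporting markers
  p <- profile_df(pos, fitted)
  expect_equal(nrow(call_regions(p, threshold = 0.5, min_markers = 10)), 0L)
  r <- call_regions(p, threshold = 0.5, min_markers = 4, bin_bp = 1e4)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start %% 1e4, 0)
  expect_equal(r$end %% 1e4, 0)
  expect_lte(r$start, pos[12])
  expect_gte(r$end, pos[15] + 1)
  # snapped region sets remain valid and calling is idempotent in shape
  expect_silent(validate_regions(r))
})

test_that("interval intersection is idempotent, commutative and contained", {
  set.seed(11)
  a <- random_region_set(4)
  expect_equal(intersect_region_sets(a, a)$start, a$start)
  expect_equal(intersect_region_sets(a, a)$end, a$end)

  d1 <- new_regions(chrom = "chr1", start = 0, end = 100,
                    n_markers = 1L, peak_fitted = 1, provenance = "SNP")
  d2 <- new_regions(chrom = "chr1", start = 200, end = 300,
                    n_markers = 1L, peak_fitted = 1, provenance = "InDel")
  expect_equal(nrow(intersect_region_sets(d1, d2)), 0L)

  x <- new_regions("chr1", 1, 100, 5L, 1, "SNP")
  y <- new_regions("chr1", 50, 150, 5L, 1, "InDel")
  z <- intersect_region_sets(x, y)
  expect_equal(z$start, 50)
  expect_equal(z$end, 100)
  expect_equal(z$provenance, "intersection")

  unsorted <- rbind(d2, d1)
  class(unsorted) <- c("genomic_regions", "data.frame")
  expect_error(intersect_region_sets(unsorted, d1), "sorted")
})

test_that("interval intersection equals per-base brute force on toy chromosomes", {
  set.seed(23)
  chrom_len <- c(chr1 = 10000)
  for (rep in 1:10) {
    a <- random_region_set(sample(1:4, 1))
    b <- random_region_set(sample(1:4, 1), provenance = "InDel")
    got <- intersect_region_sets(a, b)
    want <- brute_intersect(a, b, chrom_len)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # commutativity and containment in both inputs
    rev <- intersect_region_sets(b, a)
    expect_equal(rev$start, got$start)
    expect_equal(rev$end, got$end)
    for (i in seq_len(nrow(got))) {
      expect_true(any(a$start <= got$start[i] & a$end >= got$end[i]))
      expect_true(any(b$start <= got$start[i] & b$end >= got$end[i]))
    }
  }
})

test_that("region sizes follow the half-open end - start convention", {
  r <- new_regions(chrom = c("A09", "C08"),
                   start = c(28990000, 32340000),
                   end = c(33790000, 37740000),
                   n_markers = NA_integer_, peak_fitted = NA_real_,
                   provenance = "intersection")
  expect_equal(region_size_mb(r), c(4.8, 5.4))
  expect_equal(sum(region_size_mb(r)), 10.2)
  degenerate <- new_regions("A09", 100, 100, NA_integer_, NA_real_, "SNP")
  expect_equal(region_size_mb(degenerate), 0)
})

test_that("gene annotation counts overlaps of at least 1 bp", {
  r <- new_regions("A09", 1000, 2000, 50L, 3, "intersection")
  empty <- annotate_regions_with_genes(
    r, data.frame(gene_id = "g1", chrom = "C08", start = 1L, end = 10L,
                  strand = "+"))
  expect_equal(empty$n_genes, 0L)

  genes <- data.frame(
    gene_id = sprintf("g%d", 1:6), chrom = "A09",
    start = c(1100L, 1400L, 1700L, 1950L, 2000L, 100L),
    end   = c(1200L, 1500L, 1800L, 2100L, 2500L, 900L),
    strand = "+")
  # three inside, one straddling the right boundary, two outside
  ann <- annotate_regions_with_genes(r, genes)
  expect_equal(ann$n_genes, 4L)
  expect_setequal(ann$gene_ids[[1]], c("g1", "g2", "g3", "g4"))
  # brute-force agreement gene by gene
  for (i in seq_len(nrow(genes))) {
    expect_equal(genes$gene_id[i] %in% ann$gene_ids[[1]],
                 brute_overlaps_any(genes$chrom[i], genes$start[i],
                                    genes$end[i], r))
  }
})

test_that("gene totals are additive over disjoint regions", {
  set.seed(3)
  r <- new_regions(chrom = "A09", start = c(0, 3000, 7000),
                   end = c(2000, 5000, 9000),
                   n_markers = 1L, peak_fitted = 1, provenance = "SNP")
  genes <- data.frame(gene_id = sprintf("g%d", 1:40), chrom = "A09",
                      start = sample.int(9500, 40), strand = "+")
  genes$end <- genes$start + sample.int(300, 40)
  ann <- annotate_regions_with_genes(r, genes)
  joint <- annotate_regions_with_genes(
    new_regions("A09", 0, 9000, 1L, 1, "SNP"), genes)
  # regions are disjoint, so per-region gene lists are disjoint
  all_ids <- unlist(ann$gene_ids)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_equal(sum(ann$n_genes), length(all_ids))
  expect_true(all(all_ids %in% joint$gene_ids[[1]]))
})
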