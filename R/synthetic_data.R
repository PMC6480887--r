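# run code with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Configuration of the synthetic NIL-pool experiment
#'
#' Describes the genome layout and statistical structure of a simulated
#' two-pool near-isogenic-line (NIL) sequencing experiment: the two pools
#' share a fixed genetic background and differ only in one (or a few)
#' introgressed causal segments, around which the pools' allele
#' frequencies diverge and decay linearly with distance.  Defaults emulate
#' the design of a 40x pooled re-sequencing study scaled to desk size: one
#' 30-Mb chromosome carrying a single 3-Mb causal region, SNP markers at
#' ~1/kb and InDels at ~1/4 kb (the ~4:1 SNP:InDel ratio typical of plant
#' re-sequencing), 129 differentially expressed genes of which ~30% fall
#' inside the causal region.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param snp_density,indel_density Expected markers per bp.
#' @param causal_regions `data.frame` with `chrom`, `start`, `end`
#'   (1-based inclusive) of the trait-causal segments.
#' @param divergence_d Allele-frequency difference between pools inside
#'   causal regions, in `[0, 1]` (1 = fixed difference, as for NILs).
#' @param linkage_decay_bp Distance over which divergence decays linearly
#'   to 0 outside a causal region (default 2 Mb).
#' @param mean_depth Mean per-pool sequencing depth (default 40).
#' @param seq_error Per-read probability of reporting the other allele
#'   (sequencing/mapping error; default 0.005).
#' @param background_het Fraction of background (unlinked) marker sites
#'   that segregate at an intermediate allele frequency shared by both
#'   pools (default 1).  A BSA marker set contains, by construction, only
#'   the sites retained after filtration as informative/polymorphic, so
#'   every background marker segregates; the shared frequency reflects the
#'   residual heterozygosity two NIL pools of 30 plants each inherit from
#'   their common background.  These sites are the dominant source of null
#'   ED noise — binomial sampling of the same frequency in both pools —
#'   and without them the null ED distribution is degenerate at 0.
#'   Values below 1 dilute the marker set with fixed, noise-free sites.
#' @param n_genes,n_degs Number of simulated gene models and of planted
#'   differentially expressed genes.
#' @param deg_enrichment_inside Probability that a planted DEG is placed
#'   inside a causal region (default 39/129).
#' @param seed Default seed used by the `simulate_*` generators.
#' @return Object of class `"sim_config"`.
#' @export
simulation_config <- function(chromosomes = c(A09 = 30e6),
                              snp_density = 1 / 1000,
                              indel_density = 1 / 4000,
                              causal_regions = data.frame(
                                chrom = "A09",
                                start = 13500000, end = 16500000),
                              divergence_d = 1,
                              linkage_decay_bp = 2e6,
                              mean_depth = 40,
                              seq_error = 0.005,
                              background_het = 1,
                              n_genes = 3000,
                              n_degs = 129,
                              deg_enrichment_inside = 39 / 129,
                              seed = 1L) {
  stopifnot(length(chromosomes) >= 1L, !is.null(names(chromosomes)),
            all(chromosomes > 0),
            snp_density > 0, indel_density > 0,
            divergence_d >= 0, divergence_d <= 1,
            linkage_decay_bp >= 0, mean_depth >= 1,
            seq_error >= 0, seq_error < 0.5,
            background_het >= 0, background_het <= 1,
            n_genes >= 1, n_degs >= 0,
            deg_enrichment_inside >= 0, deg_enrichment_inside <= 1)
  cr <- causal_regions
  if (nrow(cr) > 0L) {
    stopifnot(all(c("chrom", "start", "end") %in% names(cr)),
              all(cr$chrom %in% names(chromosomes)),
              all(cr$start >= 1), all(cr$start <= cr$end),
              all(cr$end <= chromosomes[cr$chrom]))
  }
  structure(list(chromosomes = chromosomes, snp_density = snp_density,
                 indel_density = indel_density, causal_regions = cr,
                 divergence_d = divergence_d,
                 linkage_decay_bp = linkage_decay_bp,
                 mean_depth = mean_depth, seq_error = seq_error,
                 background_het = background_het,
                 n_genes = n_genes, n_degs = n_degs,
                 deg_enrichment_inside = deg_enrichment_inside,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic NIL-pool configuration: %d chromosome(s), %.4g Mb\n",
              length(x$chromosomes), sum(x$chromosomes) / 1e6))
  cat(sprintf("  SNP density 1/%.0f bp, InDel density 1/%.0f bp, depth %gx, error %g\n",
              1 / x$snp_density, 1 / x$indel_density, x$mean_depth,
              x$seq_error))
  cat(sprintf("  %d causal region(s), divergence %g, linkage decay %g Mb\n",
              nrow(x$causal_regions), x$divergence_d,
              x$linkage_decay_bp / 1e6))
  cat(sprintf("  %d genes, %d DEGs (%.0f%% inside causal), seed %d\n",
              x$n_genes, x$n_degs, 100 * x$deg_enrichment_inside, x$seed))
  invisible(x)
}

#' Multi-silique rate of a plant
#'
#' Fraction of a plant's flowers showing the mutant three-pistil
#' configuration: the number of three-pistiled flowers divided by the
#' total number of flowers on that plant.  Used to select the most extreme
#' plants for the multi-silique DNA pool.
#'
#' @param n_three_pistil Number of three-pistiled flowers (vectorized).
#' @param n_total Total flowers on the plant; must be >= 1.
#' @return Rate(s) in `[0, 1]`.
#' @examples
#' multi_silique_rate(16, 50)   # 0.32
#' @export
multi_silique_rate <- function(n_three_pistil, n_total) {
  if (any(n_total < 1)) stop("'n_total' must be >= 1")
  if (any(n_three_pistil < 0) || any(n_three_pistil > n_total))
    stop("'n_three_pistil' must be between 0 and 'n_total'")
  n_three_pistil / n_total
}

#' Simulate a genome-wide marker map
#'
#' Marker positions are drawn uniformly per chromosome at the configured
#' densities (Poisson marker counts, positions without replacement so the
#' map is deduplicated and strictly increasing).  Each marker is a SNP or
#' an InDel with probability proportional to the two densities; ref/alt
#' alleles are drawn accordingly (single bases for SNPs, a 1-bp
#' insertion or deletion for InDels).
#'
#' @param config A [simulation_config()].
#' @param seed Seed (default `config$seed`).
#' @return `data.frame` with `chrom`, `pos`, `class`, `ref`, `alt`,
#'   sorted by `(chrom, pos)`.
#' @export
simulate_marker_map <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    total_density <- config$snp_density + config$indel_density
    p_indel <- config$indel_density / total_density
    pieces <- lapply(names(config$chromosomes), function(ch) {
      len <- config$chromosomes[[ch]]
      if (len < 1) stop("zero-length chromosome: ", ch)
      n <- stats::rpois(1L, len * total_density)
      n <- min(n, len)
      pos <- sort(sample.int(len, n))
      cls <- ifelse(stats::runif(n) < p_indel, "InDel", "SNP")
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
      ins <- stats::runif(n) < 0.5
      indel <- cls == "InDel"
      ref[indel & ins] <- ref[indel & ins]
      alt[indel & ins] <- paste0(ref[indel & ins],
                                 sample(bases, sum(indel & ins), TRUE))
      ref[indel & !ins] <- paste0(ref[indel & !ins],
                                  sample(bases, sum(indel & !ins), TRUE))
      alt[indel & !ins] <- substr(ref[indel & !ins], 1L, 1L)
      data.frame(chrom = ch, pos = pos, class = cls, ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# divergence weight: 1 inside a causal region, linear decay to 0 over
# linkage_decay_bp outside, 0 on chromosomes without a causal region
causal_weight <- function(chrom, pos, causal_regions, linkage_decay_bp) {
  w <- numeric(length(pos))
  for (i in seq_len(nrow(causal_regions))) {
    on <- chrom == causal_regions$chrom[i]
    if (!any(on)) next
    s <- causal_regions$start[i]; e <- causal_regions$end[i]
    d <- numeric(sum(on))
    p <- pos[on]
    d[p < s] <- s - p[p < s]
    d[p > e] <- p[p > e] - e
    wi <- if (linkage_decay_bp > 0) pmax(0, 1 - d / linkage_decay_bp)
          else as.numeric(d == 0)
    w[on] <- pmax(w[on], wi)
  }
  w
}

#' Simulate pooled sequencing depths for two NIL pools
#'
#' At trait-linked markers the single-silique pool carries the reference
#' allele (true alt frequency 0) and the multi-silique pool's true alt
#' frequency is `divergence_d * w`, where the weight `w` is 1 inside a
#' causal region and decays linearly to 0 over `linkage_decay_bp`
#' outside.  A fraction `background_het` of the unlinked background
#' markers segregate at an intermediate alt frequency drawn uniformly in
#' (0.1, 0.9) and shared by both pools (residual heterozygosity of the
#' common background).  Per-site total depths are Poisson around
#' `mean_depth` (truncated at >= 1) and observed alt depths are binomial
#' after passing the true frequency through a symmetric sequencing-error
#' channel with rate `seq_error`.  Outside linked zones the two pools are
#' exchangeable.
#'
#' @param markers Marker map from [simulate_marker_map()].
#' @param config A [simulation_config()].
#' @param seed Seed (default `config$seed + 1`).
#' @return Site table in the format of [read_pooled_vcf()]: `chrom`,
#'   `pos`, `class`, `ref`, `alt`, and list columns `depth_ms`,
#'   `depth_217` of `(ref, alt)` depth pairs.  The per-site true
#'   multi-silique alt frequency is attached as attribute `"p_ms_true"`.
#' @export
simulate_pool_depths <- function(markers, config,
                                 seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"),
            all(c("chrom", "pos", "class") %in% names(markers)))
  with_seed(seed, {
    n <- nrow(markers)
    w <- causal_weight(markers$chrom, markers$pos, config$causal_regions,
                       config$linkage_decay_bp)
    # shared residual polymorphism at unlinked background sites
    q <- numeric(n)
    het <- w == 0 & stats::runif(n) < config$background_het
    q[het] <- stats::runif(sum(het), 0.1, 0.9)
    p_ms <- q + config$divergence_d * w
    p_217 <- q
    e <- config$seq_error
    p_ms_obs <- p_ms * (1 - e) + (1 - p_ms) * e
    p_217_obs <- p_217 * (1 - e) + (1 - p_217) * e
    dp_ms <- pmax(1L, stats::rpois(n, config$mean_depth))
    dp_217 <- pmax(1L, stats::rpois(n, config$mean_depth))
    alt_ms <- stats::rbinom(n, dp_ms, p_ms_obs)
    alt_217 <- stats::rbinom(n, dp_217, p_217_obs)
    p_217_true <- p_217
    out <- markers
    out$depth_ms <- I(mapply(function(d, a) c(d - a, a),
                             dp_ms, alt_ms, SIMPLIFY = FALSE))
    out$depth_217 <- I(mapply(function(d, a) c(d - a, a),
                              dp_217, alt_217, SIMPLIFY = FALSE))
    attr(out, "p_ms_true") <- p_ms
    attr(out, "p_217_true") <- p_217_true
    out
  })
}

#' Simulate gene models on the synthetic genome
#'
#' Genes are placed uniformly (chromosome chosen proportional to length),
#' with log-normal lengths around ~2 kb.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (default `config$seed + 2`).
#' @return Gene `data.frame` as from [read_gene_models()].
#' @export
simulate_gene_models <- function(config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n_genes
    chrom <- sample(names(config$chromosomes), n, replace = TRUE,
                    prob = config$chromosomes)
    len <- pmax(200, round(stats::rlnorm(n, log(2000), 0.6)))
    chrlen <- config$chromosomes[chrom]
    start <- floor(stats::runif(n, 1, pmax(1, chrlen - len)))
    end <- pmin(start + len - 1, chrlen)
    out <- data.frame(gene_id = sprintf("BnaG%05d", seq_len(n)),
                      chrom = chrom, start = as.integer(start),
                      end = as.integer(end),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a differential-expression results table
#'
#' `n_degs` genes are planted as differentially expressed
#' (`|log2FC| >= 2`, adjusted p <= 0.01, random direction); each planted
#' DEG falls inside a causal region with probability
#' `deg_enrichment_inside` (subject to gene availability).  All other
#' genes receive null effect sizes and non-significant adjusted p-values,
#' so filtering at the default thresholds recovers exactly the planted
#' set.
#'
#' @param genes Gene models (e.g. [simulate_gene_models()]).
#' @param regions Regions treated as causal for placement; defaults to
#'   `config$causal_regions`.
#' @param config A [simulation_config()].
#' @param seed Seed (default `config$seed + 3`).
#' @return DE `data.frame` (`gene_id`, `chrom`, `start`, `end`, `log2fc`,
#'   `padj`) for all genes, with planted DEG ids in attribute
#'   `"planted"`.
#' @export
simulate_deg_table <- function(genes, config,
                               regions = config$causal_regions,
                               seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_degs > nrow(genes))
    stop("n_degs (", config$n_degs, ") exceeds number of genes (",
         nrow(genes), ")")
  with_seed(seed, {
    n <- nrow(genes)
    inside <- rep(FALSE, n)
    for (i in seq_len(nrow(regions))) {
      inside <- inside | (genes$chrom == regions$chrom[i] &
                            genes$start <= regions$end[i] &
                            genes$end >= regions$start[i])
    }
    want_inside <- stats::runif(config$n_degs) < config$deg_enrichment_inside
    pool_in <- sample(which(inside))
    pool_out <- sample(which(!inside))
    idx <- integer(0)
    for (k in seq_len(config$n_degs)) {
      take_in <- want_inside[k]
      if (take_in && length(pool_in) == 0L) take_in <- FALSE
      if (!take_in && length(pool_out) == 0L) take_in <- TRUE
      if (take_in) { idx <- c(idx, pool_in[1L]); pool_in <- pool_in[-1L] }
      else { idx <- c(idx, pool_out[1L]); pool_out <- pool_out[-1L] }
    }
    log2fc <- pmax(pmin(stats::rnorm(n, 0, 0.4), 1.9), -1.9)
    padj <- stats::runif(n, 0.02, 1)
    log2fc[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
      (2 + stats::rexp(length(idx), 1))
    padj[idx] <- stats::runif(length(idx), 1e-8, 0.01)
    out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                      start = genes$start, end = genes$end,
                      log2fc = log2fc, padj = padj,
                      stringsAsFactors = FALSE)
    attr(out, "planted") <- genes$gene_id[idx]
    out
  })
}

#' Write a two-sample VCF with allele depths
#'
#' Emits a minimal standards-conformant VCF 4.2 with `GT:AD:DP` genotype
#' fields for the two pools, parseable by [read_pooled_vcf()].  The seed
#' used to generate the data is recorded in the header when given.
#'
#' @param sites Site table (see [simulate_pool_depths()]).
#' @param path Output path.
#' @param contigs Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @param seed Optional seed to record in the header.
#' @param pool_ms,pool_217 Sample names to write.
#' @export
write_pooled_vcf <- function(sites, path, contigs = NULL, seed = NULL,
                             pool_ms = "zws_ms", pool_217 = "zws_217") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##source=edscan synthetic NIL-pool generator%s",
                     if (is.null(seed)) "" else sprintf(" (seed=%d)", seed)),
             con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  writeLines(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    con)
  writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", pool_ms, pool_217, sep = "\t"), con)
  fmt_sample <- function(depths) {
    f <- depths / max(1, sum(depths))
    gt <- if (f[length(f)] > 0.9) "1/1" else if (f[length(f)] > 0.1) "0/1"
          else "0/0"
    sprintf("%s:%s:%d", gt, paste(depths, collapse = ","), sum(depths))
  }
  if (nrow(sites) > 0L) {
    lines <- vapply(seq_len(nrow(sites)), function(i) {
      paste(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", "GT:AD:DP",
            fmt_sample(sites$depth_ms[[i]]),
            fmt_sample(sites$depth_217[[i]]), sep = "\t")
    }, "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes Gene `data.frame`.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0L)
    writeLines(sprintf("%s\tedscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start, genes$end, genes$strand,
                       genes$gene_id), con)
  invisible(path)
}

#' Generate and write a complete synthetic two-pool dataset
#'
#' Runs the marker, depth, gene and DEG generators and writes a VCF, a
#' GFF3 and a DE table into `dir`, the three inputs [run_pipeline()]
#' consumes.  Sub-generators are seeded deterministically from `seed`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param seed Master seed (default `config$seed`).
#' @return List with file paths (`vcf`, `gff3`, `deg`), the truth
#'   (`causal_regions`, `planted_degs`), and the in-memory tables.
#' @export
simulate_bsa_dataset <- function(config, dir, seed = config$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  markers <- simulate_marker_map(config, seed)
  sites <- simulate_pool_depths(markers, config, seed + 1L)
  genes <- simulate_gene_models(config, seed + 2L)
  degs <- simulate_deg_table(genes, config, seed = seed + 3L)
  vcf <- file.path(dir, "pools.vcf")
  gff <- file.path(dir, "genes.gff3")
  de <- file.path(dir, "degs.tsv")
  write_pooled_vcf(sites, vcf, contigs = config$chromosomes, seed = seed)
  write_gene_models_gff3(genes, gff)
  write_deg_table(degs, de)
  list(vcf = vcf, gff3 = gff, deg = de,
       causal_regions = config$causal_regions,
       planted_degs = attr(degs, "planted"),
       sites = sites, genes = genes, deg_table = degs)
}
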