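#' Read two-pool variant calls from a VCF file
#'
#' Extracts per-site allele depths (FORMAT/AD) for the two DNA pools from a
#' VCF 4.x file.  One row is returned per biallelic or multiallelic record;
#' the full allele-depth vector is kept (the ED statistic consumes vectors
#' of any length >= 2).  Sites where either pool has a missing or
#' unparseable AD, or a total depth below `min_pool_depth`, are dropped and
#' counted.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param pool_ms,pool_217 Sample names of the multi-silique and
#'   single-silique pools.  Missing sample names are a fatal error.
#' @param min_pool_depth Minimum total AD per pool for a site to be
#'   retained (default 4).  Read-level quality filtering is assumed to have
#'   happened upstream of the VCF.
#' @return A `data.frame` sorted by `(chrom, pos)` with columns `chrom`,
#'   `pos` (1-based), `class` (`"SNP"` if all alleles are single bases,
#'   else `"InDel"`), `ref`, `alt`, and list columns `depth_ms`,
#'   `depth_217` holding integer per-allele depth vectors (ref first).
#'   The number of dropped sites is attached as attribute `"n_dropped"`.
#' @export
read_pooled_vcf <- function(path, pool_ms = "zws_ms", pool_217 = "zws_217",
                            min_pool_depth = 4) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  empty <- data.frame(chrom = character(), pos = integer(),
                      class = character(), ref = character(),
                      alt = character(),
                      depth_ms = I(list()), depth_217 = I(list()),
                      stringsAsFactors = FALSE)
  attr(empty, "n_dropped") <- 0L
  if (is.null(fix) || nrow(vcf@fix) == 0L) return(empty)

  samples <- colnames(vcf@gt)[-1L]
  for (s in c(pool_ms, pool_217)) {
    if (!s %in% samples)
      stop("sample '", s, "' not present in VCF (samples: ",
           paste(samples, collapse = ", "), ")")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad_ms  <- ad[, pool_ms]
  ad_217 <- ad[, pool_217]

  parse_ad <- function(x, n_alleles) {
    if (is.na(x) || x == "." || x == "") return(NULL)
    v <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1L]]))
    if (anyNA(v) || length(v) != n_alleles || any(v < 0)) return(NULL)
    v
  }

  chrom <- as.character(vcf@fix[, "CHROM"])
  pos   <- as.integer(vcf@fix[, "POS"])
  ref   <- as.character(vcf@fix[, "REF"])
  alt   <- as.character(vcf@fix[, "ALT"])

  n <- length(pos)
  keep <- logical(n)
  dm <- vector("list", n); ds <- vector("list", n)
  cls <- character(n)
  for (i in seq_len(n)) {
    if (is.na(alt[i]) || alt[i] == ".") next
    alleles <- c(ref[i], strsplit(alt[i], ",", fixed = TRUE)[[1L]])
    a <- parse_ad(ad_ms[i], length(alleles))
    b <- parse_ad(ad_217[i], length(alleles))
    if (is.null(a) || is.null(b)) next
    if (sum(a) < min_pool_depth || sum(b) < min_pool_depth) next
    keep[i] <- TRUE
    dm[[i]] <- a; ds[[i]] <- b
    cls[i] <- if (all(nchar(alleles) == 1L)) "SNP" else "InDel"
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " site(s) dropped (missing/malformed AD or total depth < ",
            min_pool_depth, ")")

  out <- data.frame(chrom = chrom[keep], pos = pos[keep], class = cls[keep],
                    ref = ref[keep], alt = alt[keep],
                    stringsAsFactors = FALSE)
  out$depth_ms  <- I(dm[keep])
  out$depth_217 <- I(ds[keep])
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read gene models from a GFF3 file
#'
#' Keeps features of type `"gene"`.  Gene identifiers are taken from the
#' `ID` attribute (falling back to `Name`, then `gene_id`).
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `strand`.  Duplicate gene ids are an error.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g[g$type == "gene", , drop = FALSE])
  id <- NULL
  for (col in c("ID", "Name", "gene_id")) {
    if (col %in% names(g) && !all(is.na(g[[col]]))) { id <- g[[col]]; break }
  }
  if (is.null(id)) stop("no gene identifier attribute (ID/Name/gene_id) in GFF3")
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate gene id(s) in GFF3: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  out <- data.frame(gene_id = id, chrom = as.character(g$seqid),
                    start = as.integer(g$start), end = as.integer(g$end),
                    strand = as.character(g$strand),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("gene with start > end in GFF3")
  rownames(out) <- NULL
  out
}

#' Write a region set to a BED file
#'
#' Regions are stored half-open internally, matching BED's convention, so
#' coordinates are written verbatim: one line per region with the
#' provenance in the name column and the supporting-marker count in the
#' score column.  [read_regions_bed()] round-trips the file losslessly.
#'
#' @param regions Region `data.frame` (see [call_regions()]); must be
#'   sorted and non-overlapping per chromosome.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  validate_regions(regions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  if (nrow(regions) > 0L) {
    score <- regions$n_markers
    score[is.na(score)] <- 0L
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d",
                       regions$chrom, as.integer(regions$start),
                       as.integer(regions$end), regions$provenance,
                       as.integer(score)), con)
  }
  invisible(path)
}

#' Read a region BED file written by [write_regions_bed()]
#'
#' @param path Path to the BED file.
#' @return Region `data.frame` with `chrom`, `start`, `end`, `n_markers`,
#'   `peak_fitted` (`NA`; not stored in BED) and `provenance`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(new_regions())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 5L)) stop("malformed BED line")
  new_regions(chrom = vapply(f, `[`, "", 1L),
              start = as.numeric(vapply(f, `[`, "", 2L)),
              end = as.numeric(vapply(f, `[`, "", 3L)),
              n_markers = as.integer(vapply(f, `[`, "", 5L)),
              peak_fitted = NA_real_,
              provenance = vapply(f, `[`, "", 4L))
}

#' Write the per-site statistic table
#'
#' Tab-separated table with a commented header: chromosome, position,
#' variant class, the two pools' allele depths (comma-joined), ED, powered
#' ED and the fitted profile value.
#'
#' @param scan An [ed_scan()] fit.
#' @param path Output path.
#' @export
write_site_table <- function(scan, path) {
  stopifnot(inherits(scan, "ed_scan"))
  s <- scan$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chrom\tpos\tclass\tdepth_ms\tdepth_217\ted\ted_pow%g\tfitted",
                     scan$params$power_k), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%.8g\t%.8g\t%.8g",
                     s$chrom, s$pos, s$class,
                     vapply(s$depth_ms, paste, "", collapse = ","),
                     vapply(s$depth_217, paste, "", collapse = ","),
                     s$ed, s$ed_powered, s$fitted), con)
  invisible(path)
}
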