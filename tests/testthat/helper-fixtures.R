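# toy VCF writer: records given as list of c(chrom, pos, ref, alt, ad_ms, ad_217)
write_toy_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                          samples = c("zws_ms", "zws_217")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  for (r in records)
    lines <- c(lines, paste(r[1], r[2], ".", r[3], r[4], ".", "PASS", ".",
                            "AD", r[5], r[6], sep = "\t"))
  writeLines(lines, path)
  path
}

write_toy_gff3 <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes)))
    lines <- c(lines, sprintf("%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                              genes$chrom[i], genes$start[i], genes$end[i],
                              genes$gene_id[i]))
  writeLines(lines, path)
  path
}

# small fast simulation configs used across tests
toy_config <- function(...) {
  simulation_config(chromosomes = c(A09 = 4e6),
                    causal_regions = data.frame(chrom = "A09",
                                                start = 15e5, end = 25e5),
                    linkage_decay_bp = 5e5,
                    n_genes = 300, n_degs = 20, ...)
}

null_config <- function(len = 10e6, ...) {
  simulation_config(chromosomes = c(A09 = len),
                    causal_regions = data.frame(chrom = character(),
                                                start = numeric(),
                                                end = numeric()),
                    divergence_d = 0, ...)
}
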