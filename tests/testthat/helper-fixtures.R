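# Fixture builders shared across test files. All fixtures are constructed in
# code; file fixtures are written to tempdir() at test time.

# One SNP row of the variant table from per-bulk base counts.
snp_row <- function(chrom = "chr1", pos = 1L, ref = "A", alt = "C",
                    high = c(A = 0L, C = 0L, G = 0L, T = 0L),
                    low = c(A = 0L, C = 0L, G = 0L, T = 0L)) {
  tb <- tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                       alt = alt, vclass = "SNP")
  for (b in c("A", "C", "G", "T")) {
    tb[[paste0("high_", b)]] <- as.integer(high[[b]])
    tb[[paste0("low_", b)]] <- as.integer(low[[b]])
  }
  tb$high_REF <- NA_integer_; tb$high_ALT <- NA_integer_
  tb$low_REF <- NA_integer_; tb$low_ALT <- NA_integer_
  tb[names(edbsa::empty_variants())]
}

# One indel row with REF/ALT counts.
indel_row <- function(chrom = "chr1", pos = 1L, ref = "A", alt = "AT",
                      high = c(REF = 0L, ALT = 0L),
                      low = c(REF = 0L, ALT = 0L)) {
  tb <- tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                       alt = alt, vclass = "indel")
  for (b in c("A", "C", "G", "T")) {
    tb[[paste0("high_", b)]] <- NA_integer_
    tb[[paste0("low_", b)]] <- NA_integer_
  }
  tb$high_REF <- as.integer(high[["REF"]])
  tb$high_ALT <- as.integer(high[["ALT"]])
  tb$low_REF <- as.integer(low[["REF"]])
  tb$low_ALT <- as.integer(low[["ALT"]])
  tb[names(edbsa::empty_variants())]
}

# A biallelic SNP locus (ref A, alt C) from bulk allele frequencies and a
# fixed depth — handy for fuzzed ED checks.
snp_from_freqs <- function(f_high, f_low, depth = 100L, pos = 1L,
                           chrom = "chr1") {
  ch <- round(depth * f_high); cl <- round(depth * f_low)
  snp_row(chrom = chrom, pos = pos, ref = "A", alt = "C",
          high = c(A = depth - ch, C = ch, G = 0L, T = 0L),
          low = c(A = depth - cl, C = cl, G = 0L, T = 0L))
}

# Random valid SNP table for fuzz tests: counts uniform in 0..max_count.
random_variants <- function(n, max_count = 50L, n_chrom = 2L) {
  counts <- function() matrix(sample.int(max_count + 1L, 4L * n,
                                         replace = TRUE) - 1L, n, 4L)
  ch <- counts(); cl <- counts()
  tb <- tibble::tibble(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    pos = sample.int(1e6, n, replace = TRUE),
    ref = "A", alt = "C", vclass = "SNP"
  )
  for (j in 1:4) {
    b <- c("A", "C", "G", "T")[j]
    tb[[paste0("high_", b)]] <- ch[, j]
    tb[[paste0("low_", b)]] <- cl[, j]
  }
  tb$high_REF <- NA_integer_; tb$high_ALT <- NA_integer_
  tb$low_REF <- NA_integer_; tb$low_ALT <- NA_integer_
  dplyr::arrange(tb[names(edbsa::empty_variants())], chrom, pos)
}

# Minimal VCF text with AD for two bulk samples; `records` is a character
# vector of pre-formatted data lines.
write_vcf_fixture <- function(records, path = tempfile(fileext = ".vcf"),
                              samples = c("high_bulk", "low_bulk")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

# GFF3 text fixture from a tibble of gene features.
write_gff_fixture <- function(genes, path = tempfile(fileext = ".gff3"),
                              extra_lines = character()) {
  lines <- c("##gff-version 3", extra_lines)
  if (nrow(genes) > 0) {
    lines <- c(lines, sprintf(
      "%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$chrom, genes$start, genes$end, genes$strand, genes$gene_id
    ))
  }
  writeLines(lines, path)
  path
}

# Phenotype table with exact seed ratios and consistent weights.
pheno_fixture <- function(ratios, ids = sprintf("P%03d", seq_along(ratios))) {
  fruit <- rep(50, length(ratios))
  tibble::tibble(
    plant_id = ids,
    fruit_weight_g = fruit,
    seed_weight_g = ratios * fruit,
    pericarp_thickness_cm = rep(5, length(ratios)),
    seed_number = rep(8L, length(ratios)),
    seed_ratio = ratios
  )
}

# Small simulation config for fast unit tests.
small_sim_config <- function(..., rng_seed = 1L) {
  edbsa::simulation_config(
    n_plants = 100L, n_chrom = 2L, chrom_length_bp = 20e6,
    n_snps_per_chrom = 400L, qtl_pos_bp = 10e6, n_per_bulk = 10L,
    rng_seed = rng_seed, ...
  )
}
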