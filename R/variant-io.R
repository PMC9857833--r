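# Variant table I/O.
#
# A variant table is a tibble with one row per called locus and the fixed
# column layout of the two-bulk TSV dialect:
#   chrom, pos, ref, alt (comma-separated for multi-allelic), vclass
#   ("SNP"/"indel"), then integer read counts high_A, high_C, high_G, high_T,
#   high_REF, high_ALT and the same with the low_ prefix. SNP rows carry
#   counts in the four base columns (REF/ALT columns NA); indel rows carry
#   counts in the REF/ALT columns (base columns NA). Coordinates are 1-based
#   inclusive throughout; conversion to 0-based half-open happens only at the
#   BED boundary.

.bases <- c("A", "C", "G", "T")

.snp_cols <- function(prefix) paste0(prefix, "_", .bases)
.indel_cols <- function(prefix) paste0(prefix, c("_REF", "_ALT"))

.variant_cols <- function() {
  c("chrom", "pos", "ref", "alt", "vclass",
    .snp_cols("high"), .indel_cols("high"),
    .snp_cols("low"), .indel_cols("low"))
}

#' Build an empty variant table
#'
#' @return A zero-row tibble with the variant-table columns.
#' @export
empty_variants <- function() {
  tb <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), vclass = character()
  )
  for (col in setdiff(.variant_cols(), names(tb))) tb[[col]] <- integer()
  tb
}

.validate_variants <- function(variants) {
  missing <- setdiff(.variant_cols(), names(variants))
  if (length(missing) > 0) {
    stop("variant table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !variants$vclass %in% c("SNP", "indel")
  if (any(bad)) {
    stop("vclass must be 'SNP' or 'indel'; offending rows: ",
         paste(head(which(bad)), collapse = ", "), call. = FALSE)
  }
  invisible(variants)
}

#' Per-bulk sequencing depth of each locus
#'
#' Depth is the sum of the allele read counts that apply to the locus class:
#' A/C/G/T columns for SNPs, REF/ALT columns for indels.
#'
#' @param variants A variant table.
#' @return A tibble with columns `high_depth` and `low_depth`.
#' @export
bulk_depths <- function(variants) {
  .validate_variants(variants)
  depth_for <- function(prefix) {
    snp <- rowSums(as.matrix(variants[.snp_cols(prefix)]), na.rm = TRUE)
    ind <- rowSums(as.matrix(variants[.indel_cols(prefix)]), na.rm = TRUE)
    as.integer(ifelse(variants$vclass == "SNP", snp, ind))
  }
  tibble(high_depth = depth_for("high"), low_depth = depth_for("low"))
}

#' Read a two-bulk variant table
#'
#' Reads called variants with per-bulk allele depths from either the TSV
#' dialect written by [write_variants_tsv()] or a VCF 4.x file whose
#' genotype columns carry the standard `AD` (allele depth) field for the two
#' bulk samples. VCF records lacking `AD` in either bulk are skipped and
#' counted; the count is attached as attribute `n_skipped` and reported with
#' a message.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension), `"tsv"`, or `"vcf"`.
#' @param high_sample,low_sample VCF sample names of the high- and
#'   low-phenotype bulks. Bulk identity is assigned by name, not column
#'   order. If both are `NULL` and the VCF has exactly two samples, the
#'   first is taken as the high bulk with a message.
#' @return A variant table sorted by (chrom, pos), with attribute
#'   `n_skipped`.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf"),
                          high_sample = NULL, low_sample = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- switch(format,
    tsv = .read_variants_tsv(path),
    vcf = .read_variants_vcf(path, high_sample, low_sample)
  )
  skipped <- attr(out, "n_skipped") %||% 0L
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "n_skipped") <- skipped
  if (skipped > 0) {
    message("read_variants: skipped ", skipped,
            " record(s) without usable allele depths")
  }
  out
}

.read_variants_tsv <- function(path) {
  tb <- tryCatch(
    suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      vclass = readr::col_character(), .default = readr::col_integer()
    ), progress = FALSE)),
    error = function(e) stop("malformed variant TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  prob <- readr::problems(tb)
  if (nrow(prob) > 0) {
    stop("parse error in '", path, "' at line ", prob$row[1] + 1L, ": ",
         prob$expected[1], " vs '", prob$actual[1], "'", call. = FALSE)
  }
  .validate_variants(tb)
  tb
}

.read_variants_vcf <- function(path, high_sample, low_sample) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (length(samples) < 2) {
    stop("VCF must contain the two bulk samples; found ",
         length(samples), call. = FALSE)
  }
  if (is.null(high_sample) && is.null(low_sample)) {
    if (length(samples) != 2) {
      stop("VCF has ", length(samples),
           " samples; specify high_sample and low_sample", call. = FALSE)
    }
    high_sample <- samples[1]
    low_sample <- samples[2]
    message("read_variants: assuming bulks high='", high_sample,
            "', low='", low_sample, "'")
  }
  if (!all(c(high_sample, low_sample) %in% samples)) {
    stop("bulk sample(s) not in VCF: ",
         paste(setdiff(c(high_sample, low_sample), samples), collapse = ", "),
         call. = FALSE)
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad_high <- ad[, high_sample]
  ad_low <- ad[, low_sample]
  usable <- !is.na(ad_high) & !is.na(ad_low) & ad_high != "." & ad_low != "."
  n_skipped <- sum(!usable)

  fix <- fix[usable, , drop = FALSE]
  ad_high <- ad_high[usable]
  ad_low <- ad_low[usable]
  n <- nrow(fix)

  tb <- empty_variants()
  if (n > 0) {
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    is_snp <- nchar(fix$REF) == 1L &
      vapply(alts, function(a) all(nchar(a) == 1L), logical(1))
    rows <- lapply(seq_len(n), function(i) {
      .vcf_record_row(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
        alts = alts[[i]], is_snp = is_snp[i],
        ad_high = .parse_ad(ad_high[i], i), ad_low = .parse_ad(ad_low[i], i)
      )
    })
    tb <- dplyr::bind_rows(rows)
  }
  attr(tb, "n_skipped") <- n_skipped
  tb
}

.parse_ad <- function(x, record) {
  out <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
  if (anyNA(out)) {
    stop("malformed AD field '", x, "' in record ", record, call. = FALSE)
  }
  out
}

# One dialect row from a parsed VCF record: ref depth first in AD, then one
# depth per alt. SNP alt depths are scattered onto their bases; indel alt
# depths are pooled into the ALT column.
.vcf_record_row <- function(chrom, pos, ref, alts, is_snp, ad_high, ad_low) {
  row <- tibble(chrom = chrom, pos = pos, ref = ref,
                alt = paste(alts, collapse = ","),
                vclass = if (is_snp) "SNP" else "indel")
  for (col in c(.snp_cols("high"), .indel_cols("high"),
                .snp_cols("low"), .indel_cols("low"))) {
    row[[col]] <- NA_integer_
  }
  fill <- function(prefix, ad) {
    ad <- c(ad, rep(0L, max(0L, length(alts) + 1L - length(ad))))
    if (is_snp) {
      counts <- setNames(rep(0L, 4L), .bases)
      counts[ref] <- ad[1]
      for (j in seq_along(alts)) counts[alts[j]] <- counts[alts[j]] + ad[j + 1L]
      row[paste0(prefix, "_", .bases)] <<- as.list(counts)
    } else {
      row[[paste0(prefix, "_REF")]] <<- ad[1]
      row[[paste0(prefix, "_ALT")]] <<- sum(ad[-1])
    }
  }
  fill("high", ad_high)
  fill("low", ad_low)
  row
}

#' Write a variant table in the two-bulk TSV dialect
#'
#' @param variants A variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  .validate_variants(variants)
  readr::write_tsv(variants[.variant_cols()], path, progress = FALSE)
  invisible(path)
}

#' Tally variant classes
#'
#' @param variants A variant table.
#' @return A list with `n_snp`, `n_indel` and `n_total`
#'   (`n_total = n_snp + n_indel`).
#' @export
tally_variants <- function(variants) {
  .validate_variants(variants)
  n_snp <- sum(variants$vclass == "SNP")
  n_indel <- sum(variants$vclass == "indel")
  structure(list(n_snp = n_snp, n_indel = n_indel, n_total = n_snp + n_indel),
            class = "bsr_tally")
}

#' @export
print.bsr_tally <- function(x, ...) {
  cat("Variant tally:", x$n_total, "loci (", x$n_snp, "SNP,",
      x$n_indel, "indel )\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Extracts `gene`-type features with their `ID` attribute. Features without
#' an ID are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns gene_id, chrom, start, end, strand
#'   (1-based inclusive coordinates, as in GFF3), sorted by (chrom, start).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$ID)
  } else {
    rep(NA_character_, length(gr))
  }
  keep <- !is.na(ids) & nzchar(ids)
  if (any(!keep)) {
    warning(sum(!keep), " gene feature(s) without an ID attribute skipped",
            call. = FALSE)
  }
  gr <- gr[keep]
  tb <- tibble(
    gene_id = ids[keep],
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  tb$strand[tb$strand == "*"] <- "."
  dplyr::arrange(tb, .data$chrom, .data$start)
}

#' Write association regions as BED6
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. The name column carries the region id and the score column the
#' peak fitted ED value.
#'
#' @param regions A region tibble (see [extract_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- tibble(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = regions$region_id,
    score = regions$peak_value,
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 region file written by [write_regions_bed()]
#'
#' @param path Path to the BED file.
#' @return A region tibble with 1-based inclusive coordinates.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), peak_value = double()))
  }
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE
  )
  tibble(
    region_id = bed$name,
    chrom = bed$chrom,
    start = bed$start + 1L,
    end = bed$end,
    peak_value = bed$score
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
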