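# Pre-association variant filtering and caller-set intersection.
#
# Rules follow the two-bulk BSR design: a locus must be covered in both
# bulks, biallelic, sequenced deeper than a per-bulk floor, supported by
# enough total reads, and show an allele-frequency difference between the
# bulks. Removal is attributed to the FIRST failing rule in the fixed order
# missing -> multi-allelic -> depth -> support -> non-polymorphic, so filter
# reports are deterministic.

.filter_rules <- c("missing", "multi_allelic", "depth", "support",
                   "non_polymorphic")

#' Filtering configuration
#'
#' @param min_depth_per_bulk Minimum read depth required in EACH bulk
#'   (default 5, i.e. depth must be greater than 4).
#' @param min_support Minimum read support (default 10); by default the
#'   TOTAL depth across both bulks, see `support_scope`.
#' @param require_polymorphic Drop loci whose bulk allele-frequency vectors
#'   do not differ (default `TRUE`).
#' @param biallelic_only Drop loci with more than one alternate allele
#'   (default `TRUE`).
#' @param drop_missing Drop loci with zero depth in either bulk
#'   (default `TRUE`).
#' @param polymorphism_eps Minimum L-infinity distance between the two
#'   bulks' allele-frequency vectors for a locus to count as polymorphic
#'   (default 0: any difference counts).
#' @param support_scope `"total"` (default) applies `min_support` to the
#'   summed depth of both bulks; `"per_bulk"` applies it to each bulk.
#' @return A `bsr_filter_config` list.
#' @export
filter_config <- function(min_depth_per_bulk = 5L, min_support = 10L,
                          require_polymorphic = TRUE, biallelic_only = TRUE,
                          drop_missing = TRUE, polymorphism_eps = 0,
                          support_scope = c("total", "per_bulk")) {
  support_scope <- match.arg(support_scope)
  stopifnot(min_depth_per_bulk >= 0, min_support >= 0, polymorphism_eps >= 0)
  structure(
    list(min_depth_per_bulk = as.integer(min_depth_per_bulk),
         min_support = as.integer(min_support),
         require_polymorphic = isTRUE(require_polymorphic),
         biallelic_only = isTRUE(biallelic_only),
         drop_missing = isTRUE(drop_missing),
         polymorphism_eps = polymorphism_eps,
         support_scope = support_scope),
    class = "bsr_filter_config"
  )
}

# L-infinity distance between the two bulks' allele-frequency vectors,
# per locus. NA where either bulk has zero depth (handled by the missing
# rule before this one is consulted).
.freq_linf <- function(variants) {
  d <- bulk_depths(variants)
  linf <- rep(NA_real_, nrow(variants))
  for (cls in c("SNP", "indel")) {
    idx <- variants$vclass == cls & d$high_depth > 0 & d$low_depth > 0
    if (!any(idx)) next
    cols <- if (cls == "SNP") .bases else c("REF", "ALT")
    fh <- as.matrix(variants[idx, paste0("high_", cols)]) / d$high_depth[idx]
    fl <- as.matrix(variants[idx, paste0("low_", cols)]) / d$low_depth[idx]
    linf[idx] <- apply(abs(fh - fl), 1, max)
  }
  linf
}

#' Filter variant loci for association analysis
#'
#' Applies the two-bulk filtering rules and returns the retained loci
#' together with a per-rule removal report. A removed locus is attributed to
#' the first rule that rejects it, in the order missing, multi-allelic,
#' depth, support, non-polymorphic.
#'
#' @param variants A variant table.
#' @param cfg A [filter_config()].
#' @return A list with `retained` (variant table) and `report`
#'   (`bsr_filter_report`: `n_input`, `n_retained`, `removed_by_rule`).
#' @export
filter_variants <- function(variants, cfg = filter_config()) {
  .validate_variants(variants)
  stopifnot(inherits(cfg, "bsr_filter_config"))
  n <- nrow(variants)
  removed <- setNames(rep(0L, length(.filter_rules)), .filter_rules)

  if (n == 0) {
    report <- structure(list(n_input = 0L, n_retained = 0L,
                             removed_by_rule = removed),
                        class = "bsr_filter_report")
    return(list(retained = variants, report = report))
  }

  d <- bulk_depths(variants)
  n_alts <- lengths(strsplit(variants$alt, ",", fixed = TRUE))
  linf <- .freq_linf(variants)

  fail <- list(
    missing = cfg$drop_missing & (d$high_depth == 0 | d$low_depth == 0),
    multi_allelic = cfg$biallelic_only & n_alts > 1,
    depth = d$high_depth < cfg$min_depth_per_bulk |
      d$low_depth < cfg$min_depth_per_bulk,
    support = if (cfg$support_scope == "total") {
      d$high_depth + d$low_depth < cfg$min_support
    } else {
      d$high_depth < cfg$min_support | d$low_depth < cfg$min_support
    },
    non_polymorphic = cfg$require_polymorphic &
      !is.na(linf) & linf <= cfg$polymorphism_eps
  )

  attributed <- rep(NA_character_, n)
  for (rule in .filter_rules) {
    hit <- is.na(attributed) & fail[[rule]]
    attributed[hit] <- rule
    removed[rule] <- sum(hit)
  }

  keep <- is.na(attributed)
  report <- structure(
    list(n_input = n, n_retained = sum(keep), removed_by_rule = removed),
    class = "bsr_filter_report"
  )
  stopifnot(report$n_input == report$n_retained + sum(removed))
  list(retained = variants[keep, , drop = FALSE], report = report)
}

#' @export
print.bsr_filter_report <- function(x, ...) {
  cat("Variant filter:", x$n_input, "in,", x$n_retained, "retained\n")
  for (rule in names(x$removed_by_rule)) {
    cat(sprintf("  removed by %-16s %d\n", paste0(rule, ":"),
                x$removed_by_rule[[rule]]))
  }
  invisible(x)
}

#' Serialize a filter report as TSV
#'
#' @param report A `bsr_filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  tb <- tibble(
    rule = c("input", "retained", names(report$removed_by_rule)),
    n = c(report$n_input, report$n_retained,
          unname(report$removed_by_rule))
  )
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Intersect variant sets from two callers
#'
#' Keeps loci present in both input sets, keyed by (chrom, pos, ref,
#' alt set). Base counts are taken from `loci_a`. Both inputs must already
#' be sorted by (chrom, pos).
#'
#' @param loci_a,loci_b Variant tables sorted by (chrom, pos).
#' @return The variant table of shared loci (counts from `loci_a`).
#' @export
intersect_caller_sets <- function(loci_a, loci_b) {
  .validate_variants(loci_a)
  .validate_variants(loci_b)
  check_sorted <- function(x, name) {
    if (nrow(x) > 1 &&
        !identical(order(x$chrom, x$pos), seq_len(nrow(x)))) {
      stop(name, " is not sorted by (chrom, pos); sort it first, e.g. ",
           "dplyr::arrange(", name, ", chrom, pos)", call. = FALSE)
    }
  }
  check_sorted(loci_a, "loci_a")
  check_sorted(loci_b, "loci_b")
  key <- function(x) {
    alt_set <- vapply(strsplit(x$alt, ",", fixed = TRUE),
                      function(a) paste(sort(a), collapse = ","), character(1))
    paste(x$chrom, x$pos, x$ref, alt_set, sep = "\r")
  }
  loci_a[key(loci_a) %in% key(loci_b), , drop = FALSE]
}
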