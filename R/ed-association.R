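# The Euclidean-distance (ED) association statistic and its profile.
#
# For each locus the statistic is the Euclidean distance between the two
# bulks' base-frequency vectors,
#
#   ED = sqrt( (A_h - A_l)^2 + (C_h - C_l)^2 + (G_h - G_l)^2 + (T_h - T_l)^2 )
#
# where X_h / X_l are the frequencies of base X among the reads of the
# high- and low-phenotype bulk. Trait-unlinked loci have ED near 0; at full
# opposite fixation of a biallelic locus ED reaches sqrt(2). Raw ED values
# are raised to the power k (default 5) to suppress background noise, then
# smoothed by averaging over transcripts or sliding genomic windows. Indel
# loci use the same distance over their two-allele {REF, ALT} frequency
# vectors, and by default are excluded from the profile (they still count in
# region annotation).

#' Allele frequencies from read counts
#'
#' @param counts Named non-negative counts (e.g. `c(A = 7, C = 3, G = 0,
#'   T = 0)`).
#' @return Frequencies summing to 1.
#' @export
base_frequencies <- function(counts) {
  if (any(counts < 0)) stop("negative read count", call. = FALSE)
  depth <- sum(counts)
  if (depth == 0) {
    stop("allele frequencies undefined at zero depth; ",
         "such loci should have been removed by the missing-data filter",
         call. = FALSE)
  }
  counts / depth
}

#' Per-locus Euclidean-distance scores
#'
#' Computes, for every locus, the Euclidean distance between the two bulks'
#' allele-frequency vectors (A/C/G/T for SNPs; REF/ALT for indels) and its
#' k-th power.
#'
#' @param variants A variant table; every locus must have depth > 0 in both
#'   bulks (the filter's missing-data rule guarantees this).
#' @param k Power-transform exponent (default 5).
#' @param include_indels Score indel loci too (default `FALSE`: SNPs only,
#'   matching a base-frequency statistic).
#' @return A tibble with chrom, pos, vclass, ed_raw, ed_powered, sorted as
#'   the input.
#' @export
ed_scores <- function(variants, k = 5, include_indels = FALSE) {
  .validate_variants(variants)
  stopifnot(is.numeric(k), length(k) == 1, k > 0)
  if (!include_indels) {
    variants <- variants[variants$vclass == "SNP", , drop = FALSE]
  }
  d <- bulk_depths(variants)
  if (any(d$high_depth == 0 | d$low_depth == 0)) {
    stop("zero-depth locus passed to ed_scores(); ",
         "filter with drop_missing first", call. = FALSE)
  }
  ed <- rep(NA_real_, nrow(variants))
  for (cls in c("SNP", "indel")) {
    idx <- variants$vclass == cls
    if (!any(idx)) next
    cols <- if (cls == "SNP") .bases else c("REF", "ALT")
    fh <- as.matrix(variants[idx, paste0("high_", cols)]) / d$high_depth[idx]
    fl <- as.matrix(variants[idx, paste0("low_", cols)]) / d$low_depth[idx]
    ed[idx] <- sqrt(rowSums((fh - fl)^2))
  }
  tibble(
    chrom = variants$chrom, pos = variants$pos, vclass = variants$vclass,
    ed_raw = ed, ed_powered = ed^k
  )
}

#' Smooth ED scores into an association profile
#'
#' Each profile entry is the arithmetic mean of `ed_powered` over its member
#' loci: either all loci of one feature (transcript mode — the feature id
#' defaults to the locus' chrom/transcript identifier) or all loci falling in
#' one sliding genomic window. Windows with no loci are omitted.
#'
#' @param scores Output of [ed_scores()].
#' @param mode `"sliding_window"` or `"per_feature"`.
#' @param window_size_bp,step_bp Window geometry for sliding-window mode
#'   (defaults 1 Mb / 100 kb); `window_size_bp >= step_bp >= 1`.
#' @param feature_map Optional named character vector mapping
#'   `"chrom:pos"` keys to feature ids for per-feature mode; by default the
#'   chrom (transcript) id is the feature.
#' @return A tibble with feature, chrom, start, end, n_loci, fitted_value,
#'   sorted by (chrom, start); attributes `mode`, `window_size_bp`,
#'   `step_bp`.
#' @export
fit_profile <- function(scores, mode = c("sliding_window", "per_feature"),
                        window_size_bp = 1e6, step_bp = 1e5,
                        feature_map = NULL) {
  mode <- match.arg(mode)
  empty <- tibble(feature = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_loci = integer(), fitted_value = double())
  if (nrow(scores) == 0) {
    attr(empty, "mode") <- mode
    return(empty)
  }

  if (mode == "per_feature") {
    if (is.null(feature_map)) {
      scores$feature <- scores$chrom
    } else {
      key <- paste0(scores$chrom, ":", scores$pos)
      if (!all(key %in% names(feature_map))) {
        stop("feature_map does not cover every locus", call. = FALSE)
      }
      scores$feature <- unname(feature_map[key])
    }
    prof <- scores |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(
        chrom = dplyr::first(.data$chrom),
        start = min(.data$pos), end = max(.data$pos),
        n_loci = dplyr::n(), fitted_value = mean(.data$ed_powered),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$feature)
  } else {
    stopifnot(window_size_bp >= step_bp, step_bp >= 1)
    prof <- scores |>
      dplyr::group_by(.data$chrom) |>
      dplyr::group_modify(~ .window_means(.x, window_size_bp, step_bp)) |>
      dplyr::ungroup() |>
      dplyr::mutate(feature = sprintf("%s:%d-%d", .data$chrom,
                                      .data$start, .data$end),
                    .before = 1) |>
      dplyr::arrange(.data$chrom, .data$start)
  }
  attr(prof, "mode") <- mode
  if (mode == "sliding_window") {
    attr(prof, "window_size_bp") <- window_size_bp
    attr(prof, "step_bp") <- step_bp
  }
  prof
}

# Window means for one chromosome via prefix sums over position-sorted loci.
# Windows start at 1, 1 + step, ... while the start does not exceed the last
# locus; empty windows are dropped.
.window_means <- function(scores, window_size_bp, step_bp) {
  ord <- order(scores$pos)
  pos <- scores$pos[ord]
  val <- scores$ed_powered[ord]
  csum <- c(0, cumsum(val))
  starts <- seq(1, max(pos), by = step_bp)
  ends <- starts + window_size_bp - 1
  lo <- findInterval(starts - 1, pos)
  hi <- findInterval(ends, pos)
  n <- hi - lo
  keep <- n > 0
  tibble(
    start = as.integer(starts[keep]), end = as.integer(ends[keep]),
    n_loci = n[keep],
    fitted_value = (csum[hi + 1] - csum[lo + 1])[keep] / n[keep]
  )
}

#' Association threshold from a fitted profile
#'
#' Threshold = center + multiplier * SD over the fitted values, where the
#' center is the median (default) or the mean and SD is the population
#' standard deviation of all fitted entries.
#'
#' @param profile Output of [fit_profile()]; must be non-empty.
#' @param center_stat `"median"` (default) or `"mean"`.
#' @param multiplier SD multiplier (default 5).
#' @return A `bsr_threshold` list with center_stat, center_value, sd,
#'   multiplier, threshold.
#' @export
compute_threshold <- function(profile, center_stat = c("median", "mean"),
                              multiplier = 5) {
  center_stat <- match.arg(center_stat)
  stopifnot(multiplier >= 0)
  v <- profile$fitted_value
  if (length(v) == 0) stop("empty profile", call. = FALSE)
  center <- if (center_stat == "median") median(v) else mean(v)
  sd_pop <- sqrt(mean((v - mean(v))^2))
  structure(
    list(center_stat = center_stat, center_value = center, sd = sd_pop,
         multiplier = multiplier, threshold = center + multiplier * sd_pop),
    class = "bsr_threshold"
  )
}

#' @export
print.bsr_threshold <- function(x, ...) {
  cat(sprintf("Association threshold: %s %.6g + %g x SD %.6g = %.6g\n",
              x$center_stat, x$center_value, x$multiplier, x$sd, x$threshold))
  invisible(x)
}

#' Extract candidate association regions
#'
#' Maximal runs of profile entries with `fitted_value >= threshold` (strict
#' `>=`, no tolerance) on one chromosome are merged into a region when the
#' gap between consecutive above-threshold entries is at most
#' `merge_gap_bp`. Region bounds are the outermost entry bounds of the run;
#' `peak_value` is the run's maximum fitted value.
#'
#' @param profile Output of [fit_profile()] (entries must carry
#'   coordinates).
#' @param threshold A `bsr_threshold` or a bare numeric threshold.
#' @param merge_gap_bp Maximum gap (bp) bridged between above-threshold
#'   entries; defaults to the profile's window size, else 0.
#' @return A tibble with region_id, chrom, start, end, peak_value,
#'   n_entries; empty when nothing exceeds the threshold.
#' @export
extract_regions <- function(profile, threshold, merge_gap_bp = NULL) {
  thr <- if (inherits(threshold, "bsr_threshold")) threshold$threshold
         else as.numeric(threshold)
  merge_gap_bp <- merge_gap_bp %||% attr(profile, "window_size_bp") %||% 0
  hits <- profile[profile$fitted_value >= thr, , drop = FALSE]
  out <- tibble(region_id = character(), chrom = character(),
                start = integer(), end = integer(),
                peak_value = double(), n_entries = integer())
  if (nrow(hits) == 0) return(out)
  hits <- dplyr::arrange(hits, .data$chrom, .data$start)
  gap <- c(Inf, hits$start[-1] - hits$end[-nrow(hits)] - 1)
  new_run <- hits$chrom != dplyr::lag(hits$chrom, default = "") | gap > merge_gap_bp
  run <- cumsum(new_run)
  out <- hits |>
    dplyr::group_by(run = run) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start), end = max(.data$end),
      peak_value = max(.data$fitted_value), n_entries = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
  out$region_id <- sprintf("region_%02d", seq_len(nrow(out)))
  out[, c("region_id", "chrom", "start", "end", "peak_value", "n_entries")]
}

#' Annotate regions with genes and variant tallies
#'
#' Adds, per region: `length_mb = (end - start) / 1e6`, the ids and number
#' of gene models overlapping the region (any overlap, inclusive
#' coordinates), and the number of SNP and indel loci with
#' `start <= pos <= end`.
#'
#' @param regions Output of [extract_regions()] (1-based inclusive bp).
#' @param genes Optional gene-model tibble from [read_gene_models()].
#' @param loci Optional variant table (typically the filtered set).
#' @return `regions` with columns length_mb, n_genes, gene_ids (list
#'   column), n_snp, n_indel added.
#' @export
annotate_regions <- function(regions, genes = NULL, loci = NULL) {
  n <- nrow(regions)
  regions$length_mb <- (regions$end - regions$start) / 1e6
  regions$gene_ids <- vector("list", n)
  regions$n_genes <- 0L
  regions$n_snp <- 0L
  regions$n_indel <- 0L
  for (i in seq_len(n)) {
    if (!is.null(genes) && nrow(genes) > 0) {
      hit <- genes$chrom == regions$chrom[i] &
        genes$start <= regions$end[i] & genes$end >= regions$start[i]
      regions$gene_ids[[i]] <- genes$gene_id[hit]
      regions$n_genes[i] <- sum(hit)
    }
    if (!is.null(loci) && nrow(loci) > 0) {
      inside <- loci$chrom == regions$chrom[i] &
        loci$pos >= regions$start[i] & loci$pos <= regions$end[i]
      regions$n_snp[i] <- sum(inside & loci$vclass == "SNP")
      regions$n_indel[i] <- sum(inside & loci$vclass == "indel")
    }
  }
  regions
}

#' Write an association profile as TSV
#'
#' @param profile Output of [fit_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(
    profile[, c("chrom", "start", "end", "feature", "n_loci", "fitted_value")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Write annotated regions as TSV
#'
#' Column layout mirrors a candidate-region summary table: chromosome,
#' start/end (bp and Mb), length (Mb), gene / SNP / indel tallies and peak
#' fitted value.
#'
#' @param regions Output of [annotate_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  tb <- tibble(
    region_id = regions$region_id,
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    start_mb = round(regions$start / 1e6, 1),
    end_mb = round(regions$end / 1e6, 1),
    length_mb = round(regions$length_mb, 1),
    n_genes = regions$n_genes,
    n_snp = regions$n_snp,
    n_indel = regions$n_indel,
    peak_value = regions$peak_value,
    gene_ids = vapply(regions$gene_ids, paste, character(1), collapse = ",")
  )
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}
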