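test_that("base_frequencies divides counts by depth and rejects zero depth", {
  expect_equal(base_frequencies(c(A = 10, C = 0, G = 0, T = 0)),
               c(A = 1, C = 0, G = 0, T = 0))
  f <- base_frequencies(c(A = 7, C = 3, G = 0, T = 0))
  expect_equal(unname(f), c(0.7, 0.3, 0, 0))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_error(base_frequencies(c(A = 0, C = 0, G = 0, T = 0)), "zero depth")
})

test_that("ED matches hand-evaluated values and the power transform", {
  # identical pools -> 0
  same <- snp_row(high = c(A = 7L, C = 3L, G = 0L, T = 0L),
                  low = c(A = 70L, C = 30L, G = 0L, T = 0L))
  s <- ed_scores(same)
  expect_equal(s$ed_raw, 0)
  expect_equal(s$ed_powered, 0)

  # opposite fixation -> sqrt(2); powered = 2^(5/2)
  opp <- snp_row(high = c(A = 50L, C = 0L, G = 0L, T = 0L),
                 low = c(A = 0L, C = 50L, G = 0L, T = 0L))
  s <- ed_scores(opp)
  expect_equal(s$ed_raw, sqrt(2), tolerance = 1e-12)
  expect_equal(s$ed_powered, 2^(5 / 2), tolerance = 1e-12)

  # (0.7, 0.3) vs (0.5, 0.5) -> sqrt(0.08)
  mid <- snp_row(high = c(A = 7L, C = 3L, G = 0L, T = 0L),
                 low = c(A = 5L, C = 5L, G = 0L, T = 0L))
  expect_equal(ed_scores(mid)$ed_raw, sqrt(0.08), tolerance = 1e-12)
  expect_equal(ed_scores(mid, k = 3)$ed_powered, sqrt(0.08)^3,
               tolerance = 1e-12)
})

test_that("indel loci use the two-allele distance and are profile-excluded by default", {
  v <- dplyr::bind_rows(
    indel_row(pos = 1, high = c(REF = 10L, ALT = 0L),
              low = c(REF = 0L, ALT = 10L)),
    snp_row(pos = 2, high = c(A = 5L, C = 5L, G = 0L, T = 0L),
            low = c(A = 5L, C = 5L, G = 0L, T = 0L))
  )
  excl <- ed_scores(v)
  expect_equal(excl$vclass, "SNP")
  incl <- ed_scores(v, include_indels = TRUE)
  expect_equal(incl$ed_raw[incl$vclass == "indel"], sqrt(2),
               tolerance = 1e-12)
})

test_that("zero-depth loci are rejected rather than silently scored", {
  v <- snp_row(high = c(A = 0L, C = 0L, G = 0L, T = 0L),
               low = c(A = 10L, C = 0L, G = 0L, T = 0L))
  expect_error(ed_scores(v), "zero-depth")
})

test_that("ED is bounded, bulk-swap symmetric, relabel invariant, monotone (fuzzed)", {
  set.seed(7)
  n <- 3000
  counts <- function() matrix(sample.int(60, 4 * n, replace = TRUE), n, 4)
  ch <- counts(); cl <- counts()
  v <- random_variants(n)
  for (j in 1:4) {
    b <- c("A", "C", "G", "T")[j]
    v[[paste0("high_", b)]] <- ch[, j]
    v[[paste0("low_", b)]] <- cl[, j]
  }
  s <- ed_scores(v)
  expect_true(all(s$ed_raw >= 0))
  expect_true(all(s$ed_raw <= sqrt(2) + 1e-12))
  expect_equal(s$ed_powered, s$ed_raw^5, tolerance = 1e-12)

  # bulk swap
  vswap <- v
  for (b in c("A", "C", "G", "T")) {
    vswap[[paste0("high_", b)]] <- v[[paste0("low_", b)]]
    vswap[[paste0("low_", b)]] <- v[[paste0("high_", b)]]
  }
  expect_equal(ed_scores(vswap)$ed_raw, s$ed_raw, tolerance = 1e-12)

  # base relabelling applied to BOTH bulks
  perm <- sample(c("A", "C", "G", "T"))
  vperm <- v
  for (j in 1:4) {
    vperm[[paste0("high_", perm[j])]] <- v[[paste0("high_", c("A", "C", "G", "T")[j])]]
    vperm[[paste0("low_", perm[j])]] <- v[[paste0("low_", c("A", "C", "G", "T")[j])]]
  }
  expect_equal(ed_scores(vperm)$ed_raw, s$ed_raw, tolerance = 1e-12)
})

test_that("for biallelic loci ED grows strictly with the frequency gap", {
  gaps <- seq(0, 1, by = 0.05)
  v <- dplyr::bind_rows(lapply(seq_along(gaps), function(i) {
    snp_from_freqs(f_high = gaps[i], f_low = 0, depth = 100L, pos = i)
  }))
  ed <- ed_scores(v)$ed_raw
  expect_true(all(diff(ed) > 0))
  expect_equal(ed, sqrt(2) * gaps, tolerance = 1e-12)
})

test_that("power transform sharpens contrast between unequal scores", {
  e1 <- runif(100, 0.01, 0.5)
  e2 <- e1 + runif(100, 0.01, 0.5)
  expect_true(all((e2 / e1)^5 > e2 / e1))
})

test_that("fit_profile averages ed_powered per feature and per window", {
  one <- tibble::tibble(chrom = "tr1", pos = 10L, vclass = "SNP",
                        ed_raw = 0.3^(1 / 5), ed_powered = 0.3)
  p <- fit_profile(one, mode = "per_feature")
  expect_equal(p$feature, "tr1")
  expect_equal(p$fitted_value, 0.3)
  expect_equal(p$n_loci, 1L)

  two <- tibble::tibble(chrom = "chr1", pos = c(100L, 900L), vclass = "SNP",
                        ed_raw = c(0.1, 0.3)^(1 / 5),
                        ed_powered = c(0.1, 0.3))
  p <- fit_profile(two, mode = "sliding_window",
                   window_size_bp = 1000, step_bp = 1000)
  expect_equal(p$fitted_value, 0.2)
  expect_equal(p$start, 1L)
  expect_equal(p$end, 1000L)

  expect_equal(nrow(fit_profile(one[0, ], mode = "sliding_window")), 0)
})

test_that("window means match a brute-force oracle on 1000 random loci", {
  set.seed(11)
  scores <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos = sample.int(5e6, 1000),
    vclass = "SNP",
    ed_powered = runif(1000)^5
  )
  scores$ed_raw <- scores$ed_powered^(1 / 5)
  win <- 1e6; step <- 2.5e5
  prof <- fit_profile(scores, "sliding_window",
                      window_size_bp = win, step_bp = step)

  # oracle: enumerate every window on every chromosome directly
  oracle <- do.call(rbind, lapply(unique(scores$chrom), function(cc) {
    sc <- scores[scores$chrom == cc, ]
    starts <- seq(1, max(sc$pos), by = step)
    do.call(rbind, lapply(starts, function(s0) {
      inside <- sc$pos >= s0 & sc$pos <= s0 + win - 1
      if (!any(inside)) return(NULL)
      data.frame(chrom = cc, start = s0, n_loci = sum(inside),
                 fitted_value = mean(sc$ed_powered[inside]))
    }))
  }))
  oracle <- oracle[order(oracle$chrom, oracle$start), ]
  expect_equal(nrow(prof), nrow(oracle))
  expect_equal(prof$n_loci, oracle$n_loci)
  expect_equal(prof$fitted_value, oracle$fitted_value, tolerance = 1e-9)
})

test_that("threshold is center + multiplier * population SD of fitted values", {
  flat <- tibble::tibble(fitted_value = rep(0.7, 5))
  thr <- compute_threshold(flat)
  expect_equal(thr$threshold, 0.7)
  expect_equal(thr$sd, 0)

  skew <- tibble::tibble(fitted_value = c(0, 0, 0, 1))
  thr <- compute_threshold(skew, center_stat = "median", multiplier = 5)
  expect_equal(thr$center_value, 0)
  expect_equal(thr$sd, sqrt(3 / 16), tolerance = 1e-12)
  expect_equal(thr$threshold, 5 * 0.4330127, tolerance = 1e-6)

  expect_equal(compute_threshold(skew, multiplier = 0)$threshold, 0)
  thr_mean <- compute_threshold(skew, center_stat = "mean", multiplier = 0)
  expect_equal(thr_mean$threshold, 0.25)

  expect_error(compute_threshold(skew[0, ]), "empty")
})

test_that("extract_regions merges above-threshold runs by gap and chromosome", {
  prof <- tibble::tibble(
    feature = as.character(1:6),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(1L, 1001L, 5001L, 9001L, 1L, 1001L),
    end = c(1000L, 2000L, 6000L, 10000L, 1000L, 2000L),
    n_loci = 1L,
    fitted_value = c(0.9, 0.8, 0.1, 0.95, 0.9, 0.2)
  )
  # everything below threshold -> no regions
  expect_equal(nrow(extract_regions(prof, 2, merge_gap_bp = 0)), 0)

  # single above-threshold window spans itself
  r <- extract_regions(prof[3, ], 0.05, merge_gap_bp = 0)
  expect_equal(r$start, 5001L)
  expect_equal(r$end, 6000L)

  # adjacent windows merge; a gap larger than merge_gap splits; chromosomes
  # never merge
  r <- extract_regions(prof, 0.5, merge_gap_bp = 1000)
  expect_equal(nrow(r), 3)
  expect_equal(r$start, c(1L, 9001L, 1L))
  expect_equal(r$end, c(2000L, 10000L, 1000L))
  expect_equal(r$peak_value, c(0.9, 0.95, 0.9))

  # widening the gap merges the chr1 runs
  r <- extract_regions(prof, 0.5, merge_gap_bp = 1e4)
  expect_equal(nrow(r), 2)
  expect_equal(r$end[1], 10000L)

  # comparison is >= with no tolerance
  r <- extract_regions(prof, 0.9, merge_gap_bp = 0)
  expect_true(all(r$peak_value >= 0.9))
})

test_that("region extraction matches a brute-force oracle on a random profile", {
  set.seed(13)
  starts <- seq(1, 3e6, by = 1e5)
  prof <- tibble::tibble(
    feature = as.character(seq_along(starts)),
    chrom = "chr1", start = as.integer(starts),
    end = as.integer(starts + 1e6 - 1), n_loci = 1L,
    fitted_value = runif(length(starts))^5
  )
  thr <- compute_threshold(prof, multiplier = 1)
  gap <- 1e6
  regions <- extract_regions(prof, thr, merge_gap_bp = gap)

  # oracle: scan entries one by one, opening/extending runs
  hits <- prof[prof$fitted_value >= thr$threshold, ]
  expected <- list()
  for (i in seq_len(nrow(hits))) {
    if (length(expected) > 0 &&
        hits$start[i] - expected[[length(expected)]]$end - 1 <= gap) {
      run <- expected[[length(expected)]]
      run$end <- max(run$end, hits$end[i])
      run$peak <- max(run$peak, hits$fitted_value[i])
      expected[[length(expected)]] <- run
    } else {
      expected[[length(expected) + 1]] <-
        list(start = hits$start[i], end = hits$end[i],
             peak = hits$fitted_value[i])
    }
  }
  expect_equal(nrow(regions), length(expected))
  expect_equal(regions$start, vapply(expected, `[[`, numeric(1), "start"))
  expect_equal(regions$end, vapply(expected, `[[`, numeric(1), "end"))
  expect_equal(regions$peak_value, vapply(expected, `[[`, numeric(1), "peak"),
               tolerance = 1e-12)
})

test_that("annotate_regions computes lengths in Mb and inclusive overlaps", {
  regions <- tibble::tibble(
    region_id = c("region_01", "region_02"),
    chrom = c("chr2", "chr15"),
    start = c(140800000L, 35300000L),
    end = c(148400000L, 37300000L),
    peak_value = c(1, 1)
  )
  ann <- annotate_regions(regions)
  expect_identical(ann$length_mb, c(7.6, 2.0))

  genes <- tibble::tibble(
    gene_id = c("inside", "abut_end", "abut_start", "outside", "spanning"),
    chrom = "chr2",
    start = c(141e6L, 148400000L, 140000000L, 150000000L, 140000000L),
    end = c(141.5e6L, 148500000L, 140800000L, 151000000L, 149000000L),
    strand = "+"
  )
  loci <- dplyr::bind_rows(
    snp_row("chr2", 140800000L), snp_row("chr2", 148400000L),
    snp_row("chr2", 139000000L), indel_row("chr2", 141000000L),
    snp_row("chr15", 36000000L)
  )
  ann <- annotate_regions(regions, genes = genes, loci = loci)
  # genes abutting either boundary count (inclusive overlap)
  expect_setequal(ann$gene_ids[[1]],
                  c("inside", "abut_end", "abut_start", "spanning"))
  expect_equal(ann$n_genes, c(4L, 0L))
  expect_equal(ann$n_snp, c(2L, 1L))
  expect_equal(ann$n_indel, c(1L, 0L))
})
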