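# Half-sib population and pooled-sequencing simulator.
#
# The design emulated: one heterozygous, self-incompatible mother pollinated
# by an unknown, panmictic donor pool; ~300 F1 half-sib progeny with a
# normally distributed seed-ratio trait driven by one additive causal locus;
# 20-plant extreme bulks; and per-SNP per-bulk read depths with binomial
# allele sampling plus a uniform sequencing-error rate. Maternal gametes
# follow a Markov chain of haplotype origin along each chromosome with
# Haldane crossover probabilities from a fixed cM/Mb constant; at
# heterozygous maternal markers the alternate allele rides haplotype 1, so
# truncation selection on the trait drags linked marker frequencies apart in
# the two bulks and the divergence decays with recombination distance from
# the QTL. Paternal alleles are independent Bernoulli draws at the donor
# pool's allele frequency (no donor identity, no donor LD). An optional F2
# mode draws BOTH gametes from heterozygous-parent chains (biparental
# selfed-F1 reading of the design).

#' Simulation configuration
#'
#' Defaults describe the emulated study: 300 half-sib plants, seed ratio
#' centered at 0.34, 20-plant extreme bulks, and 100x pooled sequencing.
#'
#' @param n_plants Population size (default 300).
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_length_bp Chromosome length in bp (default 150 Mb).
#' @param n_snps_per_chrom Markers per chromosome (default 5000).
#' @param qtl_chrom,qtl_pos_bp Causal locus position (default chr1 at
#'   75 Mb).
#' @param qtl_effect Additive seed-ratio shift per alternate allele copy
#'   (default 0.06).
#' @param baseline_seed_ratio Population mean seed ratio (default 0.34).
#' @param trait_noise_sd Environmental noise SD on the seed ratio
#'   (default 0.05).
#' @param maternal_het_fraction Fraction of markers heterozygous in the
#'   mother (default 0.8; the QTL is always heterozygous so it segregates).
#' @param pop_alt_freq Alternate-allele frequency in the pollen-donor pool
#'   (default 0.3).
#' @param recomb_cm_per_mb Map density converting physical to genetic
#'   distance (default 2.5 cM/Mb).
#' @param depth_per_locus Read depth per marker per bulk (default 100).
#' @param seq_error_rate Per-read probability of miscalling to a uniform
#'   other base (default 0.001).
#' @param n_per_bulk Plants per extreme bulk (default 20).
#' @param indel_fraction Fraction of markers emitted as biallelic indel
#'   loci instead of SNPs (default 0; indels carry REF/ALT counts only).
#' @param population_type `"half_sib"` (default) or `"f2"`.
#' @param rng_seed Optional integer seed; identical seeds give
#'   bit-identical simulations.
#' @return A validated `bsr_sim_config` list.
#' @export
simulation_config <- function(n_plants = 300L, n_chrom = 2L,
                              chrom_length_bp = 150e6,
                              n_snps_per_chrom = 5000L,
                              qtl_chrom = 1L, qtl_pos_bp = 75e6,
                              qtl_effect = 0.06,
                              baseline_seed_ratio = 0.34,
                              trait_noise_sd = 0.05,
                              maternal_het_fraction = 0.8,
                              pop_alt_freq = 0.3,
                              recomb_cm_per_mb = 2.5,
                              depth_per_locus = 100L,
                              seq_error_rate = 0.001,
                              n_per_bulk = 20L,
                              indel_fraction = 0,
                              population_type = c("half_sib", "f2"),
                              rng_seed = NULL) {
  population_type <- match.arg(population_type)
  cfg <- list(
    n_plants = as.integer(n_plants), n_chrom = as.integer(n_chrom),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_snps_per_chrom = as.integer(n_snps_per_chrom),
    qtl_chrom = as.integer(qtl_chrom), qtl_pos_bp = as.numeric(qtl_pos_bp),
    qtl_effect = qtl_effect, baseline_seed_ratio = baseline_seed_ratio,
    trait_noise_sd = trait_noise_sd,
    maternal_het_fraction = maternal_het_fraction,
    pop_alt_freq = pop_alt_freq, recomb_cm_per_mb = recomb_cm_per_mb,
    depth_per_locus = as.integer(depth_per_locus),
    seq_error_rate = seq_error_rate, n_per_bulk = as.integer(n_per_bulk),
    indel_fraction = indel_fraction, population_type = population_type,
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "bsr_sim_config")
}

.validate_sim_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  check(cfg$n_plants >= 2, "n_plants must be >= 2")
  check(cfg$n_chrom >= 1, "n_chrom must be >= 1")
  check(cfg$chrom_length_bp > 0, "chrom_length_bp must be positive")
  check(cfg$n_snps_per_chrom >= 1, "n_snps_per_chrom must be >= 1")
  check(cfg$qtl_chrom >= 1 && cfg$qtl_chrom <= cfg$n_chrom,
        "qtl_chrom out of range")
  check(cfg$qtl_pos_bp >= 1 && cfg$qtl_pos_bp <= cfg$chrom_length_bp,
        "qtl_pos_bp must lie on the chromosome")
  check(cfg$qtl_effect >= 0, "qtl_effect must be non-negative")
  check(cfg$baseline_seed_ratio >= 0 && cfg$baseline_seed_ratio <= 1,
        "baseline_seed_ratio must be in [0, 1]")
  check(cfg$trait_noise_sd >= 0, "trait_noise_sd must be non-negative")
  for (p in c("maternal_het_fraction", "pop_alt_freq", "seq_error_rate",
              "indel_fraction")) {
    check(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0, 1]"))
  }
  check(cfg$recomb_cm_per_mb >= 0, "recomb_cm_per_mb must be non-negative")
  check(cfg$depth_per_locus >= 1, "depth_per_locus must be >= 1")
  check(cfg$n_per_bulk >= 1 && 2 * cfg$n_per_bulk <= cfg$n_plants,
        "n_per_bulk must satisfy 2 * n_per_bulk <= n_plants")
  invisible(cfg)
}

# Marker map: sorted unique positions per chromosome, with the causal locus
# inserted as a marker at exactly qtl_pos_bp (heterozygous in the mother).
.simulate_markers <- function(cfg) {
  maps <- lapply(seq_len(cfg$n_chrom), function(ci) {
    pos <- sort(sample.int(cfg$chrom_length_bp, cfg$n_snps_per_chrom))
    if (ci == cfg$qtl_chrom && !cfg$qtl_pos_bp %in% pos) {
      pos <- sort(c(pos, cfg$qtl_pos_bp))
    }
    m <- length(pos)
    ref_idx <- sample.int(4L, m, replace = TRUE)
    alt_idx <- 1L + (ref_idx - 1L + sample.int(3L, m, replace = TRUE)) %% 4L
    tibble(
      chrom = paste0("chr", ci), pos = as.integer(pos),
      ref = .bases[ref_idx], alt = .bases[alt_idx],
      vclass = ifelse(runif(m) < cfg$indel_fraction, "indel", "SNP"),
      mother_het = runif(m) < cfg$maternal_het_fraction
    )
  })
  markers <- dplyr::bind_rows(maps)
  qtl_idx <- which(markers$chrom == paste0("chr", cfg$qtl_chrom) &
                     markers$pos == cfg$qtl_pos_bp)[1]
  markers$mother_het[qtl_idx] <- TRUE
  markers$vclass[qtl_idx] <- "SNP"
  list(markers = markers, qtl_index = qtl_idx)
}

# Haplotype-origin Markov chains for one chromosome: n gametes x m markers,
# entries 0/1 (haplotype of origin), with per-interval switch probability
# from Haldane's map function at recomb_cm_per_mb.
.gamete_origins <- function(n, pos, cfg) {
  m <- length(pos)
  morgans <- diff(pos) * cfg$recomb_cm_per_mb * 1e-8
  r <- 0.5 * (1 - exp(-2 * morgans))
  first <- rbinom(n, 1L, 0.5)
  if (m == 1) return(matrix(first, n, 1))
  switches <- matrix(rbinom(n * (m - 1), 1L, rep(r, each = n)), n, m - 1)
  t(apply(cbind(first, switches), 1, cumsum)) %% 2L
}

#' Simulate a half-sib population with a causal seed-ratio locus
#'
#' Generates marker genotypes (maternal gamete via recombination chains,
#' paternal allele from the donor pool), the seed-ratio trait
#' `baseline + qtl_effect * (dose - E[dose]) + N(0, trait_noise_sd)`
#' truncated to \[0, 1\] (centering the additive effect keeps the population
#' mean at the baseline), and the correlated fruit traits: fruit weight and
#' pericarp thickness load negatively on seed ratio, seed number positively,
#' and seed weight is exactly `seed_ratio * fruit_weight` so the phenotype
#' invariant holds by construction.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `phenotypes` (phenotype tibble) and `truth`
#'   (`bsr_sim_truth`: markers, genotype dosage matrix, qtl description,
#'   distance of each marker to the QTL, config).
#' @export
simulate_population <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "bsr_sim_config"))
  .validate_sim_config(cfg)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)

  mk <- .simulate_markers(cfg)
  markers <- mk$markers
  n <- cfg$n_plants

  maternal <- matrix(0L, n, nrow(markers))
  paternal <- matrix(0L, n, nrow(markers))
  for (ci in seq_len(cfg$n_chrom)) {
    idx <- which(markers$chrom == paste0("chr", ci))
    origins <- .gamete_origins(n, markers$pos[idx], cfg)
    het <- matrix(markers$mother_het[idx], n, length(idx), byrow = TRUE)
    # haplotype 0 carries the alternate allele at heterozygous markers
    maternal[, idx] <- (origins == 0L) * het
    if (cfg$population_type == "f2") {
      origins2 <- .gamete_origins(n, markers$pos[idx], cfg)
      paternal[, idx] <- (origins2 == 0L) * het
    }
  }
  if (cfg$population_type == "half_sib") {
    paternal[] <- rbinom(length(paternal), 1L, cfg$pop_alt_freq)
  }
  dosage <- maternal + paternal

  dose_q <- dosage[, mk$qtl_index]
  e_dose <- if (cfg$population_type == "half_sib") {
    0.5 + cfg$pop_alt_freq
  } else {
    1
  }
  ratio <- cfg$baseline_seed_ratio +
    cfg$qtl_effect * (dose_q - e_dose) +
    rnorm(n, 0, cfg$trait_noise_sd)
  ratio <- pmin(pmax(ratio, 0), 1)

  # trait loadings reproduce the emulated study's extreme-bulk means
  fruit <- pmax(53 - 75 * (ratio - 0.34) + rnorm(n, 0, 5), 5)
  pericarp <- pmax(5.15 - 14 * (ratio - 0.34) + rnorm(n, 0, 0.5), 0.1)
  seed_n <- as.integer(round(pmax(8 + 10 * (ratio - 0.34) +
                                    rnorm(n, 0, 1.5), 1)))

  phenotypes <- tibble(
    plant_id = sprintf("P%03d", seq_len(n)),
    fruit_weight_g = fruit,
    seed_weight_g = ratio * fruit,
    pericarp_thickness_cm = pericarp,
    seed_number = seed_n,
    seed_ratio = ratio
  )

  dist_to_qtl <- ifelse(
    markers$chrom == paste0("chr", cfg$qtl_chrom),
    abs(markers$pos - cfg$qtl_pos_bp), Inf
  )
  truth <- structure(
    list(markers = markers, genotypes = dosage,
         qtl = list(chrom = paste0("chr", cfg$qtl_chrom),
                    pos_bp = cfg$qtl_pos_bp, effect = cfg$qtl_effect,
                    marker_index = mk$qtl_index),
         dist_to_qtl = dist_to_qtl, config = cfg),
    class = "bsr_sim_truth"
  )
  list(phenotypes = phenotypes, truth = truth)
}

# Observed base counts for one bulk at all loci: binomial allele sampling at
# the bulk's true alternate frequency, then a uniform error channel
# re-assigning each read to one of the other three bases with probability e.
# Sequential conditional binomials give the exact multinomial law, fully
# vectorised over loci.
.bulk_base_counts <- function(freq_alt, depth, e, ref_idx, alt_idx) {
  m <- length(freq_alt)
  p <- matrix(e / 3, m, 4L)
  p[cbind(seq_len(m), alt_idx)] <- freq_alt * (1 - e) + (1 - freq_alt) * e / 3
  p[cbind(seq_len(m), ref_idx)] <- (1 - freq_alt) * (1 - e) + freq_alt * e / 3

  counts <- matrix(0L, m, 4L, dimnames = list(NULL, .bases))
  left <- rep(as.integer(depth), m)
  prem <- rep(1, m)
  for (j in 1:3) {
    pj <- ifelse(prem > 0, pmin(p[, j] / prem, 1), 0)
    counts[, j] <- rbinom(m, left, pj)
    left <- left - counts[, j]
    prem <- prem - p[, j]
  }
  counts[, 4L] <- left
  counts
}

#' Simulate pooled sequencing of the two bulks
#'
#' For each marker and bulk, the true alternate-allele frequency is the mean
#' allele dosage of the bulk's plants divided by 2; observed read counts are
#' binomial at that frequency and `depth_per_locus` trials, with a fraction
#' `seq_error_rate` of reads re-assigned uniformly to the other bases. SNP
#' counts land on the marker's ref/alt bases (errors on the remaining two);
#' indel markers carry plain REF/ALT counts.
#'
#' @param truth `truth` from [simulate_population()].
#' @param design A [select_bulks()] design over the same plants.
#' @param cfg Simulation configuration; defaults to the one inside `truth`.
#' @param rng_seed Optional seed for just this step.
#' @return A variant table (the TSV dialect) sorted by (chrom, pos).
#' @export
simulate_bulk_counts <- function(truth, design, cfg = truth$config,
                                 rng_seed = NULL) {
  stopifnot(inherits(truth, "bsr_sim_truth"),
            inherits(design, "bsr_bulk_design"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  markers <- truth$markers
  m <- nrow(markers)
  plant_ids <- sprintf("P%03d", seq_len(nrow(truth$genotypes)))
  high_rows <- match(design$high_ids, plant_ids)
  low_rows <- match(design$low_ids, plant_ids)
  if (anyNA(high_rows) || anyNA(low_rows)) {
    stop("bulk design refers to plants outside the simulated population",
         call. = FALSE)
  }

  f_high <- colMeans(truth$genotypes[high_rows, , drop = FALSE]) / 2
  f_low <- colMeans(truth$genotypes[low_rows, , drop = FALSE]) / 2
  ref_idx <- match(markers$ref, .bases)
  alt_idx <- match(markers$alt, .bases)
  e <- cfg$seq_error_rate
  depth <- cfg$depth_per_locus

  ch <- .bulk_base_counts(f_high, depth, e, ref_idx, alt_idx)
  cl <- .bulk_base_counts(f_low, depth, e, ref_idx, alt_idx)

  tb <- tibble(
    chrom = markers$chrom, pos = markers$pos,
    ref = markers$ref, alt = markers$alt, vclass = markers$vclass
  )
  for (b in .bases) {
    tb[[paste0("high_", b)]] <- ifelse(tb$vclass == "SNP", ch[, b], NA_integer_)
    tb[[paste0("low_", b)]] <- ifelse(tb$vclass == "SNP", cl[, b], NA_integer_)
  }
  # indel loci: binomial alt counts without the base-error channel
  is_ind <- tb$vclass == "indel"
  alt_h <- ifelse(is_ind, rbinom(m, depth, f_high), NA_integer_)
  alt_l <- ifelse(is_ind, rbinom(m, depth, f_low), NA_integer_)
  tb$high_REF <- ifelse(is_ind, depth - alt_h, NA_integer_)
  tb$high_ALT <- as.integer(alt_h)
  tb$low_REF <- ifelse(is_ind, depth - alt_l, NA_integer_)
  tb$low_ALT <- as.integer(alt_l)
  tb$high_REF <- as.integer(tb$high_REF)
  tb$low_REF <- as.integer(tb$low_REF)
  # indel ref/alt tokens: a base and a 2-bp extension of it
  tb$alt[is_ind] <- paste0(tb$ref[is_ind], tb$ref[is_ind])

  dplyr::arrange(tb[.variant_cols()], .data$chrom, .data$pos)
}
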