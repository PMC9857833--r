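# Seed-ratio phenotyping, extreme-bulk selection and trait correlations.
#
# A phenotype table has one row per plant with plant_id, fruit_weight_g,
# seed_weight_g, pericarp_thickness_cm, seed_number (per-fruit means over
# the sampled fruits) and the derived seed_ratio. Seed ratios are stored as
# fractions in [0, 1]; render as percentages only in reports.

#' Fresh seed ratio
#'
#' `seed_ratio = fresh seed weight / fruit weight`, dimensionless in
#' \[0, 1\] and invariant to rescaling both weights.
#'
#' @param seed_weight_g Fresh seed weight(s), 0 <= seed <= fruit.
#' @param fruit_weight_g Fruit weight(s), > 0.
#' @return Seed ratio(s).
#' @export
seed_ratio <- function(seed_weight_g, fruit_weight_g) {
  if (any(fruit_weight_g <= 0)) {
    stop("fruit_weight_g must be positive", call. = FALSE)
  }
  if (any(seed_weight_g < 0)) {
    stop("seed_weight_g must be non-negative", call. = FALSE)
  }
  if (any(seed_weight_g > fruit_weight_g)) {
    stop("seed_weight_g exceeds fruit_weight_g", call. = FALSE)
  }
  seed_weight_g / fruit_weight_g
}

#' Select extreme-phenotype bulks
#'
#' Picks the `n_per_bulk` plants with the largest seed ratios (high bulk)
#' and, from the remaining plants, the `n_per_bulk` with the smallest (low
#' bulk). Ties are broken by plant_id (lexicographic) so repeated runs give
#' identical bulks.
#'
#' @param phenotypes A phenotype table with plant_id and seed_ratio.
#' @param n_per_bulk Plants per bulk (default 20).
#' @return A `bsr_bulk_design` list: high_ids, low_ids, n_per_bulk,
#'   high_range, low_range.
#' @export
select_bulks <- function(phenotypes, n_per_bulk = 20L) {
  n_per_bulk <- as.integer(n_per_bulk)
  stopifnot(n_per_bulk >= 1)
  if (nrow(phenotypes) < 2 * n_per_bulk) {
    stop("need at least ", 2 * n_per_bulk, " plants, have ",
         nrow(phenotypes), call. = FALSE)
  }
  r <- phenotypes$seed_ratio
  id <- phenotypes$plant_id
  high_idx <- head(order(-r, id), n_per_bulk)
  rest <- setdiff(seq_along(r), high_idx)
  low_idx <- rest[head(order(r[rest], id[rest]), n_per_bulk)]
  design <- structure(
    list(high_ids = id[high_idx], low_ids = id[low_idx],
         n_per_bulk = n_per_bulk,
         high_range = range(r[high_idx]), low_range = range(r[low_idx])),
    class = "bsr_bulk_design"
  )
  if (min(r[high_idx]) <= max(r[low_idx])) {
    warning("high and low bulks are not separated in seed ratio ",
            "(ties span the selection cut)", call. = FALSE)
  }
  design
}

#' @export
print.bsr_bulk_design <- function(x, ...) {
  cat(sprintf(
    "Bulk design: %d + %d plants; high seed ratio %.1f%%-%.1f%%, low %.1f%%-%.1f%%\n",
    length(x$high_ids), length(x$low_ids),
    100 * x$high_range[1], 100 * x$high_range[2],
    100 * x$low_range[1], 100 * x$low_range[2]
  ))
  invisible(x)
}

.pheno_traits <- c("seed_ratio", "seed_weight_g", "seed_number",
                   "fruit_weight_g", "pericarp_thickness_cm")

#' Pairwise trait correlations
#'
#' Correlation matrix (Pearson by default, Spearman optional) with
#' two-sided p-values across the fruit traits. Constant traits yield NA
#' entries with a warning.
#'
#' @param phenotypes A phenotype table.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param traits Trait columns to correlate.
#' @return A `bsr_correlations` list with `estimate` and `p_value`
#'   matrices and `method`.
#' @export
trait_correlations <- function(phenotypes, method = c("pearson", "spearman"),
                               traits = .pheno_traits) {
  method <- match.arg(method)
  missing <- setdiff(traits, names(phenotypes))
  if (length(missing) > 0) {
    stop("phenotype table missing trait(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(phenotypes) < 3) stop("need at least 3 plants", call. = FALSE)
  x <- as.matrix(phenotypes[traits])
  k <- length(traits)
  est <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  pval <- est
  diag(est) <- 1
  diag(pval) <- 0
  constant <- apply(x, 2, function(v) isTRUE(sd(v) == 0))
  if (any(constant)) {
    warning("constant trait(s), correlations undefined: ",
            paste(traits[constant], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (constant[i] || constant[j]) next
      ct <- suppressWarnings(
        cor.test(x[, i], x[, j], method = method, exact = FALSE)
      )
      est[i, j] <- est[j, i] <- unname(ct$estimate)
      pval[i, j] <- pval[j, i] <- ct$p.value
    }
  }
  structure(list(estimate = est, p_value = pval, method = method),
            class = "bsr_correlations")
}

#' @export
print.bsr_correlations <- function(x, ...) {
  cat("Trait correlations (", x$method, "):\n")
  print(round(x$estimate, 3))
  invisible(x)
}

#' Write bulk membership as TSV
#'
#' @param design A `bsr_bulk_design`.
#' @param phenotypes The phenotype table the design was drawn from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bulks_tsv <- function(design, phenotypes, path) {
  tb <- tibble(
    plant_id = c(design$high_ids, design$low_ids),
    bulk = rep(c("high", "low"), each = design$n_per_bulk)
  )
  tb <- dplyr::left_join(tb, phenotypes, by = "plant_id")
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}
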