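# FPKM computation and fold-change classification of candidate genes
# between the two bulks. No replicates exist in a two-bulk design, so this
# is descriptive categorisation, not differential-expression testing.

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = count * 1e9 / (library_total * length_bp)`: linear in the
#' fragment count, inversely proportional to transcript length and library
#' size.
#'
#' @param count Non-negative fragment count(s).
#' @param length_bp Transcript length(s) in bp (> 0).
#' @param library_total Total mapped fragments in the library (> 0).
#' @return FPKM value(s).
#' @export
compute_fpkm <- function(count, length_bp, library_total) {
  if (any(length_bp <= 0)) stop("length_bp must be positive", call. = FALSE)
  if (any(library_total <= 0)) {
    stop("library_total must be positive", call. = FALSE)
  }
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count * 1e9 / (library_total * length_bp)
}

.expr_categories <- c("not_expressed_both", "higher_in_high", "higher_in_low",
                      "ge2x_high", "ge2x_low", "equal")

#' Classify per-gene expression between the two bulks
#'
#' Computes FPKM for each feature in both bulks (when not already present)
#' and assigns one category per feature: `not_expressed_both` when both
#' FPKM fall below `min_expr`; otherwise the direction of the FPKM
#' difference, upgraded to `ge2x_high` / `ge2x_low` when the larger FPKM is
#' at least `fold` times the smaller (the smaller floored at `min_expr` for
#' ratio stability); exact ties are `equal`. The tally counts each feature
#' once per direction and once more when it passes the fold test, mirroring
#' nested "n higher, of which m at least fold-times higher" reporting.
#'
#' @param records A tibble with feature_id, length_bp, count_high,
#'   count_low (or precomputed fpkm_high / fpkm_low columns).
#' @param fold Fold-change cutoff (default 2).
#' @param min_expr FPKM below which a gene counts as not expressed
#'   (default 0.1).
#' @param library_totals Optional `c(high =, low =)` mapped-fragment
#'   totals; defaults to the column sums of the counts.
#' @return A `bsr_expression` list with `records` (input plus fpkm_high,
#'   fpkm_low, category) and `tally` (named counts).
#' @export
classify_expression <- function(records, fold = 2, min_expr = 0.1,
                                library_totals = NULL) {
  stopifnot(fold >= 1, min_expr >= 0)
  if (!all(c("fpkm_high", "fpkm_low") %in% names(records))) {
    need <- c("feature_id", "length_bp", "count_high", "count_low")
    missing <- setdiff(need, names(records))
    if (length(missing) > 0) {
      stop("expression records missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    totals <- library_totals %||%
      c(high = sum(records$count_high), low = sum(records$count_low))
    records$fpkm_high <- compute_fpkm(records$count_high, records$length_bp,
                                      totals[["high"]])
    records$fpkm_low <- compute_fpkm(records$count_low, records$length_bp,
                                     totals[["low"]])
  }

  fh <- records$fpkm_high
  fl <- records$fpkm_low
  ge2x <- pmax(fh, fl) >= fold * pmax(pmin(fh, fl), min_expr)
  category <- dplyr::case_when(
    fh < min_expr & fl < min_expr ~ "not_expressed_both",
    fh == fl ~ "equal",
    fh > fl & ge2x ~ "ge2x_high",
    fh > fl ~ "higher_in_high",
    ge2x ~ "ge2x_low",
    .default = "higher_in_low"
  )
  records$category <- factor(category, levels = .expr_categories)

  tally <- c(
    not_expressed_both = sum(category == "not_expressed_both"),
    higher_in_high = sum(category %in% c("higher_in_high", "ge2x_high")),
    higher_in_low = sum(category %in% c("higher_in_low", "ge2x_low")),
    ge2x_high = sum(category == "ge2x_high"),
    ge2x_low = sum(category == "ge2x_low"),
    equal = sum(category == "equal")
  )
  structure(list(records = records, tally = tally), class = "bsr_expression")
}

#' @export
print.bsr_expression <- function(x, ...) {
  t <- x$tally
  cat("Expression categories (", nrow(x$records), "features ):\n")
  cat("  not expressed in either bulk:", t[["not_expressed_both"]], "\n")
  cat("  higher in high bulk:", t[["higher_in_high"]],
      sprintf("( %d at >=2x )\n", t[["ge2x_high"]]))
  cat("  higher in low bulk:", t[["higher_in_low"]],
      sprintf("( %d at >=2x )\n", t[["ge2x_low"]]))
  cat("  equal:", t[["equal"]], "\n")
  invisible(x)
}
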