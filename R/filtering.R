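#' Assign expression bins to mean pext values
#'
#' Bins a mean pext value as `low` (< `low_cut`), `medium`
#' (`low_cut` \eqn{\le} x \eqn{\le} `high_cut`, boundaries inclusive) or
#' `high` (> `high_cut`). NA values stay NA: an unevaluable variant is not
#' the same as an unexpressed one.
#'
#' @param x numeric vector of mean pext values in `[0, 1]` (NA allowed).
#' @param low_cut,high_cut bin boundaries (defaults 0.1 and 0.9).
#' @return character vector of `"low"`, `"medium"`, `"high"` or `NA`.
#' @export
#' @examples
#' assign_bin(c(0.05, 0.1, 0.5, 0.9, 0.95, NA))
assign_bin <- function(x, low_cut = 0.1, high_cut = 0.9) {
  .assert(low_cut > 0 && high_cut < 1 && low_cut < high_cut,
          "bin thresholds must satisfy 0 < low < high < 1")
  ok <- is.na(x) | (x >= 0 & x <= 1)
  .assert(all(ok), "pext value(s) outside [0, 1]")
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x < low_cut] <- "low"
  out[!is.na(x) & x >= low_cut & x <= high_cut] <- "medium"
  out[!is.na(x) & x > high_cut] <- "high"
  out
}

#' Filter a pext-annotated variant set by expression bin
#'
#' Removes records whose expression bin matches `bin` (typically `"low"`:
#' variants affecting under 10% of the gene's transcriptional output).
#' Records in blacklisted genes (from [gene_max_pext_filter()]) are set
#' aside as unevaluable rather than filtered, as are records with NA mean
#' pext; the report partitions the input so that
#' kept + removed + blacklisted + NA = total.
#'
#' @param records pext table from [pext_values()].
#' @param bin bin label to remove (default `"low"`).
#' @param gene_blacklist character vector of gene ids excluded by the
#'   gene-level QC filter.
#' @param label a name for the variant set, carried into the report.
#' @return a list with `kept`, `removed`, `blacklisted`, `na` subsets and
#'   a `report` list (`label`, `n_total`, `n_blacklisted`, `n_na`,
#'   `n_removed`, `n_kept`, `proportion_filtered` among evaluable records,
#'   and `by_class` breakdown).
#' @export
filter_variants <- function(records, bin = "low", gene_blacklist = character(),
                            label = "variants") {
  records <- data.table::as.data.table(records)
  .assert(all(c("gene_id", "bin") %in% names(records)),
          "records must carry gene_id and bin columns")
  is_black <- records$gene_id %in% gene_blacklist
  is_na <- !is_black & is.na(records$bin)
  is_removed <- !is_black & !is_na & records$bin == bin
  is_kept <- !is_black & !is_na & !is_removed

  n_na <- sum(is_na)
  if (n_na > 0L) {
    warning(n_na, " record(s) with NA bin retained as unevaluable, not filtered")
  }

  evaluable <- sum(is_removed) + sum(is_kept)
  target_bin <- bin
  by_class <- if ("worst_term" %in% names(records)) {
    records[!is_black & !is_na,
            .(n = .N, n_removed = sum(bin == target_bin)), by = worst_term]
  } else NULL

  report <- list(
    label = label,
    n_total = nrow(records),
    n_blacklisted = sum(is_black),
    n_na = n_na,
    n_removed = sum(is_removed),
    n_kept = sum(is_kept),
    proportion_filtered = if (evaluable > 0) sum(is_removed) / evaluable else NA_real_,
    by_class = by_class)

  list(kept = records[is_kept], removed = records[is_removed],
       blacklisted = records[is_black], na = records[is_na],
       report = report)
}

#' Compare filtered proportions between two variant sets
#'
#' Builds the 2x2 table of filtered/unfiltered counts for two filter
#' reports and returns the sample (cross-product) odds ratio together
#' with the two-sided Fisher exact p-value. This is the comparison used
#' to contrast, for example, the fraction of putative loss-of-function
#' variants removed in a population database against the fraction of
#' curated pathogenic variants removed in the same genes.
#'
#' @param report_a,report_b reports from [filter_variants()] (the `report`
#'   element, or the full returned list).
#' @return a list with `odds_ratio` (sample OR; `Inf`/0 on zero cells),
#'   `p_value` (two-sided Fisher exact), and the 2x2 `table`.
#' @export
compare_filtered_proportions <- function(report_a, report_b) {
  a <- .as_report(report_a)
  b <- .as_report(report_b)
  tab <- matrix(c(a$n_removed, a$n_kept, b$n_removed, b$n_kept), nrow = 2,
                dimnames = list(c("filtered", "unfiltered"),
                                c(a$label, b$label)))
  .assert(sum(tab[, 1]) > 0 && sum(tab[, 2]) > 0,
          "both variant sets must have evaluable records")
  or <- .sample_or(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}

.as_report <- function(x) {
  if (!is.null(x$report)) x$report else x
}

## cross-product odds ratio with explicit zero-margin behaviour
.sample_or <- function(a, b, c, d) {
  if (b * c == 0) {
    if (a * d == 0) return(NaN)
    return(Inf)
  }
  (a * d) / (b * c)
}

#' Write a filter report
#'
#' @param report report list from [filter_variants()].
#' @param path output path; `.json` writes JSON, anything else a TSV of
#'   the scalar fields.
#' @return the path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  report <- .as_report(report)
  if (grepl("\\.json$", path)) {
    scalars <- report[setdiff(names(report), "by_class")]
    out <- c(scalars, list(by_class = report$by_class))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    scalars <- report[setdiff(names(report), "by_class")]
    dt <- data.table::data.table(field = names(scalars),
                                 value = as.character(unlist(scalars)))
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}
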