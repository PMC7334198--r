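#' Annotation-level expression across transcripts (ext)
#'
#' For every variant, transcripts are grouped by identical annotation
#' class — the worst consequence plus, when present, the LOFTEE filter and
#' flags — and the median TPMs of the transcripts in each class are summed
#' per tissue. For example, a variant that is synonymous on ENST1, a
#' high-confidence stop-gain on ENST3 and ENST4 and a low-confidence
#' stop-gain on ENST5 and ENST6 yields three classes with ext values
#' TPM(ENST1), TPM(ENST3)+TPM(ENST4) and TPM(ENST5)+TPM(ENST6).
#'
#' @param consequences per-transcript consequence table
#'   ([read_vep_csq()] / [classify_variants()]).
#' @param matrix a `TissueExpressionMatrix`.
#' @param missing_transcript what to do when a consequence names a
#'   transcript absent from the expression matrix: `"error"` (default) or
#'   `"zero"` (treat as unexpressed, with a warning).
#' @return a `data.table` with the variant key, `gene_id`, the class
#'   columns (`worst_term`, `loftee_filter`, `loftee_flags`) and one ext
#'   column per tissue (TPM units).
#' @export
ext_values <- function(consequences, matrix,
                       missing_transcript = c("error", "zero")) {
  missing_transcript <- match.arg(missing_transcript)
  .assert(inherits(matrix, "TissueExpressionMatrix"),
          "expected a TissueExpressionMatrix")
  cons <- data.table::as.data.table(consequences)
  tissues <- matrix$tissues

  unknown <- setdiff(unique(cons$transcript_id), matrix$medians$transcript_id)
  if (length(unknown) > 0L) {
    if (missing_transcript == "error") {
      stop("transcript(s) absent from expression matrix: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    warning(length(unknown), " transcript(s) absent from expression matrix, ",
            "treated as unexpressed")
  }

  j <- matrix$medians[cons, on = "transcript_id"]
  for (tt in tissues) data.table::set(j, which(is.na(j[[tt]])), tt, 0)
  ## gene id comes from the consequence table; the matrix copy must agree
  if ("i.gene_id" %in% names(j)) {
    j[, gene_id := data.table::fifelse(is.na(gene_id) | gene_id == "",
                                       i.gene_id, gene_id)]
    j[, i.gene_id := NULL]
  }
  ext <- j[, lapply(.SD, sum),
           by = c(.variant_key, "gene_id", .class_key), .SDcols = tissues]
  .order_records(ext)
}

#' Proportion expressed across transcripts (pext)
#'
#' Normalizes ext values by the gene's total expression per tissue:
#' `pext = ext / gene_total`. The result is the proportion of the gene's
#' transcriptional output affected by the variant annotation in that
#' tissue. Where the gene total is 0 the proportion is undefined and
#' reported as `NA`; NA tissues are excluded from the cross-tissue
#' summary. A mean pext and an expression bin (low/medium/high, see
#' [assign_bin()]) are attached.
#'
#' @param ext output of [ext_values()].
#' @param matrix the `TissueExpressionMatrix` whose gene totals form the
#'   denominators.
#' @param tissues tissue subset for the cross-tissue summary (default:
#'   all tissues of the matrix).
#' @param summary `"mean"` (default) or `"max"` across tissues.
#' @return a `data.table` with the variant key, `gene_id`, class columns,
#'   one pext column per tissue (in `[0, 1]` or `NA`), `mean_pext` and
#'   `bin`.
#' @export
pext_values <- function(ext, matrix, tissues = NULL,
                        summary = c("mean", "max")) {
  summary <- match.arg(summary)
  .assert(inherits(matrix, "TissueExpressionMatrix"),
          "expected a TissueExpressionMatrix")
  all_tissues <- matrix$tissues
  tissues <- tissues %||% all_tissues
  .assert(all(tissues %in% all_tissues), "unknown tissue(s) requested")

  ext <- data.table::as.data.table(ext)
  missing_g <- setdiff(unique(ext$gene_id), matrix$gene_total$gene_id)
  .assert(length(missing_g) == 0L, "gene(s) without totals in matrix: %s",
          paste(utils::head(missing_g, 5), collapse = ", "))

  totals <- matrix$gene_total[match(ext$gene_id, matrix$gene_total$gene_id)]
  px <- data.table::copy(ext)
  for (tt in all_tissues) {
    denom <- totals[[tt]]
    px[, (tt) := data.table::fifelse(denom > 0, ext[[tt]] / denom, NA_real_)]
  }
  px[, mean_pext := mean_pext(px[, tissues, with = FALSE], tissues = tissues,
                              mode = summary)]
  px[, bin := assign_bin(mean_pext)]
  .order_records(px)
}

#' Summarize per-tissue pext across tissues
#'
#' NA tissues (gene total zero) are removed before summarizing; if every
#' requested tissue is NA the summary itself is NA. The default is the
#' arithmetic mean; `"max"` (maximum expression in any tissue) is an
#' alternative summary for interpretation goals that privilege any-tissue
#' expression.
#'
#' @param values a numeric vector of per-tissue pext values, or a
#'   data.frame/data.table whose `tissues` columns hold them (rowwise
#'   summary).
#' @param tissues tissue subset (columns) to summarize; ignored for plain
#'   vectors.
#' @param mode `"mean"` or `"max"`.
#' @return numeric scalar (vector input) or vector (tabular input).
#' @export
#' @examples
#' mean_pext(c(A = 0.8, B = NA, C = 0.4))            # 0.6
#' mean_pext(c(A = 0.8, B = NA, C = 0.4), mode = "max")  # 0.8
mean_pext <- function(values, tissues = NULL, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  f <- if (mode == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }
  if (is.data.frame(values)) {
    tissues <- tissues %||% names(values)
    .assert(length(tissues) > 0L, "empty tissue subset")
    m <- as.matrix(data.table::as.data.table(values)[, tissues, with = FALSE])
    return(apply(m, 1L, f))
  }
  if (!is.null(tissues)) {
    .assert(length(tissues) > 0L, "empty tissue subset")
    values <- values[tissues]
  }
  .assert(length(values) > 0L, "empty tissue subset")
  f(as.numeric(values))
}
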