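## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Strip a trailing version suffix from transcript or gene identifiers
#'
#' Ensembl/GENCODE identifiers often carry a version (`ENST00000123456.3`)
#' that differs between a quantification release and the gene models used
#' for annotation. Stripping the suffix makes the join robust.
#'
#' @param ids character vector of identifiers.
#' @return character vector with any trailing `.<digits>` removed.
#' @export
#' @examples
#' strip_versions(c("ENST00000123456.3", "ENST00000999999"))
strip_versions <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

## key columns identifying a variant and an annotation class
.variant_key <- c("chrom", "pos", "ref", "alt")
.class_key <- c("worst_term", "loftee_filter", "loftee_flags")

## order a variant-level table deterministically:
## (chromosome, position, ref, alt, class severity rank)
.order_records <- function(dt, severity = NULL) {
  dt <- data.table::copy(dt)
  if (!is.null(severity) && "worst_term" %in% names(dt)) {
    dt[, class_rank := consequence_rank(worst_term, severity)]
    data.table::setorderv(dt, c(.variant_key, "class_rank"))
    dt[, class_rank := NULL]
  } else {
    data.table::setorderv(dt, intersect(.variant_key, names(dt)))
  }
  dt[]
}
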