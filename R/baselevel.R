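#' Base-level pext track for one gene
#'
#' For each base in the union of a gene's exons, the base-level pext in a
#' tissue is the summed median TPM of the transcripts whose exons contain
#' that base, divided by the gene's total expression in the tissue. This
#' is the per-base expression track displayed alongside gene models in
#' population browsers; it is the upper envelope of the class-level pext
#' of any variant at that base.
#'
#' @param models list of `TranscriptModel` objects, all from one gene.
#' @param matrix a `TissueExpressionMatrix`.
#' @param tissues tissue subset (default: all tissues of the matrix).
#' @return a `BaseLevelTrack`: a `data.table` with `chrom`, `pos` (1-based)
#'   and one pext column per tissue (`NA` where the gene total is 0), with
#'   attributes `gene_id`.
#' @export
base_level_pext <- function(models, matrix, tissues = NULL) {
  .assert(length(models) > 0L, "no transcript models supplied")
  gene_ids <- unique(vapply(models, `[[`, character(1), "gene_id"))
  .assert(length(gene_ids) == 1L, "transcripts from multiple genes supplied")
  chroms <- unique(vapply(models, `[[`, character(1), "chrom"))
  .assert(length(chroms) == 1L, "transcripts span multiple chromosomes")
  tissues <- tissues %||% matrix$tissues
  .assert(all(tissues %in% matrix$tissues), "unknown tissue(s) requested")

  med <- matrix$medians[gene_id == gene_ids]
  total <- matrix$gene_total[gene_id == gene_ids]
  .assert(nrow(total) == 1L, "gene %s absent from expression matrix", gene_ids)

  exon_ranges <- lapply(models, function(m) {
    IRanges::IRanges(start = m$exons$start, end = m$exons$end)
  })
  footprint <- IRanges::reduce(do.call(c, unname(exon_ranges)))
  pos <- unlist(lapply(seq_along(footprint), function(i) {
    seq.int(IRanges::start(footprint)[i], IRanges::end(footprint)[i])
  }))

  track <- data.table::data.table(chrom = chroms, pos = pos)
  for (tt in tissues) {
    denom <- total[[tt]]
    if (is.na(denom) || denom <= 0) {
      track[, (tt) := NA_real_]
      next
    }
    num <- numeric(length(pos))
    for (m in models) {
      tpm <- med[transcript_id == m$transcript_id][[tt]]
      if (length(tpm) == 0L || tpm == 0) next
      hit <- IRanges::overlapsAny(IRanges::IRanges(pos, pos),
                                  IRanges::IRanges(m$exons$start, m$exons$end))
      num[hit] <- num[hit] + tpm
    }
    track[, (tt) := num / denom]
  }
  data.table::setattr(track, "gene_id", gene_ids)
  data.table::setattr(track, "class",
                      c("BaseLevelTrack", class(track)))
  track
}

#' Average base-level pext over an interval
#'
#' Averages the base-level values of a track over a 1-based closed
#' interval, per tissue — the operation used to score conserved or
#' unconserved regions by their expression.
#'
#' @param track a `BaseLevelTrack`.
#' @param start,end 1-based closed interval bounds.
#' @param tissues tissue subset (default: all tissue columns).
#' @return named numeric vector of per-tissue interval means (NA where the
#'   track is NA).
#' @export
region_mean_pext <- function(track, start, end, tissues = NULL) {
  tissues <- tissues %||% setdiff(names(track), c("chrom", "pos"))
  sub <- track[pos >= start & pos <= end]
  .assert(nrow(sub) > 0L, "interval contains no exonic bases")
  vapply(tissues, function(tt) {
    v <- sub[[tt]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Write a base-level track as bedGraph
#'
#' Converts the 1-based closed per-base records to bedGraph's 0-based
#' half-open intervals, merging runs of equal value. NA bases are skipped.
#'
#' @param track a `BaseLevelTrack`.
#' @param tissue which tissue column to export.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, tissue, path) {
  .assert(tissue %in% names(track), "tissue %s not in track", tissue)
  dt <- track[!is.na(track[[tissue]])]
  if (nrow(dt) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  v <- dt[[tissue]]
  ## split on position discontinuities or value changes
  brk <- cumsum(c(1L, as.integer(diff(dt$pos) != 1L | diff(v) != 0)))
  runs <- dt[, .(start0 = pos[1] - 1L, end0 = pos[.N], value = v[.N]),
             by = .(chrom, run = brk)]
  writeLines(sprintf("%s\t%d\t%d\t%.6g",
                     runs$chrom, runs$start0, runs$end0, runs$value), path)
  invisible(path)
}

#' Gene-level maximum-pext quality filter
#'
#' For a minority of genes the isoform quantification assigns most of the
#' gene's expression to non-coding transcripts, so every coding variant in
#' the gene receives a low pext and would be filtered wholesale. To guard
#' against this artefact, the maximum base-level pext attainable by coding
#' variation is computed per gene — the per-base sum of coding-transcript
#' TPMs over the coding footprint, across all tissues — and genes whose
#' maximum falls strictly below the threshold are flagged for exclusion.
#' A gene whose maximum equals the threshold exactly is retained. Genes
#' with no protein-coding transcript cannot be evaluated and are excluded
#' by construction.
#'
#' @param models list of `TranscriptModel` objects (any number of genes).
#' @param matrix a `TissueExpressionMatrix`.
#' @param threshold exclusion threshold on the per-gene maximum (default
#'   0.2).
#' @param tissues tissue subset over which the maximum is taken.
#' @return a `data.table` with `gene_id`, `max_pext`, logical `excluded`
#'   and `reason` (`""`, `"max_pext_below_threshold"` or
#'   `"no_coding_transcript"`).
#' @export
gene_max_pext_filter <- function(models, matrix, threshold = 0.2,
                                 tissues = NULL) {
  tissues <- tissues %||% matrix$tissues
  genes <- unique(vapply(models, `[[`, character(1), "gene_id"))
  res <- lapply(genes, function(g) {
    gm <- Filter(function(m) identical(m$gene_id, g), models)
    coding <- Filter(is_coding, gm)
    if (length(coding) == 0L) {
      return(data.table::data.table(gene_id = g, max_pext = NA_real_,
                                    excluded = TRUE,
                                    reason = "no_coding_transcript"))
    }
    ## coding-variant upper envelope: restrict numerator to coding
    ## transcripts and positions to the union of their CDS intervals
    cds_models <- lapply(coding, function(m) {
      transcript_model(m$transcript_id, m$gene_id, m$biotype, m$strand,
                       m$chrom, exons = m$cds, cds = m$cds)
    })
    track <- base_level_pext(cds_models, matrix, tissues = tissues)
    vals <- unlist(track[, tissues, with = FALSE], use.names = FALSE)
    mx <- if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
    excl <- is.na(mx) || mx < threshold
    data.table::data.table(
      gene_id = g, max_pext = mx, excluded = excl,
      reason = if (excl) "max_pext_below_threshold" else "")
  })
  data.table::rbindlist(res)
}
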