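#' Consequence severity ordering
#'
#' Loads a severity-ordered consequence vocabulary (most severe first).
#' The packaged default lists the Ensembl VEP consequence terms in their
#' canonical severity order; an alternative two-column TSV (`term`, `rank`)
#' can be supplied to override it.
#'
#' @param path optional TSV with columns `term` and `rank`; the packaged
#'   VEP ordering is used when `NULL`.
#' @return a `data.table` with columns `term` and integer `rank`
#'   (1 = most severe).
#' @export
read_severity_order <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vep_severity_order.tsv", package = "pextr")
  }
  x <- data.table::fread(path, header = TRUE)
  data.table::setnames(x, 1:2, c("term", "rank"))
  x[, rank := as.integer(rank)]
  .assert(anyDuplicated(x$term) == 0L, "duplicate terms in severity order")
  x[]
}

#' Rank of consequence terms in a severity order
#'
#' @param terms character vector of consequence terms.
#' @param severity severity table from [read_severity_order()].
#' @return integer ranks (1 = most severe); errors on unknown terms.
#' @export
consequence_rank <- function(terms, severity = read_severity_order()) {
  idx <- match(terms, severity$term)
  .assert(!anyNA(idx), "consequence term(s) absent from severity order: %s",
          paste(unique(terms[is.na(idx)]), collapse = ", "))
  severity$rank[idx]
}

#' Worst (most severe) consequence of a set of terms
#'
#' When a variant has several consequences on one transcript (for example
#' both missense and splice region), annotation proceeds with the worst
#' one under the severity ordering: missense takes precedence over splice
#' region.
#'
#' @param terms non-empty character vector of consequence terms.
#' @param severity severity table from [read_severity_order()].
#' @return the single most severe term.
#' @export
#' @examples
#' worst_consequence(c("missense_variant", "splice_region_variant"))
worst_consequence <- function(terms, severity = read_severity_order()) {
  .assert(length(terms) > 0L, "empty consequence set")
  terms[which.min(consequence_rank(terms, severity))]
}

# ---------------------------------------------------------------------------
# GTF gene models

#' Read GENCODE-style transcript models from a GTF file
#'
#' Builds one `TranscriptModel` per transcript from the exon and CDS
#' features of a GTF file. The transcript biotype is taken from the
#' `transcript_biotype` or `transcript_type` attribute. Exons are stored
#' genomically sorted with the strand carried alongside.
#'
#' @param path GTF file with gene/transcript/exon/CDS features.
#' @return a named list of `TranscriptModel` objects, each a list with
#'   `transcript_id`, `gene_id`, `biotype`, `strand`, `chrom`, `exons`
#'   and `cds` (data.frames of 1-based closed `start`/`end` intervals).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  bt_col <- intersect(c("transcript_biotype", "transcript_type"), names(mc))
  .assert(length(bt_col) > 0L,
          "GTF lacks a transcript_biotype/transcript_type attribute")
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    biotype = as.character(mc[[bt_col[1]]]))

  feats <- dt[type %in% c("exon", "CDS") & !is.na(transcript_id)]
  tx_meta <- unique(feats[, .(transcript_id, gene_id, biotype, strand, chrom)])
  .assert(anyDuplicated(tx_meta$transcript_id) == 0L,
          "transcript with inconsistent gene/strand/chromosome attributes")
  orphan <- setdiff(dt[type == "CDS"]$transcript_id, dt[type == "exon"]$transcript_id)
  .assert(length(orphan) == 0L, "CDS feature without exon parent: %s",
          paste(utils::head(orphan, 5), collapse = ", "))

  models <- lapply(seq_len(nrow(tx_meta)), function(i) {
    m <- tx_meta[i]
    ex <- feats[transcript_id == m$transcript_id & type == "exon",
                .(start, end)][order(start)]
    cds <- feats[transcript_id == m$transcript_id & type == "CDS",
                 .(start, end)][order(start)]
    transcript_model(m$transcript_id, m$gene_id, m$biotype, m$strand,
                     m$chrom, as.data.frame(ex), as.data.frame(cds))
  })
  stats::setNames(models, tx_meta$transcript_id)
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param biotype transcript biotype label (e.g. `protein_coding`).
#' @param strand `"+"` or `"-"`.
#' @param chrom chromosome label.
#' @param exons,cds data.frames of 1-based closed intervals (`start`,
#'   `end`), genomically sorted and non-overlapping; `cds` may be empty
#'   for non-coding transcripts.
#' @return a `TranscriptModel` object.
#' @export
transcript_model <- function(transcript_id, gene_id, biotype, strand,
                             chrom, exons, cds = exons[0, ]) {
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  .assert(strand %in% c("+", "-"), "strand must be '+' or '-'")
  if (nrow(exons) > 1L) {
    .assert(all(exons$start[-1] > exons$end[-nrow(exons)]),
            "overlapping exons in transcript %s", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 biotype = biotype, strand = strand, chrom = chrom,
                 exons = exons, cds = cds),
            class = "TranscriptModel")
}

#' @method print TranscriptModel
#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s, %s, %s strand): %d exon(s), %d CDS segment(s)\n",
              x$transcript_id, x$gene_id, x$biotype, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

is_coding <- function(model) {
  identical(model$biotype, "protein_coding") && nrow(model$cds) > 0L
}

#' Write transcript models as a GENCODE-style GTF
#'
#' @param models list of `TranscriptModel` objects.
#' @param path output file.
#' @param source source field for the GTF lines.
#' @return the path, invisibly.
#' @export
write_gtf <- function(models, path, source = "pextr") {
  fmt_attr <- function(m, extra = "") {
    sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";%s',
            m$gene_id, m$transcript_id, m$biotype, extra)
  }
  lines <- unlist(lapply(models, function(m) {
    tx <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                  m$chrom, source, min(m$exons$start), max(m$exons$end),
                  m$strand, fmt_attr(m))
    ex <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                  m$chrom, source, m$exons$start, m$exons$end,
                  m$strand, fmt_attr(m))
    cds <- if (nrow(m$cds) > 0L) {
      sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\t%s",
              m$chrom, source, m$cds$start, m$cds$end, m$strand, fmt_attr(m))
    } else character()
    c(tx, ex, cds)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# VEP CSQ parsing

#' Read per-transcript consequences from VEP CSQ annotations in a VCF
#'
#' Parses the pipe-delimited CSQ INFO field written by VEP, splits
#' ampersand-joined consequence lists, reduces each (variant, transcript)
#' pair to its worst consequence, and keeps only consequences on
#' protein-coding transcripts. LOFTEE columns (`LoF`, `LoF_flags`) are
#' passed through when present. Multi-allelic records are split per
#' alternate allele; when the CSQ format carries an `Allele` column the
#' consequence entries are matched to their allele.
#'
#' @param vcf path to a VCF whose header defines the CSQ field format.
#' @param csq_field INFO key holding the annotations (default `"CSQ"`).
#' @param severity severity table from [read_severity_order()].
#' @return a `data.table` with one row per (variant, transcript):
#'   `chrom`, `pos`, `ref`, `alt`, `transcript_id`, `gene_id`,
#'   `worst_term`, `loftee_filter`, `loftee_flags`.
#' @export
read_vep_csq <- function(vcf, csq_field = "CSQ",
                         severity = read_severity_order()) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  meta <- v@meta
  hdr <- grep(sprintf("^##INFO=<ID=%s[,>]", csq_field), meta, value = TRUE)
  .assert(length(hdr) == 1L, "VCF header does not define the %s INFO field",
          csq_field)
  fmt <- sub('.*Format: ?([^">]+)"?>.*', "\\1", hdr)
  fields <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  .assert(all(c("Consequence", "Feature") %in% fields),
          "%s format lacks Consequence/Feature columns", csq_field)

  fix <- v@fix
  csq_raw <- vcfR::extract.info(v, element = csq_field)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    if (is.na(csq_raw[i])) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    entries <- strsplit(csq_raw[i], ",", fixed = TRUE)[[1]]
    parts <- strsplit(entries, "|", fixed = TRUE)
    bad <- lengths(parts) > length(fields)
    .assert(!any(bad), "CSQ entry with more fields than the header declares")
    ann <- data.table::as.data.table(
      do.call(rbind, lapply(parts, function(p) {
        length(p) <- length(fields)  # trailing empties
        p
      })))
    data.table::setnames(ann, fields)
    ann[is.na(ann)] <- ""
    ## per-alt assignment
    if ("Allele" %in% fields && length(alts) > 1L) {
      ann[, alt := .match_csq_allele(Allele, fix[i, "REF"], alts)]
    } else if (length(alts) == 1L) {
      ann[, alt := alts]
    } else {
      ann[, alt := alts[1]]
    }
    ann[, `:=`(chrom = fix[i, "CHROM"],
               pos = as.integer(fix[i, "POS"]),
               ref = fix[i, "REF"])]
    out[[i]] <- ann
  }
  ann <- data.table::rbindlist(out, use.names = TRUE, fill = TRUE)
  if (nrow(ann) == 0L) return(.empty_consequences())

  if ("BIOTYPE" %in% names(ann)) ann <- ann[BIOTYPE == "protein_coding"]
  if (nrow(ann) == 0L) return(.empty_consequences())

  ann[, worst_term := vapply(strsplit(Consequence, "&", fixed = TRUE),
                             worst_consequence, character(1),
                             severity = severity)]
  res <- data.table::data.table(
    chrom = ann$chrom, pos = ann$pos, ref = ann$ref, alt = ann$alt,
    transcript_id = strip_versions(ann$Feature),
    gene_id = strip_versions(if ("Gene" %in% names(ann)) ann$Gene else ""),
    worst_term = ann$worst_term,
    loftee_filter = if ("LoF" %in% names(ann)) ann$LoF else "",
    loftee_flags = if ("LoF_flags" %in% names(ann)) ann$LoF_flags else "")
  .order_records(res, severity)
}

.empty_consequences <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         transcript_id = character(), gene_id = character(),
                         worst_term = character(), loftee_filter = character(),
                         loftee_flags = character())
}

## VEP abbreviates the allele in CSQ (e.g. deletions as "-"); match each
## annotation row to one ALT, falling back to position in the ALT list
.match_csq_allele <- function(allele, ref, alts) {
  hit <- match(allele, alts)
  if (anyNA(hit)) {
    ## VEP-minimal representation: drop the shared leading base of indels
    trimmed <- ifelse(nchar(alts) > 1 | nchar(ref) > 1, sub("^.", "", alts), alts)
    trimmed[trimmed == ""] <- "-"
    hit[is.na(hit)] <- match(allele[is.na(hit)], trimmed)
  }
  hit[is.na(hit)] <- 1L
  alts[hit]
}
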