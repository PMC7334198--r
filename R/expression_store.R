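#' Read isoform quantification tables
#'
#' Parses transcript-level TPM quantifications into a long table with one
#' row per transcript per sample. Three dialects are supported:
#' \describe{
#'   \item{`rsem`}{RSEM `isoforms.results` files, one per sample, with at
#'     least `transcript_id`, `gene_id` and `TPM` columns.}
#'   \item{`salmon`}{salmon `quant.sf` files, one per sample, with `Name`
#'     and `TPM` columns. salmon rows carry no gene identifier, so a
#'     `transcript_gene_map` is required.}
#'   \item{`matrix`}{a single wide TSV with rows = transcripts and one
#'     column per sample; a `gene_id` column (or a map file) supplies the
#'     transcript-to-gene assignment.}
#' }
#'
#' @param paths character vector of file paths (one per sample for the
#'   `rsem` and `salmon` dialects; a single file for `matrix`). Names, if
#'   present, are used as sample identifiers; otherwise file basenames
#'   (without extension) are used.
#' @param dialect one of `"rsem"`, `"salmon"`, `"matrix"`.
#' @param transcript_gene_map optional path to a two-column headered TSV
#'   (`transcript_id`, `gene_id`). Required for salmon input.
#' @param strip_transcript_versions drop trailing `.N` version suffixes from
#'   transcript and gene identifiers (default `TRUE`; quantification and
#'   gene-model releases frequently disagree on versions).
#' @return a `data.table` with columns `transcript_id`, `gene_id`,
#'   `sample_id`, `tpm` (non-negative; one row per transcript per sample).
#' @export
read_isoform_quant <- function(paths,
                               dialect = c("rsem", "salmon", "matrix"),
                               transcript_gene_map = NULL,
                               strip_transcript_versions = TRUE) {
  dialect <- match.arg(dialect)
  .assert(all(file.exists(paths)), "input file not found: %s",
          paste(paths[!file.exists(paths)], collapse = ", "))

  sample_ids <- names(paths)
  if (is.null(sample_ids) || any(sample_ids == "")) {
    sample_ids <- sub("\\.[A-Za-z0-9.]+$", "", basename(paths))
  }

  map <- NULL
  if (!is.null(transcript_gene_map)) {
    map <- data.table::fread(transcript_gene_map, header = TRUE)
    data.table::setnames(map, 1:2, c("transcript_id", "gene_id"))
    if (strip_transcript_versions) {
      map[, transcript_id := strip_versions(transcript_id)]
      map[, gene_id := strip_versions(gene_id)]
    }
  }

  quant <- switch(dialect,
    rsem = data.table::rbindlist(lapply(seq_along(paths), function(i) {
      x <- data.table::fread(paths[i], header = TRUE)
      .assert(all(c("transcript_id", "gene_id", "TPM") %in% names(x)),
              "RSEM file %s lacks transcript_id/gene_id/TPM columns", paths[i])
      data.table::data.table(transcript_id = x$transcript_id,
                             gene_id = x$gene_id,
                             sample_id = sample_ids[i],
                             tpm = as.numeric(x$TPM))
    })),
    salmon = {
      .assert(!is.null(map),
              "salmon quantifications carry no gene id; transcript_gene_map is required")
      data.table::rbindlist(lapply(seq_along(paths), function(i) {
        x <- data.table::fread(paths[i], header = TRUE)
        .assert(all(c("Name", "TPM") %in% names(x)),
                "salmon file %s lacks Name/TPM columns", paths[i])
        data.table::data.table(transcript_id = x$Name,
                               sample_id = sample_ids[i],
                               tpm = as.numeric(x$TPM))
      }))
    },
    matrix = {
      .assert(length(paths) == 1L, "matrix dialect expects a single file")
      x <- data.table::fread(paths[1], header = TRUE)
      data.table::setnames(x, 1L, "transcript_id")
      id_cols <- intersect(c("transcript_id", "gene_id"), names(x))
      long <- data.table::melt(x, id.vars = id_cols,
                               variable.name = "sample_id",
                               value.name = "tpm",
                               variable.factor = FALSE)
      long[, tpm := as.numeric(tpm)]
      long
    })

  if (strip_transcript_versions) {
    quant[, transcript_id := strip_versions(transcript_id)]
    if ("gene_id" %in% names(quant)) quant[, gene_id := strip_versions(gene_id)]
  }

  if (!"gene_id" %in% names(quant)) {
    .assert(!is.null(map),
            "no gene_id column present; supply transcript_gene_map")
    missing <- setdiff(unique(quant$transcript_id), map$transcript_id)
    .assert(length(missing) == 0L,
            "transcript(s) absent from gene map: %s",
            paste(utils::head(missing, 5), collapse = ", "))
    quant <- map[quant, on = "transcript_id"]
  }

  .assert(all(quant$tpm >= 0), "negative TPM values encountered")
  .assert(anyDuplicated(quant, by = c("transcript_id", "sample_id")) == 0L,
          "duplicate (transcript, sample) rows in quantification input")
  n_genes <- quant[, data.table::uniqueN(gene_id), by = transcript_id]
  .assert(all(n_genes$V1 == 1L),
          "transcript mapped to multiple genes: %s",
          paste(utils::head(n_genes[V1 > 1L]$transcript_id, 5), collapse = ", "))
  data.table::setcolorder(quant, c("transcript_id", "gene_id", "sample_id", "tpm"))
  quant[]
}

#' Read a sample-to-tissue map
#'
#' @param path two-column headered TSV (`sample_id`, `tissue`).
#' @return a `data.table` with columns `sample_id` and `tissue`.
#' @export
read_sample_map <- function(path) {
  x <- data.table::fread(path, header = TRUE)
  data.table::setnames(x, 1:2, c("sample_id", "tissue"))
  .assert(anyDuplicated(x$sample_id) == 0L, "duplicate sample_id in sample map")
  x[]
}

#' Median transcript expression per tissue
#'
#' Collapses per-sample TPMs to the median per transcript per tissue, and
#' computes each gene's total expression per tissue as the sum of the
#' medians over all of its transcripts, coding and non-coding alike. The
#' gene total is the pext denominator, so non-coding transcripts must be
#' retained here: a gene whose output is dominated by a non-coding isoform
#' legitimately has low pext on its coding variants.
#'
#' A transcript absent from a sample's table is treated as TPM 0 in that
#' sample, so medians are always over the full sample count of the tissue.
#' Even sample counts use the midpoint of the two central values.
#'
#' @param quant long quantification table from [read_isoform_quant()].
#' @param samples sample map (`sample_id`, `tissue`), e.g. from
#'   [read_sample_map()].
#' @return a `TissueExpressionMatrix`: a list with
#'   \describe{
#'     \item{`medians`}{`data.table` of `transcript_id`, `gene_id`, one
#'       numeric column per tissue (median TPM).}
#'     \item{`gene_total`}{`data.table` of `gene_id` plus one column per
#'       tissue (sum of transcript medians).}
#'     \item{`tissues`}{ordered tissue labels.}
#'     \item{`n_samples`}{named integer, samples per tissue.}
#'   }
#' @export
median_by_tissue <- function(quant, samples) {
  samples <- data.table::as.data.table(samples)
  missing <- setdiff(unique(quant$sample_id), samples$sample_id)
  .assert(length(missing) == 0L,
          "sample(s) without tissue assignment: %s",
          paste(utils::head(missing, 5), collapse = ", "))

  tissues <- unique(samples$tissue)
  n_samples <- samples[, .N, by = tissue]
  n_by_tissue <- stats::setNames(n_samples$N, n_samples$tissue)

  q <- samples[quant, on = "sample_id"]
  tx_gene <- unique(quant[, .(transcript_id, gene_id)])

  ## median over all samples of the tissue, counting absent pairs as zero
  med <- q[, .(median_tpm = .median_with_zeros(tpm, n_by_tissue[[.BY$tissue]])),
           by = .(transcript_id, tissue)]
  medians <- data.table::dcast(med, transcript_id ~ tissue,
                               value.var = "median_tpm", fill = 0)
  medians <- tx_gene[medians, on = "transcript_id"]
  data.table::setcolorder(medians, c("transcript_id", "gene_id", tissues))

  gene_total <- medians[, lapply(.SD, sum), by = gene_id, .SDcols = tissues]

  new_tissue_matrix(medians, gene_total, tissues, n_by_tissue[tissues])
}

## median of `x` padded with zeros up to n values (transcripts missing from
## some samples' tables count as unexpressed there)
.median_with_zeros <- function(x, n) {
  if (length(x) < n) x <- c(x, numeric(n - length(x)))
  stats::median(x)
}

new_tissue_matrix <- function(medians, gene_total, tissues, n_samples) {
  structure(list(medians = medians, gene_total = gene_total,
                 tissues = tissues, n_samples = n_samples),
            class = "TissueExpressionMatrix")
}

#' @method print TissueExpressionMatrix
#' @export
print.TissueExpressionMatrix <- function(x, ...) {
  cat(sprintf("TissueExpressionMatrix: %d transcripts, %d genes, %d tissues\n",
              nrow(x$medians), nrow(x$gene_total), length(x$tissues)))
  cat("tissues:", paste(utils::head(x$tissues, 8), collapse = ", "),
      if (length(x$tissues) > 8) "..." else "", "\n")
  invisible(x)
}

#' Restrict a tissue expression matrix to a tissue subset
#'
#' Drops excluded tissues and tissues with fewer than `min_samples`
#' samples. With the GTEx-style defaults (reproductive tissues and cell
#' lines excluded, at least 100 samples) this reproduces the 38-tissue set
#' used for cross-tissue pext means.
#'
#' @param matrix a `TissueExpressionMatrix`.
#' @param exclude character vector of tissue labels to drop (see
#'   [default_tissue_exclusions()]).
#' @param min_samples minimum number of samples a tissue must have.
#' @return a `TissueExpressionMatrix` restricted to the retained tissues.
#' @export
select_tissues <- function(matrix, exclude = character(), min_samples = 0L) {
  .assert(inherits(matrix, "TissueExpressionMatrix"),
          "expected a TissueExpressionMatrix")
  .assert(min_samples >= 0, "min_samples must be non-negative")
  keep <- setdiff(matrix$tissues, exclude)
  keep <- keep[matrix$n_samples[keep] >= min_samples]
  .assert(length(keep) > 0L,
          "no tissues retained after exclusion/minimum-sample filtering")
  new_tissue_matrix(
    matrix$medians[, c("transcript_id", "gene_id", keep), with = FALSE],
    matrix$gene_total[, c("gene_id", keep), with = FALSE],
    keep, matrix$n_samples[keep])
}

#' Default tissue exclusion list
#'
#' The reproductive tissues and derived cell lines conventionally excluded
#' before computing cross-tissue pext means on GTEx-style tissue labels.
#' Tissues with small sample counts are handled separately via the
#' `min_samples` argument of [select_tissues()].
#'
#' @return character vector of tissue labels.
#' @export
default_tissue_exclusions <- function() {
  c("Cervix_Ectocervix", "Cervix_Endocervix", "Fallopian_Tube",
    "Prostate", "Uterus", "Ovary", "Testis", "Vagina",
    "Cells_Transformed_fibroblasts", "Cells_EBV-transformed_lymphocytes")
}

#' Serialize / load a tissue expression matrix
#'
#' Writes the transcript medians and the gene totals as two plain TSVs
#' (`<stem>.medians.tsv`, `<stem>.gene_totals.tsv`) plus a small
#' `<stem>.tissues.tsv` with per-tissue sample counts.
#'
#' @param matrix a `TissueExpressionMatrix`.
#' @param stem output path stem.
#' @return `write_tx_matrix`: the stem, invisibly. `read_tx_matrix`: a
#'   `TissueExpressionMatrix`.
#' @export
write_tx_matrix <- function(matrix, stem) {
  data.table::fwrite(matrix$medians, paste0(stem, ".medians.tsv"), sep = "\t")
  data.table::fwrite(matrix$gene_total, paste0(stem, ".gene_totals.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(tissue = matrix$tissues,
                           n_samples = as.integer(matrix$n_samples)),
    paste0(stem, ".tissues.tsv"), sep = "\t")
  invisible(stem)
}

#' @rdname write_tx_matrix
#' @export
read_tx_matrix <- function(stem) {
  medians <- data.table::fread(paste0(stem, ".medians.tsv"))
  gene_total <- data.table::fread(paste0(stem, ".gene_totals.tsv"))
  tt <- data.table::fread(paste0(stem, ".tissues.tsv"))
  new_tissue_matrix(medians, gene_total, tt$tissue,
                    stats::setNames(as.integer(tt$n_samples), tt$tissue))
}
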