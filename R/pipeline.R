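#' Run configuration
#'
#' Bundles the tunable thresholds of the annotation pipeline: the tissue
#' exclusion list and minimum sample count used when selecting tissues,
#' the expression-bin boundaries, the gene-level maximum-pext threshold,
#' the severity order, the tissue subset and summary mode for
#' cross-tissue means, and a seed.
#'
#' @param tissue_exclusions tissues dropped before cross-tissue means
#'   (default [default_tissue_exclusions()]).
#' @param min_samples minimum samples per tissue (default 100).
#' @param bin_low,bin_high expression-bin boundaries (defaults 0.1, 0.9).
#' @param gene_filter_threshold gene maximum-pext threshold (default 0.2).
#' @param severity_path optional severity-order TSV override.
#' @param mean_tissues optional tissue subset for the cross-tissue
#'   summary (e.g. brain tissues for neurodevelopmental analyses).
#' @param summary_mode `"mean"` or `"max"` across tissues.
#' @param seed integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(tissue_exclusions = default_tissue_exclusions(),
                       min_samples = 100L, bin_low = 0.1, bin_high = 0.9,
                       gene_filter_threshold = 0.2, severity_path = NULL,
                       mean_tissues = NULL,
                       summary_mode = c("mean", "max"), seed = 1L) {
  summary_mode <- match.arg(summary_mode)
  .assert(bin_low > 0 && bin_high < 1 && bin_low < bin_high,
          "bin thresholds must satisfy 0 < low < high < 1")
  .assert(gene_filter_threshold > 0 && gene_filter_threshold < 1,
          "gene filter threshold must lie in (0, 1)")
  structure(list(tissue_exclusions = tissue_exclusions,
                 min_samples = as.integer(min_samples),
                 bin_low = bin_low, bin_high = bin_high,
                 gene_filter_threshold = gene_filter_threshold,
                 severity_path = severity_path,
                 mean_tissues = mean_tissues, summary_mode = summary_mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration alongside outputs
#'
#' @param config a [run_config()].
#' @param path output file (key-value text).
#' @return the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  kv <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, if (is.null(v)) "" else paste(v, collapse = ","))
  }, character(1))
  writeLines(kv, path)
  invisible(path)
}

#' Prepare a tissue expression matrix from quantification files
#'
#' Reads isoform quantifications and the sample map, computes median
#' transcript expression per tissue, applies the tissue selection, and
#' serializes the matrix.
#'
#' @param quant_paths quantification files (see [read_isoform_quant()]).
#' @param sample_map_path sample-to-tissue TSV.
#' @param out_stem output path stem for the serialized matrix.
#' @param dialect quantification dialect.
#' @param transcript_gene_map optional map file (salmon).
#' @param config a [run_config()].
#' @param apply_tissue_selection apply exclusions/minimum samples
#'   (default TRUE).
#' @return the `TissueExpressionMatrix`, invisibly (also written to
#'   `out_stem`).
#' @export
run_prepare <- function(quant_paths, sample_map_path, out_stem,
                        dialect = "rsem", transcript_gene_map = NULL,
                        config = run_config(),
                        apply_tissue_selection = TRUE) {
  quant <- read_isoform_quant(quant_paths, dialect = dialect,
                              transcript_gene_map = transcript_gene_map)
  samples <- read_sample_map(sample_map_path)
  mat <- median_by_tissue(quant, samples)
  message(sprintf("tissue census: %s",
                  paste(sprintf("%s=%d", mat$tissues, mat$n_samples),
                        collapse = ", ")))
  if (apply_tissue_selection) {
    mat <- select_tissues(mat, exclude = config$tissue_exclusions,
                          min_samples = config$min_samples)
  }
  write_tx_matrix(mat, out_stem)
  invisible(mat)
}

#' Annotate a VCF with pext values
#'
#' Computes per-transcript consequences (from the VCF's CSQ field, or by
#' classifying against GTF gene models and a genome sequence), derives
#' ext and pext per annotation class, applies the gene-level QC filter
#' and the expression-bin filter, and writes an annotated VCF plus a flat
#' per-class TSV and a filter report.
#'
#' @param vcf_path input VCF.
#' @param matrix a `TissueExpressionMatrix` (or a stem accepted by
#'   [read_tx_matrix()]).
#' @param out_dir output directory.
#' @param gtf_path,genome GTF models and chromosome sequences for
#'   classifier mode; leave `NULL` to use the VCF's CSQ annotations.
#' @param config a [run_config()].
#' @param filter_bin expression bin removed by the filter (default
#'   `"low"`).
#' @return a list with `pext` (flat table), `filter` (result of
#'   [filter_variants()]), `gene_qc` (QC table) and output `paths`,
#'   invisibly.
#' @export
run_annotate <- function(vcf_path, matrix, out_dir, gtf_path = NULL,
                         genome = NULL, config = run_config(),
                         filter_bin = "low") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(matrix)) matrix <- read_tx_matrix(matrix)
  severity <- read_severity_order(config$severity_path)

  if (!is.null(gtf_path)) {
    .assert(!is.null(genome), "classifier mode requires genome sequences")
    models <- read_gtf(gtf_path)
    variants <- .read_vcf_sites(vcf_path)
    cons <- classify_variants(variants, models, genome, severity = severity)
  } else {
    models <- NULL
    cons <- read_vep_csq(vcf_path, severity = severity)
  }

  paths <- list(tsv = file.path(out_dir, "pext.tsv"),
                vcf = file.path(out_dir, "annotated.vcf"),
                report = file.path(out_dir, "filter_report.tsv"),
                gene_qc = file.path(out_dir, "gene_qc.tsv"),
                config = file.path(out_dir, "run_config.txt"))
  write_run_config(config, paths$config)

  if (nrow(cons) == 0L) {
    empty <- data.table::data.table()
    data.table::fwrite(empty, paths$tsv, sep = "\t")
    file.copy(vcf_path, paths$vcf, overwrite = TRUE)
    return(invisible(list(pext = empty, filter = NULL, gene_qc = NULL,
                          paths = paths)))
  }

  ext <- ext_values(cons, matrix, missing_transcript = "zero")
  px <- pext_values(ext, matrix, tissues = config$mean_tissues,
                    summary = config$summary_mode)
  px[, bin := assign_bin(mean_pext, config$bin_low, config$bin_high)]

  gene_qc <- if (!is.null(models)) {
    gene_max_pext_filter(models, matrix,
                         threshold = config$gene_filter_threshold)
  } else NULL
  blacklist <- if (!is.null(gene_qc)) gene_qc[excluded == TRUE]$gene_id else character()

  flt <- filter_variants(px, bin = filter_bin, gene_blacklist = blacklist)

  data.table::fwrite(px, paths$tsv, sep = "\t", na = "NA")
  .write_annotated_vcf(vcf_path, px, matrix$tissues, paths$vcf, severity)
  write_filter_report(flt$report, paths$report)
  if (!is.null(gene_qc)) data.table::fwrite(gene_qc, paths$gene_qc, sep = "\t")

  invisible(list(pext = px, filter = flt, gene_qc = gene_qc, paths = paths))
}

## minimal site reader for classifier mode (CHROM/POS/REF/ALT only)
.read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()))
  }
  dt <- data.table::data.table(chrom = fix[, "CHROM"],
                               pos = as.integer(fix[, "POS"]),
                               ref = fix[, "REF"], alt = fix[, "ALT"])
  ## split multi-allelic records into per-alt rows
  dt <- dt[, .(alt = strsplit(alt, ",", fixed = TRUE)[[1]]),
           by = .(chrom, pos, ref)]
  dt[]
}

## append PEXT_* INFO keys to the worst class of each variant
.write_annotated_vcf <- function(vcf_path, px, tissues, out_path, severity) {
  lines <- readLines(vcf_path)
  is_hdr <- startsWith(lines, "#")
  extra_hdr <- c(
    '##INFO=<ID=PEXT_MEAN,Number=1,Type=Float,Description="Cross-tissue mean pext of the worst annotation class">',
    '##INFO=<ID=PEXT_BIN,Number=1,Type=String,Description="Expression bin (low/medium/high)">',
    '##INFO=<ID=PEXT_CLASS,Number=1,Type=String,Description="Worst annotation class">')
  hdr <- lines[is_hdr]
  chrom_line <- which(startsWith(hdr, "#CHROM"))
  hdr <- append(hdr, extra_hdr, after = chrom_line - 1L)

  ## worst class per variant
  worst <- data.table::copy(px)
  worst[, class_rank := consequence_rank(worst_term, severity)]
  data.table::setorderv(worst, c(.variant_key, "class_rank"))
  worst <- worst[, .SD[1L], by = .variant_key]

  body <- lines[!is_hdr]
  out_body <- vapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    key <- worst[chrom == f[1] & pos == as.integer(f[2]) & ref == f[4] &
                 alt == strsplit(f[5], ",", fixed = TRUE)[[1]][1]]
    if (nrow(key) == 0L) return(ln)
    mp <- key$mean_pext[1]
    info <- sprintf("PEXT_MEAN=%s;PEXT_BIN=%s;PEXT_CLASS=%s",
                    if (is.na(mp)) "." else sprintf("%.6g", mp),
                    if (is.na(key$bin[1])) "." else key$bin[1],
                    key$worst_term[1])
    f[8] <- if (f[8] %in% c(".", "")) info else paste(f[8], info, sep = ";")
    paste(f, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(c(hdr, out_body), out_path)
  invisible(out_path)
}
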