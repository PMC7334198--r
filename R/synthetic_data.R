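#' Specification for a synthetic fixture
#'
#' Describes a self-contained test universe: multi-isoform genes with
#' shared and isoform-unique exons, a mix of coding and non-coding
#' isoforms, tissue-specific isoform usage, and a multiplicative
#' log-normal noise model for per-sample TPMs. Every downstream quantity
#' (median profile, gene totals, per-variant pext) is analytically known
#' from the noiseless usage profile, so pipeline output can be checked
#' exactly.
#'
#' @param seed integer seed; all generators are deterministic given it.
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer range (min, max) of coding isoforms
#'   per gene.
#' @param frac_noncoding fraction of additional non-coding isoforms per
#'   gene (each gene gets `round(coding * frac)` of them, at least one
#'   for the QC-fail gene).
#' @param tissues tissue labels.
#' @param n_samples_per_tissue samples drawn per tissue.
#' @param noise_sigma standard deviation of the log-normal multiplicative
#'   TPM noise (0 = noiseless).
#' @param n_qc_fail_genes how many genes get a dominant non-coding
#'   isoform (>80% of output) so the gene-level maximum-pext filter has
#'   something to catch.
#' @param zero_expression_tissue if `TRUE`, the last gene has zero total
#'   expression in the last tissue, to exercise NA pext semantics.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 3L,
                         isoforms_per_gene = c(2L, 4L),
                         frac_noncoding = 0.25,
                         tissues = c("adipose", "brain_cortex", "liver",
                                     "muscle"),
                         n_samples_per_tissue = 30L,
                         noise_sigma = 0.2,
                         n_qc_fail_genes = 1L,
                         zero_expression_tissue = TRUE) {
  .assert(n_genes >= 1L, "at least one gene required")
  .assert(all(isoforms_per_gene >= 1L), "at least one isoform per gene")
  .assert(n_qc_fail_genes <= n_genes, "more QC-fail genes than genes")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 frac_noncoding = frac_noncoding, tissues = tissues,
                 n_samples_per_tissue = as.integer(n_samples_per_tissue),
                 noise_sigma = noise_sigma,
                 n_qc_fail_genes = as.integer(n_qc_fail_genes),
                 zero_expression_tissue = zero_expression_tissue),
            class = "fixture_spec")
}

## codons free of stop codons and of the engineered motifs' ambiguity
.safe_codons <- c("GCT", "GCC", "GGA", "GGC", "CTT", "CTC", "ACA", "ACC",
                  "TCC", "TCT", "GAG", "GAA", "AAG", "AAA", "GTT", "GTC",
                  "CGT", "CGC", "ATC", "ATT")

#' Generate synthetic gene models
#'
#' Builds `n_genes` genes on one synthetic chromosome. Each gene has a
#' shared first exon, one isoform-unique middle exon per coding isoform,
#' and a shared last exon ending in a stop codon; coding isoform `j`
#' splices exon 1 to middle exon `j` to the last exon. Exon lengths are
#' multiples of three so codon boundaries coincide with exon boundaries
#' in every isoform. Engineered codons (a `CAA` that a C>T turns into a
#' stop, a `TTA` whose third base is synonymous-mutable) are placed at
#' fixed positions in the shared and unique exons so variants of every
#' class can be created with known affected-transcript sets. Non-coding
#' isoforms (biotype `processed_transcript`) overlap the coding footprint.
#' Gene strands alternate between `+` and `-`.
#'
#' @param spec a [fixture_spec()].
#' @return a list with `models` (named list of `TranscriptModel`),
#'   `genome` (named character vector of chromosome sequence), and
#'   `layout` (internal per-gene coordinate bookkeeping used by
#'   [generate_variants()]).
#' @export
generate_gene_models <- function(spec) {
  set.seed(spec$seed)
  exon1_len <- 18L; mid_len <- 15L; last_len <- 18L; intron_len <- 30L
  flank <- 50L

  models <- list()
  layout <- list()
  chrom <- "chrS"
  genome_parts <- character()
  offset <- 0L

  for (g in seq_len(spec$n_genes)) {
    gene_id <- sprintf("GENE%03d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    iso_range <- seq(spec$isoforms_per_gene[1], spec$isoforms_per_gene[2])
    n_coding <- if (length(iso_range) == 1L) iso_range else sample(iso_range, 1L)
    n_nc <- round(n_coding * spec$frac_noncoding)
    if (g <= spec$n_qc_fail_genes) n_nc <- max(1L, n_nc)

    ## local + orientation layout
    p <- flank
    exon1 <- c(p + 1L, p + exon1_len); p <- p + exon1_len
    mids <- vector("list", n_coding)
    for (j in seq_len(n_coding)) {
      p <- p + intron_len
      mids[[j]] <- c(p + 1L, p + mid_len)
      p <- p + mid_len
    }
    p <- p + intron_len
    last <- c(p + 1L, p + last_len); p <- p + last_len
    L <- p + flank

    ## local sequence: random safe codons, engineered motifs, GT..AG introns
    seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    fill_codons <- function(iv) {
      n_codon <- (iv[2] - iv[1] + 1L) %/% 3L
      codons <- sample(.safe_codons, n_codon, replace = TRUE)
      strsplit(paste(codons, collapse = ""), "")[[1]]
    }
    seq_chars[exon1[1]:exon1[2]] <- fill_codons(exon1)
    for (m in mids) seq_chars[m[1]:m[2]] <- fill_codons(m)
    seq_chars[last[1]:last[2]] <- fill_codons(last)
    ## engineered codons: exon1 codon 2 = CAA (C>T => TAA stop),
    ## exon1 codon 3 = TTA (A>G synonymous Leu), middle codon 2 = CAA
    seq_chars[(exon1[1] + 3L):(exon1[1] + 5L)] <- c("C", "A", "A")
    seq_chars[(exon1[1] + 6L):(exon1[1] + 8L)] <- c("T", "T", "A")
    for (m in mids) seq_chars[(m[1] + 3L):(m[1] + 5L)] <- c("C", "A", "A")
    ## terminal stop codon in the last exon
    seq_chars[(last[2] - 2L):last[2]] <- c("T", "A", "A")
    ## canonical splice dinucleotides at every exon boundary
    all_ex <- c(list(exon1), mids, list(last))
    for (k in seq_along(all_ex)) {
      iv <- all_ex[[k]]
      if (k < length(all_ex)) seq_chars[(iv[2] + 1L):(iv[2] + 2L)] <- c("G", "T")
      if (k > 1L) seq_chars[(iv[1] - 2L):(iv[1] - 1L)] <- c("A", "G")
    }
    local_seq <- paste(seq_chars, collapse = "")

    ## map a local (transcription-orientation) interval to genomic coords
    map_iv <- function(iv) {
      if (strand == "+") c(offset + iv[1], offset + iv[2])
      else c(offset + L - iv[2] + 1L, offset + L - iv[1] + 1L)
    }
    iv_df <- function(ivs) {
      m <- do.call(rbind, lapply(ivs, map_iv))
      df <- data.frame(start = m[, 1], end = m[, 2])
      df[order(df$start), , drop = FALSE]
    }

    tx_ids <- character()
    for (j in seq_len(n_coding)) {
      tid <- sprintf("%s.T%02d", gene_id, j)
      ex <- list(exon1, mids[[j]], last)
      cds <- list(exon1, mids[[j]], c(last[1], last[2] - 3L))
      models[[tid]] <- transcript_model(tid, gene_id, "protein_coding",
                                        strand, chrom, iv_df(ex), iv_df(cds))
      tx_ids <- c(tx_ids, tid)
    }
    for (j in seq_len(n_nc)) {
      tid <- sprintf("%s.NC%02d", gene_id, j)
      ex <- list(exon1, mids[[1L]], last)
      models[[tid]] <- transcript_model(tid, gene_id, "processed_transcript",
                                        strand, chrom, iv_df(ex))
      tx_ids <- c(tx_ids, tid)
    }

    layout[[gene_id]] <- list(gene_id = gene_id, strand = strand,
                              offset = offset, L = L,
                              exon1 = exon1, mids = mids, last = last,
                              local_seq = local_seq,
                              coding = tx_ids[seq_len(n_coding)],
                              noncoding = if (n_nc > 0) tx_ids[n_coding + seq_len(n_nc)] else character(),
                              qc_fail = g <= spec$n_qc_fail_genes)

    genome_parts[g] <- if (strand == "+") local_seq else .revcomp(local_seq)
    offset <- offset + L
  }

  genome <- stats::setNames(paste(genome_parts, collapse = ""), chrom)
  list(models = models, genome = genome, layout = layout)
}

#' Generate synthetic expression data with known ground truth
#'
#' Draws tissue-specific isoform usage profiles and per-sample TPMs
#' around them. For each tissue the gene's total TPM and the isoform
#' usage weights define a noiseless median profile; per-sample TPMs
#' multiply the profile by `exp(N(0, sigma^2))` noise (the log-normal has
#' median 1, so sample medians converge on the profile). QC-fail genes
#' give their non-coding isoform a dominant (0.85--0.95) usage share in
#' every tissue; if requested, the last gene is entirely unexpressed in
#' the last tissue.
#'
#' @param fixture output of [generate_gene_models()].
#' @param spec the same [fixture_spec()].
#' @return a list with `quant` (long per-sample TPM `data.table`),
#'   `samples` (sample-to-tissue map), and `truth`, a
#'   `TissueExpressionMatrix` built from the noiseless profile (medians =
#'   profile, totals = per-gene sums).
#' @export
generate_expression <- function(fixture, spec) {
  set.seed(spec$seed + 1L)
  models <- fixture$models
  layout <- fixture$layout
  tissues <- spec$tissues
  tx <- data.table::data.table(
    transcript_id = vapply(models, `[[`, character(1), "transcript_id"),
    gene_id = vapply(models, `[[`, character(1), "gene_id"))

  profile <- data.table::copy(tx)
  genes <- names(layout)
  for (tt in tissues) profile[, (tt) := 0]
  for (g in genes) {
    lay <- layout[[g]]
    ids <- c(lay$coding, lay$noncoding)
    for (tt in tissues) {
      if (spec$zero_expression_tissue && g == genes[length(genes)] &&
          tt == tissues[length(tissues)]) {
        next  # gene total stays 0 in this tissue
      }
      total <- stats::runif(1, 5, 50)
      if (lay$qc_fail && length(lay$noncoding) > 0) {
        nc_share <- stats::runif(1, 0.85, 0.95)
        w_nc <- rep(nc_share / length(lay$noncoding), length(lay$noncoding))
        w_c <- stats::rgamma(length(lay$coding), shape = 1)
        w_c <- (1 - nc_share) * w_c / sum(w_c)
        w <- c(w_c, w_nc)
      } else {
        w <- stats::rgamma(length(ids), shape = 0.8)
        w <- w / sum(w)
      }
      profile[match(ids, transcript_id), (tt) := total * w]
    }
  }

  samples <- data.table::data.table(
    sample_id = sprintf("S%s_%03d", rep(seq_along(tissues),
                                        each = spec$n_samples_per_tissue),
                        seq_len(spec$n_samples_per_tissue)),
    tissue = rep(tissues, each = spec$n_samples_per_tissue))

  quant <- data.table::rbindlist(lapply(seq_len(nrow(samples)), function(i) {
    tt <- samples$tissue[i]
    mu <- profile[[tt]]
    noise <- if (spec$noise_sigma > 0) {
      exp(stats::rnorm(length(mu), 0, spec$noise_sigma))
    } else rep(1, length(mu))
    data.table::data.table(transcript_id = profile$transcript_id,
                           gene_id = profile$gene_id,
                           sample_id = samples$sample_id[i],
                           tpm = mu * noise)
  }))

  gene_total <- profile[, lapply(.SD, sum), by = gene_id, .SDcols = tissues]
  truth <- new_tissue_matrix(
    profile, gene_total, tissues,
    stats::setNames(rep(spec$n_samples_per_tissue, length(tissues)), tissues))

  list(quant = quant, samples = samples, truth = truth)
}

#' Generate engineered variants with known consequences and pext
#'
#' Creates, for every gene, one variant per engineered class: a
#' stop-gain on the isoform-unique middle exon of isoform 1, a stop-gain
#' on the shared first exon, a synonymous change on the shared exon, a
#' splice-donor SNV in the first intron, and (on plus-strand genes) a
#' 1-bp frameshift insertion in the shared exon. Because the affected
#' transcript sets are known by construction, each variant's expected
#' per-tissue pext, mean pext and bin are computed analytically from the
#' noiseless expression profile — independently of the classifier.
#'
#' @param fixture output of [generate_gene_models()].
#' @param truth the `truth` matrix from [generate_expression()].
#' @param tissues tissue subset for the expected mean (default: all).
#' @return a `data.table` with `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `intended_class`, `affected_transcripts` (comma-joined),
#'   `expected_mean_pext`, `expected_bin`, `variant_id`.
#' @export
generate_variants <- function(fixture, truth, tissues = NULL) {
  layout <- fixture$layout
  tissues <- tissues %||% truth$tissues
  chrom <- names(fixture$genome)
  out <- list()

  for (g in names(layout)) {
    lay <- layout[[g]]
    loc <- function(p) {  # local position -> genomic position
      if (lay$strand == "+") lay$offset + p else lay$offset + lay$L - p + 1L
    }
    base_at <- function(p) substr(lay$local_seq, p, p)
    flip <- function(b) if (lay$strand == "+") b else .revcomp(b)

    add <- function(id, p_local, ref_local, alt_local, class, affected) {
      out[[length(out) + 1L]] <<- data.table::data.table(
        chrom = chrom, pos = loc(p_local),
        ref = flip(ref_local), alt = flip(alt_local),
        gene_id = g, intended_class = class,
        affected_transcripts = paste(affected, collapse = ","),
        variant_id = id)
    }

    ## stop-gain on isoform-1-unique middle exon (codon 2, CAA -> TAA)
    p <- lay$mids[[1]][1] + 3L
    add(sprintf("%s_stop_unique", g), p, "C", "T", "stop_gained", lay$coding[1])
    ## stop-gain on shared exon 1 (codon 2)
    p <- lay$exon1[1] + 3L
    add(sprintf("%s_stop_shared", g), p, "C", "T", "stop_gained", lay$coding)
    ## synonymous on shared exon 1 (codon 3, TTA -> TTG, Leu -> Leu)
    p <- lay$exon1[1] + 8L
    add(sprintf("%s_synonymous", g), p, "A", "G", "synonymous_variant",
        lay$coding)
    ## splice donor: first intronic base after exon 1 (G of the GT)
    p <- lay$exon1[2] + 1L
    add(sprintf("%s_splice_donor", g), p, base_at(p), "C",
        "splice_donor_variant", lay$coding)
    ## frameshift: 1-bp insertion inside exon 1 CDS (plus-strand genes,
    ## where VCF left-anchoring matches local orientation)
    if (lay$strand == "+") {
      p <- lay$exon1[1] + 12L
      add(sprintf("%s_frameshift", g), p, base_at(p),
          paste0(base_at(p), "A"), "frameshift_variant", lay$coding)
    }
  }
  variants <- data.table::rbindlist(out)

  ## analytic expected pext from the noiseless profile
  med <- truth$medians
  totals <- truth$gene_total
  variants[, expected_mean_pext := {
    vapply(seq_len(.N), function(i) {
      tx_ids <- strsplit(affected_transcripts[i], ",", fixed = TRUE)[[1]]
      gt <- totals[gene_id == variants$gene_id[i]]
      vals <- vapply(tissues, function(tt) {
        denom <- gt[[tt]]
        if (denom <= 0) return(NA_real_)
        sum(med[transcript_id %in% tx_ids][[tt]]) / denom
      }, numeric(1))
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, numeric(1))
  }]
  variants[, expected_bin := assign_bin(expected_mean_pext)]
  data.table::setorderv(variants, c("chrom", "pos", "ref", "alt"))
  variants[]
}

#' Write engineered variants as a VCF
#'
#' @param variants table from [generate_variants()].
#' @param path output VCF path.
#' @param contig_length length of the synthetic chromosome (for the
#'   header); inferred from the maximum position if missing.
#' @return the path, invisibly.
#' @export
write_variants_vcf <- function(variants, path, contig_length = NULL) {
  contig_length <- contig_length %||% (max(variants$pos) + 1000L)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", variants$chrom[1],
                   contig_length),
           "##INFO=<ID=INTENDED,Number=1,Type=String,Description=\"Engineered consequence class\">",
           "##INFO=<ID=EXPECTED_MEAN_PEXT,Number=1,Type=Float,Description=\"Analytic mean pext\">",
           "##INFO=<ID=EXPECTED_BIN,Number=1,Type=String,Description=\"Analytic expression bin\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("INTENDED=%s;EXPECTED_MEAN_PEXT=%s;EXPECTED_BIN=%s",
                  variants$intended_class,
                  ifelse(is.na(variants$expected_mean_pext), ".",
                         sprintf("%.6g", variants$expected_mean_pext)),
                  ifelse(is.na(variants$expected_bin), ".",
                         variants$expected_bin))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom, variants$pos, variants$variant_id,
                  variants$ref, variants$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write per-sample RSEM-style quantification files and a sample map
#'
#' @param quant long quantification table (`transcript_id`, `gene_id`,
#'   `sample_id`, `tpm`).
#' @param samples sample-to-tissue map.
#' @param dir output directory (created if needed).
#' @return named list with `quant_paths` (named by sample) and
#'   `sample_map` path.
#' @export
write_rsem_files <- function(quant, samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(unique(quant$sample_id), function(s) {
    f <- file.path(dir, paste0(s, ".isoforms.results"))
    sub <- quant[sample_id == s, .(transcript_id, gene_id, TPM = tpm)]
    data.table::fwrite(sub, f, sep = "\t")
    f
  }, character(1))
  map_path <- file.path(dir, "sample_map.tsv")
  data.table::fwrite(samples, map_path, sep = "\t")
  list(quant_paths = paths, sample_map = map_path)
}

#' Simulate case-control de novo burden tables
#'
#' Draws Poisson event counts for a case and a control cohort with a
#' known true rate ratio, for rate-ratio recovery and confidence-interval
#' coverage experiments.
#'
#' @param rr_true true case/control rate ratio (> 0).
#' @param n_case,n_ctrl cohort sizes.
#' @param baseline_rate control per-individual event rate.
#' @param seed integer seed.
#' @param reps number of replicate tables.
#' @return a `data.table` with `rep_id`, `x1`, `n1`, `x2`, `n2`.
#' @export
generate_burden_counts <- function(rr_true, n_case, n_ctrl, baseline_rate,
                                   seed = 1L, reps = 1L) {
  .assert(rr_true > 0, "rr_true must be positive")
  set.seed(seed)
  data.table::data.table(
    rep_id = seq_len(reps),
    x1 = stats::rpois(reps, rr_true * baseline_rate * n_case),
    n1 = n_case,
    x2 = stats::rpois(reps, baseline_rate * n_ctrl),
    n2 = n_ctrl)
}
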