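#' Classify a simple variant against one transcript model
#'
#' A deliberately minimal consequence classifier used to build
#' self-contained fixtures; real analyses consume VEP CSQ annotations via
#' [read_vep_csq()]. For an SNV or a simple left-anchored indel it returns
#' one term:
#' \itemize{
#'   \item `splice_donor_variant` / `splice_acceptor_variant` for the two
#'     intronic bases flanking an exon (strand-aware);
#'   \item within the CDS: `stop_gained`, `missense_variant` or
#'     `synonymous_variant` for SNVs by codon translation;
#'     `frameshift_variant` for indels whose length change is not a
#'     multiple of three, otherwise `inframe_insertion`/`inframe_deletion`;
#'   \item `splice_region_variant` for the 3 exonic / 3--8 intronic bases
#'     around an exon boundary when no coding consequence applies;
#'   \item `intron_variant` deeper into an intron;
#'   \item `non_coding_transcript_exon_variant` for exonic positions on a
#'     transcript without CDS.
#' }
#' UTRs, stop/start loss and multi-nucleotide variants are out of scope.
#'
#' @param chrom,pos,ref,alt the variant (VCF conventions: 1-based `pos`,
#'   indels left-anchored with the shared base included).
#' @param model a `TranscriptModel`.
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences (used to verify `ref` and translate codons).
#' @return a single consequence term.
#' @export
classify_consequence <- function(chrom, pos, ref, alt, model, genome) {
  .assert(identical(chrom, model$chrom),
          "variant on %s but transcript %s is on %s",
          chrom, model$transcript_id, model$chrom)
  seq <- .chrom_seq(genome, chrom)
  exons <- model$exons
  lo <- min(exons$start) - 8L
  hi <- max(exons$end) + 8L
  .assert(pos >= lo && pos <= hi,
          "variant at %s:%d outside footprint of transcript %s",
          chrom, pos, model$transcript_id)
  obs <- substr(seq, pos, pos + nchar(ref) - 1L)
  .assert(identical(toupper(obs), toupper(ref)),
          "ref allele %s does not match sequence %s at %s:%d",
          ref, obs, chrom, pos)

  in_exon <- any(pos >= exons$start & pos <= exons$end)
  splice <- .splice_site(pos, exons, model$strand)
  if (!is.na(splice) && splice %in% c("splice_donor_variant",
                                      "splice_acceptor_variant")) {
    return(splice)
  }

  cds <- model$cds
  in_cds <- nrow(cds) > 0L && any(pos >= cds$start & pos <= cds$end)
  if (in_cds) {
    if (nchar(ref) != nchar(alt)) {
      shift <- abs(nchar(ref) - nchar(alt))
      if (shift %% 3L != 0L) return("frameshift_variant")
      return(if (nchar(alt) > nchar(ref)) "inframe_insertion" else "inframe_deletion")
    }
    return(.classify_cds_snv(pos, ref, alt, model, seq))
  }
  if (!is.na(splice)) return(splice)              # splice_region_variant
  if (in_exon) return("non_coding_transcript_exon_variant")
  "intron_variant"
}

.chrom_seq <- function(genome, chrom) {
  if (inherits(genome, "DNAStringSet") || inherits(genome, "XStringSet")) {
    .assert(chrom %in% names(genome), "chromosome %s absent from genome", chrom)
    return(as.character(genome[[chrom]]))
  }
  .assert(chrom %in% names(genome), "chromosome %s absent from genome", chrom)
  genome[[chrom]]
}

## splice classification relative to exon boundaries; intron i lies between
## genomic exons i and i+1. On '+' the donor is the intron's first two
## bases; on '-' transcription runs right to left so donor and acceptor swap.
.splice_site <- function(pos, exons, strand) {
  n <- nrow(exons)
  if (n < 2L) {
    ## still allow exonic splice-region bases to be absent for single exons
    return(NA_character_)
  }
  for (i in seq_len(n - 1L)) {
    int_start <- exons$end[i] + 1L
    int_end <- exons$start[i + 1L] - 1L
    if (int_end < int_start) next
    off_left <- pos - int_start + 1L   # 1-based offset into intron from left
    off_right <- int_end - pos + 1L    # from right
    if (pos >= int_start && pos <= int_end) {
      d2 <- if (strand == "+") off_left else off_right   # distance from donor
      a2 <- if (strand == "+") off_right else off_left   # from acceptor
      if (d2 <= 2L) return("splice_donor_variant")
      if (a2 <= 2L) return("splice_acceptor_variant")
      if (d2 <= 8L || a2 <= 8L) return("splice_region_variant")
      return(NA_character_)
    }
  }
  ## exonic splice region: last/first 3 exonic bases adjacent to an intron
  for (i in seq_len(n)) {
    if (pos >= exons$start[i] && pos <= exons$end[i]) {
      near_next <- i < n && (exons$end[i] - pos) < 3L
      near_prev <- i > 1L && (pos - exons$start[i]) < 3L
      if (near_next || near_prev) return("splice_region_variant")
      return(NA_character_)
    }
  }
  NA_character_
}

## translate the affected codon before and after an SNV substitution
.classify_cds_snv <- function(pos, ref, alt, model, seq) {
  cds <- model$cds
  ## spliced CDS coordinate of pos (1-based, in transcription direction)
  cum <- 0L
  cds_pos <- NA_integer_
  if (model$strand == "+") {
    for (i in seq_len(nrow(cds))) {
      if (pos >= cds$start[i] && pos <= cds$end[i]) {
        cds_pos <- cum + (pos - cds$start[i]) + 1L
        break
      }
      cum <- cum + (cds$end[i] - cds$start[i] + 1L)
    }
  } else {
    for (i in rev(seq_len(nrow(cds)))) {
      if (pos >= cds$start[i] && pos <= cds$end[i]) {
        cds_pos <- cum + (cds$end[i] - pos) + 1L
        break
      }
      cum <- cum + (cds$end[i] - cds$start[i] + 1L)
    }
  }
  .assert(!is.na(cds_pos), "position not in CDS")

  cds_seq <- .spliced_cds_seq(model, seq)
  codon_i <- (cds_pos - 1L) %/% 3L
  within <- (cds_pos - 1L) %% 3L + 1L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  .assert(nchar(codon) == 3L, "CDS length not a multiple of 3 at codon boundary")

  alt_base <- if (model$strand == "+") alt else .revcomp(alt)
  new_codon <- codon
  substr(new_codon, within, within) <- alt_base

  aa_ref <- .translate_codon(codon)
  aa_alt <- .translate_codon(new_codon)
  if (aa_alt == "*" && aa_ref != "*") return("stop_gained")
  if (aa_alt == aa_ref) return("synonymous_variant")
  "missense_variant"
}

## CDS sequence in transcription order
.spliced_cds_seq <- function(model, seq) {
  parts <- vapply(seq_len(nrow(model$cds)), function(i) {
    substr(seq, model$cds$start[i], model$cds$end[i])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- .revcomp(s) else s
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.translate_codon <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify a variant table against a set of transcript models
#'
#' Runs [classify_consequence()] for every variant against every
#' protein-coding-or-not transcript whose footprint (padded by the splice
#' window) it overlaps, keeping consequences on protein-coding transcripts
#' only, as pext is defined over coding annotation classes.
#'
#' @param variants `data.table`/data.frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param models list of `TranscriptModel` objects.
#' @param genome chromosome sequences (see [classify_consequence()]).
#' @param severity severity table, used to order the output.
#' @param coding_only drop consequences on non-protein-coding transcripts
#'   (default `TRUE`).
#' @return consequence table as from [read_vep_csq()] (empty
#'   `loftee_filter`/`loftee_flags`).
#' @export
classify_variants <- function(variants, models, genome,
                              severity = read_severity_order(),
                              coding_only = TRUE) {
  variants <- data.table::as.data.table(variants)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i]
    for (m in models) {
      if (!identical(m$chrom, v$chrom)) next
      if (v$pos < min(m$exons$start) - 8L || v$pos > max(m$exons$end) + 8L) next
      if (coding_only && !identical(m$biotype, "protein_coding")) next
      term <- classify_consequence(v$chrom, v$pos, v$ref, v$alt, m, genome)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        transcript_id = m$transcript_id, gene_id = m$gene_id,
        worst_term = term, loftee_filter = "", loftee_flags = "")
    }
  }
  if (length(rows) == 0L) return(.empty_consequences())
  .order_records(data.table::rbindlist(rows), severity)
}
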