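test_that("worst_consequence follows the severity ordering", {
  expect_equal(worst_consequence(c("missense_variant",
                                   "splice_region_variant")),
               "missense_variant")
  expect_equal(worst_consequence("synonymous_variant"), "synonymous_variant")
  expect_equal(worst_consequence(c("synonymous_variant", "stop_gained")),
               "stop_gained")
  expect_error(worst_consequence(character()), "empty")
  expect_error(worst_consequence("made_up_term"), "absent from severity")
})

test_that("worst_consequence is stable under adding less severe terms", {
  sev <- read_severity_order()
  set.seed(3)
  for (i in 1:20) {
    terms <- sample(sev$term, sample(2:6, 1))
    w <- worst_consequence(terms, sev)
    extra <- sample(sev$term[sev$rank >= consequence_rank(w, sev)], 1)
    expect_equal(worst_consequence(c(terms, extra), sev), w)
  }
})

test_that("GTF writing and reading round-trips transcript models", {
  fx <- cached_fixture(seed = 11, noise_sigma = 0)
  path <- file.path(withr::local_tempdir(), "models.gtf")
  write_gtf(fx$models, path)
  back <- read_gtf(path)
  expect_setequal(names(back), names(fx$models))
  for (tid in names(fx$models)) {
    a <- fx$models[[tid]]; b <- back[[tid]]
    expect_equal(b$gene_id, a$gene_id)
    expect_equal(b$biotype, a$biotype)
    expect_equal(b$strand, a$strand)
    expect_equal(b$exons$start, a$exons$start)
    expect_equal(b$exons$end, a$exons$end)
    expect_equal(b$cds$start, a$cds$start)
    expect_equal(b$cds$end, a$cds$end)
  }
  ## non-coding biotype is retained, flagged non-coding
  nc <- Filter(function(m) m$biotype != "protein_coding", back)
  expect_gt(length(nc), 0)
  expect_true(all(vapply(nc, function(m) nrow(m$cds) == 0L, logical(1))))
})

test_that("read_vep_csq parses CSQ, keeps coding transcripts, splits alleles", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "in.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence ',
           'annotations from VEP. Format: Allele|Consequence|Feature|Gene|',
           'BIOTYPE|LoF|LoF_flags">'),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr1\t100\t.\tC\tT\t.\tPASS\tCSQ=",
           "T|missense_variant&splice_region_variant|ENST1|ENSG1|protein_coding||,",
           "T|non_coding_transcript_exon_variant|ENST2|ENSG1|lincRNA||"),
    paste0("chr1\t200\t.\tG\tA,C\t.\tPASS\tCSQ=",
           "A|stop_gained|ENST1|ENSG1|protein_coding|HC|SINGLE_EXON,",
           "C|synonymous_variant|ENST1|ENSG1|protein_coding||")
  ), vcf)
  cons <- read_vep_csq(vcf)
  ## lincRNA row dropped; worst term picked from ampersand list
  expect_equal(nrow(cons), 3L)
  r1 <- cons[pos == 100]
  expect_equal(r1$worst_term, "missense_variant")
  expect_equal(r1$transcript_id, "ENST1")
  ## multi-allelic record split per alt with LOFTEE pass-through
  r2 <- cons[pos == 200]
  expect_equal(r2[alt == "A"]$worst_term, "stop_gained")
  expect_equal(r2[alt == "A"]$loftee_filter, "HC")
  expect_equal(r2[alt == "A"]$loftee_flags, "SINGLE_EXON")
  expect_equal(r2[alt == "C"]$worst_term, "synonymous_variant")
  expect_equal(r2[alt == "C"]$loftee_filter, "")

  ## header without CSQ definition fails
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t1\t.\tA\tT\t.\t.\t."), vcf)
  expect_error(read_vep_csq(vcf), "does not define")
})

test_that("classifier handles the canonical fixed-codon examples", {
  ## single-exon gene, CDS ATG CAA TAA-free coding part: ATG CAA GGG + TAA
  seq <- paste0(strrep("T", 10), "ATGCAAGGGTAA", strrep("T", 10))
  genome <- c(c1 = seq)
  m <- transcript_model("TX", "G", "protein_coding", "+", "c1",
                        exons = data.frame(start = 11L, end = 22L),
                        cds = data.frame(start = 11L, end = 19L))
  ## CDS position 4: CAA -> TAA
  expect_equal(classify_consequence("c1", 14L, "C", "T", m, genome),
               "stop_gained")
  ## CDS position 6: CAA -> CAG (Gln -> Gln)
  expect_equal(classify_consequence("c1", 16L, "A", "G", m, genome),
               "synonymous_variant")
  ## CDS position 5: CAA -> CGA (Gln -> Arg)
  expect_equal(classify_consequence("c1", 15L, "A", "G", m, genome),
               "missense_variant")
  ## frameshift vs inframe indels
  expect_equal(classify_consequence("c1", 12L, "TG", "T", m, genome),
               "frameshift_variant")
  expect_equal(classify_consequence("c1", 12L, "TGCA", "T", m, genome),
               "inframe_deletion")
  ## ref mismatch and footprint violations are errors
  expect_error(classify_consequence("c1", 14L, "G", "T", m, genome),
               "does not match")
  expect_error(classify_consequence("c1", 500L, "T", "A", m, genome),
               "outside footprint")
})

test_that("classifier calls splice sites at the 2-bp / 3-8-bp windows", {
  seq <- paste0(strrep("A", 10), "ATGGCA", "GT", strrep("C", 26), "AG",
                "GCATAA", strrep("A", 10))
  genome <- c(c1 = seq)
  m <- transcript_model("TX", "G", "protein_coding", "+", "c1",
                        exons = data.frame(start = c(11L, 47L),
                                           end = c(16L, 52L)),
                        cds = data.frame(start = c(11L, 47L),
                                         end = c(16L, 49L)))
  expect_equal(classify_consequence("c1", 17L, "G", "A", m, genome),
               "splice_donor_variant")   # first intronic base
  expect_equal(classify_consequence("c1", 18L, "T", "A", m, genome),
               "splice_donor_variant")
  expect_equal(classify_consequence("c1", 45L, "A", "T", m, genome),
               "splice_acceptor_variant")
  expect_equal(classify_consequence("c1", 21L, "C", "G", m, genome),
               "splice_region_variant")  # intronic base 5 from donor
  expect_equal(classify_consequence("c1", 30L, "C", "G", m, genome),
               "intron_variant")
})

test_that("classifier SNV calls agree with a full-translation oracle", {
  ## enumerate all 9 x 3 substitutions of a 3-codon CDS; oracle translates
  ## the full mutated CDS with Biostrings
  seq <- paste0(strrep("G", 10), "ATGCATAGA", strrep("G", 10))
  genome <- c(c1 = seq)
  m <- transcript_model("TX", "G", "protein_coding", "+", "c1",
                        exons = data.frame(start = 11L, end = 19L),
                        cds = data.frame(start = 11L, end = 19L))
  for (off in 0:8) {
    pos <- 11L + off
    ref <- substr(seq, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- classify_consequence("c1", pos, ref, alt, m, genome)
      mut <- seq
      substr(mut, pos, pos) <- alt
      aa_ref <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(seq, 11, 19)), no.init.codon = TRUE))
      aa_alt <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(mut, 11, 19)), no.init.codon = TRUE))
      want <- if (grepl("\\*", aa_alt) && !grepl("\\*", aa_ref)) "stop_gained"
              else if (aa_alt == aa_ref) "synonymous_variant"
              else "missense_variant"
      expect_equal(got, want,
                   info = sprintf("pos %d %s>%s", pos, ref, alt))
    }
  }
})

test_that("classification is invariant under reverse complement", {
  ## mirror a plus-strand gene onto the minus strand and check every
  ## engineered variant classifies identically
  fx <- cached_fixture(seed = 11, noise_sigma = 0)
  plus_genes <- Filter(function(l) l$strand == "+", fx$layout)
  lay <- plus_genes[[1]]
  L_chrom <- nchar(fx$genome[[1]])
  flipped_genome <- c(chrS = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fx$genome[[1]]))))
  flip_iv <- function(df) {
    out <- data.frame(start = L_chrom - df$end + 1L,
                      end = L_chrom - df$start + 1L)
    out[order(out$start), ]
  }
  for (m in Filter(function(m) m$gene_id == lay$gene_id, fx$models)) {
    fm <- transcript_model(m$transcript_id, m$gene_id, m$biotype,
                           ifelse(m$strand == "+", "-", "+"), m$chrom,
                           flip_iv(m$exons),
                           if (nrow(m$cds)) flip_iv(m$cds) else m$cds)
    vs <- fx$variants[gene_id == lay$gene_id & nchar(ref) == 1 &
                        nchar(alt) == 1]
    for (i in seq_len(nrow(vs))) {
      v <- vs[i]
      orig <- classify_consequence(v$chrom, v$pos, v$ref, v$alt, m,
                                   fx$genome)
      rc <- function(b) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(b)))
      flipped <- classify_consequence(v$chrom, L_chrom - v$pos + 1L,
                                      rc(v$ref), rc(v$alt), fm,
                                      flipped_genome)
      expect_equal(flipped, orig, info = v$variant_id)
    }
  }
})
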