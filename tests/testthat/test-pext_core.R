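test_that("ext sums median TPM over transcripts sharing an annotation class", {
  mat <- toy_matrix()
  cons <- toy_consequences()
  ext <- ext_values(cons, mat)
  expect_equal(nrow(ext), 2L)  # one row per (variant, class)
  expect_equal(ext[worst_term == "stop_gained"]$A, 8)
  expect_equal(ext[worst_term == "synonymous_variant"]$A, 2)

  ## LOFTEE filter/flag combinations split classes
  cons2 <- data.table(
    chrom = "chr1", pos = 50L, ref = "G", alt = "A",
    transcript_id = c("T1", "T2", "T3"),
    gene_id = c("G1", "G1", "G2"),
    worst_term = "stop_gained",
    loftee_filter = c("HC", "LC", "HC"), loftee_flags = "")
  ext2 <- ext_values(cons2, mat)
  expect_equal(nrow(ext2), 3L)
  expect_equal(ext2[gene_id == "G1" & loftee_filter == "HC"]$A, 8)
  expect_equal(ext2[gene_id == "G1" & loftee_filter == "LC"]$A, 2)

  ## unknown transcripts: strict error or zero with warning
  cons3 <- copy(cons)[1, transcript_id := "T_UNKNOWN"]
  expect_error(ext_values(cons3, mat), "T_UNKNOWN")
  expect_warning(ext3 <- ext_values(cons3, mat, missing_transcript = "zero"),
                 "unexpressed")
  expect_equal(ext3[worst_term == "stop_gained"]$A, 0)
})

test_that("pext divides by gene total, NA exactly where the total is zero", {
  mat <- toy_matrix()
  px <- pext_values(ext_values(toy_consequences(), mat), mat)
  expect_equal(px[worst_term == "stop_gained"]$A, 0.8)
  expect_equal(px[worst_term == "synonymous_variant"]$A, 0.2)
  expect_equal(sum(px$A), 1.0)              # classes partition the gene
  expect_true(all(is.na(px$B)))             # zero-total tissue
  expect_equal(px$mean_pext, px$A)          # NA tissue excluded from mean

  ## scale invariance: doubling all TPMs in a tissue leaves pext unchanged
  mat2 <- toy_matrix()
  mat2$medians[, A := A * 2]
  mat2$gene_total[, A := A * 2]
  px2 <- pext_values(ext_values(toy_consequences(), mat2), mat2)
  expect_equal(px2$A, px$A)
})

test_that("mean_pext removes NA tissues, supports max mode, rejects empty subsets", {
  expect_equal(mean_pext(c(A = 0.8, B = NA, C = 0.4)), 0.6)
  expect_true(is.na(mean_pext(c(A = NA_real_, B = NA_real_))))
  expect_equal(mean_pext(c(A = 0.8, B = NA, C = 0.4), mode = "max"), 0.8)
  expect_error(mean_pext(numeric(0)), "empty tissue subset")
  ## single-tissue mean equals that tissue's pext
  expect_equal(mean_pext(c(A = 0.35, B = 0.9), tissues = "A"), 0.35)
})

test_that("pipeline pext equals per-transcript enumeration oracle on random fixtures", {
  for (seed in 1:30) {
    f <- random_pext_fixture(seed)
    ext <- ext_values(f$consequences, f$matrix)
    oracle <- ext_oracle(f$consequences, f$matrix)
    setorderv(ext, c("worst_term", "loftee_filter"))
    setorderv(oracle, c("worst_term", "loftee_filter"))
    for (tt in f$matrix$tissues) {
      expect_equal(ext[[tt]], oracle[[tt]], tolerance = 1e-12)
    }
    px <- pext_values(ext, f$matrix)
    for (tt in f$matrix$tissues) {
      total <- f$matrix$gene_total[[tt]]
      if (total == 0) {
        expect_true(all(is.na(px[[tt]])))
      } else {
        expect_true(all(px[[tt]] >= 0 & px[[tt]] <= 1))
        expect_lte(sum(px[[tt]]), 1 + 1e-9)
        if (f$all_coding) expect_equal(sum(px[[tt]]), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("ext is monotone in transcripts added to a class", {
  mat <- toy_matrix()
  cons <- toy_consequences()[worst_term == "stop_gained"]
  base <- ext_values(cons, mat)
  grown <- ext_values(rbind(cons, data.table(
    chrom = "chr1", pos = 100L, ref = "C", alt = "T", transcript_id = "T2",
    gene_id = "G1", worst_term = "stop_gained", loftee_filter = "HC",
    loftee_flags = "")), mat)
  for (tt in mat$tissues) expect_gte(grown[[tt]], base[[tt]])
})

test_that("base-level pext matches interval membership and bounds variant pext", {
  fx <- cached_fixture(seed = 11, noise_sigma = 0)
  mat <- median_by_tissue(fx$quant, fx$samples)
  for (g in unique(vapply(fx$models, `[[`, character(1), "gene_id"))) {
    gm <- Filter(function(m) identical(m$gene_id, g), fx$models)
    track <- base_level_pext(gm, mat)
    ## interval-stabbing oracle over every base of the track
    totals <- mat$gene_total[gene_id == g]
    for (tt in mat$tissues) {
      denom <- totals[[tt]]
      want <- vapply(track$pos, function(p) {
        if (denom <= 0) return(NA_real_)
        s <- 0
        for (m in gm) {
          if (any(p >= m$exons$start & p <= m$exons$end)) {
            s <- s + mat$medians[transcript_id == m$transcript_id][[tt]]
          }
        }
        s / denom
      }, numeric(1))
      expect_equal(track[[tt]], want, tolerance = 1e-12)
    }
  }
})

test_that("base shared by all transcripts scores 1, unique exon scores its share", {
  medians <- data.table(transcript_id = c("T1", "T2"), gene_id = "G",
                        A = c(8, 2))
  totals <- data.table(gene_id = "G", A = 10)
  mat <- pextr:::new_tissue_matrix(medians, totals, "A", c(A = 3L))
  models <- list(
    transcript_model("T1", "G", "protein_coding", "+", "c1",
                     data.frame(start = c(1L, 50L), end = c(10L, 60L)),
                     data.frame(start = c(1L, 50L), end = c(10L, 60L))),
    transcript_model("T2", "G", "protein_coding", "+", "c1",
                     data.frame(start = c(1L, 20L), end = c(10L, 30L)),
                     data.frame(start = c(1L, 20L), end = c(10L, 30L))))
  track <- base_level_pext(models, mat)
  expect_equal(track[pos == 5]$A, 1.0)    # shared exon
  expect_equal(track[pos == 25]$A, 0.2)   # unique to T2 (TPM 2 / 10)
  expect_equal(track[pos == 55]$A, 0.8)   # unique to T1

  ## region mean helper
  expect_equal(unname(region_mean_pext(track, 20, 30)["A"]), 0.2)

  ## bedGraph round-trip of coordinates (0-based half-open, merged runs)
  path <- file.path(withr::local_tempdir(), "track.bedGraph")
  write_bedgraph(track, "A", path)
  bg <- fread(path, col.names = c("chrom", "start0", "end0", "value"))
  expect_equal(sum(bg$end0 - bg$start0), nrow(track))
  expect_equal(bg[start0 <= 24 & end0 >= 25]$value, 0.2)
})

test_that("gene max-pext filter excludes low-max genes with strict inequality", {
  ## coding transcript carries 20% of output in its best tissue: max = 0.2,
  ## retained (strict inequality)
  medians <- data.table(transcript_id = c("C1", "N1"), gene_id = "G",
                        A = c(2, 8), B = c(1, 9))
  totals <- data.table(gene_id = "G", A = 10, B = 10)
  mat <- pextr:::new_tissue_matrix(medians, totals, c("A", "B"),
                                   c(A = 3L, B = 3L))
  iv <- data.frame(start = 1L, end = 30L)
  models <- list(
    transcript_model("C1", "G", "protein_coding", "+", "c1", iv, iv),
    transcript_model("N1", "G", "processed_transcript", "+", "c1", iv))
  qc <- gene_max_pext_filter(models, mat)
  expect_equal(qc$max_pext, 0.2)
  expect_false(qc$excluded)

  ## drop the coding share below the threshold: excluded
  mat$medians[transcript_id == "C1", `:=`(A = 1.5, B = 1)]
  qc2 <- gene_max_pext_filter(models, mat)
  expect_true(qc2$excluded)
  expect_equal(qc2$reason, "max_pext_below_threshold")

  ## no coding transcript: excluded by construction
  qc3 <- gene_max_pext_filter(models[2], mat)
  expect_true(qc3$excluded)
  expect_equal(qc3$reason, "no_coding_transcript")

  ## single coding transcript, nothing else: max 1, retained
  mat1 <- pextr:::new_tissue_matrix(
    data.table(transcript_id = "C1", gene_id = "G", A = 4),
    data.table(gene_id = "G", A = 4), "A", c(A = 3L))
  qc4 <- gene_max_pext_filter(models[1], mat1)
  expect_equal(qc4$max_pext, 1)
  expect_false(qc4$excluded)
})

test_that("engineered fixture gene with dominant non-coding isoform is filtered", {
  fx <- cached_fixture(seed = 11, noise_sigma = 0)
  mat <- median_by_tissue(fx$quant, fx$samples)
  qc <- gene_max_pext_filter(fx$models, mat)
  fail_genes <- names(Filter(function(l) l$qc_fail, fx$layout))
  all_coding_genes <- names(Filter(function(l) length(l$noncoding) == 0,
                                   fx$layout))
  expect_true(all(qc[gene_id %in% fail_genes]$excluded))
  expect_false(any(qc[gene_id %in% all_coding_genes]$excluded))
})
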