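library(data.table)

## ---- hand-built toy expression matrix ------------------------------------
## gene G1: transcripts T1 (TPM 8) and T2 (TPM 2) in tissue A; tissue B has
## gene total 0 (NA pext). gene G2: single transcript T3.
toy_matrix <- function() {
  medians <- data.table(
    transcript_id = c("T1", "T2", "T3"),
    gene_id = c("G1", "G1", "G2"),
    A = c(8, 2, 5), B = c(0, 0, 4))
  gene_total <- data.table(gene_id = c("G1", "G2"), A = c(10, 5), B = c(0, 4))
  pextr:::new_tissue_matrix(medians, gene_total, c("A", "B"),
                            c(A = 3L, B = 3L))
}

toy_consequences <- function() {
  data.table(
    chrom = "chr1", pos = c(100L, 100L), ref = "C", alt = "T",
    transcript_id = c("T1", "T2"), gene_id = "G1",
    worst_term = c("stop_gained", "synonymous_variant"),
    loftee_filter = c("HC", ""), loftee_flags = c("", ""))
}

## ---- cached generated fixture --------------------------------------------
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 11L, noise_sigma = 0, n_genes = 3L,
                           n_samples = 30L) {
  key <- paste(seed, noise_sigma, n_genes, n_samples, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- fixture_spec(seed = seed, n_genes = n_genes,
                       noise_sigma = noise_sigma,
                       n_samples_per_tissue = n_samples)
  fx <- generate_gene_models(spec)
  expr <- generate_expression(fx, spec)
  vars <- generate_variants(fx, expr$truth)
  out <- list(spec = spec, models = fx$models, genome = fx$genome,
              layout = fx$layout, quant = expr$quant,
              samples = expr$samples, truth = expr$truth, variants = vars)
  .fixture_cache[[key]] <- out
  out
}

## ---- independent oracles --------------------------------------------------

## sort-based median oracle (midpoint of central pair for even n)
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

## brute-force ext oracle: per-transcript enumeration and summation
ext_oracle <- function(consequences, matrix) {
  tissues <- matrix$tissues
  keys <- unique(consequences[, .(chrom, pos, ref, alt, gene_id,
                                  worst_term, loftee_filter, loftee_flags)])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i]
    tx <- consequences[chrom == k$chrom & pos == k$pos & ref == k$ref &
                       alt == k$alt & worst_term == k$worst_term &
                       loftee_filter == k$loftee_filter &
                       loftee_flags == k$loftee_flags]$transcript_id
    vals <- vapply(tissues, function(tt) {
      s <- 0
      for (t1 in tx) {
        row <- matrix$medians[transcript_id == t1]
        if (nrow(row) == 1L) s <- s + row[[tt]]
      }
      s
    }, numeric(1))
    cbind(k, data.table(t(vals)))
  })
  rbindlist(out)
}

## two-sided Fisher p by full hypergeometric enumeration at fixed margins
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## doubled-tail conditional binomial p by explicit enumeration
poisson_p_oracle <- function(x1, n1, x2, n2) {
  N <- x1 + x2
  p0 <- n1 / (n1 + n2)
  probs <- stats::dbinom(0:N, N, p0)
  lower <- sum(probs[seq_len(x1 + 1L)])
  upper <- sum(probs[(x1 + 1L):(N + 1L)])
  min(1, 2 * min(lower, upper))
}

## random consequence-table fixture with random expression, for pext
## correctness property tests (no classifier involvement)
random_pext_fixture <- function(seed) {
  set.seed(seed)
  n_tx <- sample(2:6, 1)
  n_tis <- sample(2:4, 1)
  tissues <- paste0("tis", seq_len(n_tis))
  tx <- paste0("TX", seq_len(n_tx))
  all_coding <- sample(c(TRUE, FALSE), 1)
  medians <- data.table(transcript_id = tx, gene_id = "G")
  for (tt in tissues) {
    v <- round(stats::runif(n_tx, 0, 20), 3)
    if (stats::runif(1) < 0.3) v <- rep(0, n_tx)  # zero-total tissue
    medians[, (tt) := v]
  }
  gene_total <- medians[, lapply(.SD, sum), by = gene_id, .SDcols = tissues]
  mat <- pextr:::new_tissue_matrix(medians, gene_total, tissues,
                                   setNames(rep(5L, n_tis), tissues))
  ## every transcript gets a class iff all_coding; else a random subset does
  classes <- c("stop_gained", "missense_variant", "synonymous_variant")
  filt <- c("HC", "LC", "")
  keep <- if (all_coding) rep(TRUE, n_tx) else stats::runif(n_tx) < 0.7
  if (!any(keep)) keep[1] <- TRUE
  cons <- data.table(
    chrom = "c1", pos = 10L, ref = "A", alt = "G",
    transcript_id = tx[keep], gene_id = "G",
    worst_term = sample(classes, sum(keep), replace = TRUE),
    loftee_filter = sample(filt, sum(keep), replace = TRUE),
    loftee_flags = "")
  list(matrix = mat, consequences = cons, all_coding = all_coding)
}
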