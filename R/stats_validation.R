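#' Exact Poisson rate ratio test
#'
#' Compares event rates between two cohorts (e.g. de novo variant counts
#' per proband in cases versus controls). Inference conditions on the
#' total count: given `x1 + x2`, `x1` is binomial with success probability
#' `n1*RR / (n1*RR + n2)`, so the exact two-sided p-value doubles the
#' smaller binomial tail (capped at 1) and the confidence interval inverts
#' the Clopper-Pearson interval for that binomial proportion.
#'
#' @param x1,x2 event counts in the two groups (`x1 + x2 > 0`).
#' @param n1,n2 cohort sizes (or exposure times) of the two groups.
#' @param conf_level confidence level (default 0.95).
#' @return a list with `rate_ratio` (`(x1/n1)/(x2/n2)`; `Inf` when
#'   `x2 = 0`), `conf_int` (length-2 numeric; upper bound `Inf` when the
#'   conditional proportion reaches 1), `p_value`, and the inputs.
#' @export
#' @examples
#' rate_ratio_poisson(50, 5305, 19, 2179)
rate_ratio_poisson <- function(x1, n1, x2, n2, conf_level = 0.95) {
  .assert(x1 >= 0 && x2 >= 0 && n1 > 0 && n2 > 0,
          "counts must be non-negative and cohort sizes positive")
  .assert(x1 + x2 > 0, "at least one event is required (x1 + x2 > 0)")
  total <- x1 + x2
  p0 <- n1 / (n1 + n2)

  rr <- if (x2 == 0) Inf else (x1 / n1) / (x2 / n2)

  lower_tail <- stats::pbinom(x1, total, p0)
  upper_tail <- stats::pbinom(x1 - 1, total, p0, lower.tail = FALSE)
  p <- min(1, 2 * min(lower_tail, upper_tail))

  alpha <- 1 - conf_level
  pi_lo <- if (x1 == 0) 0 else stats::qbeta(alpha / 2, x1, total - x1 + 1)
  pi_hi <- if (x1 == total) 1 else stats::qbeta(1 - alpha / 2, x1 + 1, total - x1)
  to_rr <- function(pi) {
    if (pi >= 1) return(Inf)
    (pi / (1 - pi)) * (n2 / n1)
  }
  ci <- c(to_rr(pi_lo), to_rr(pi_hi))

  list(rate_ratio = rr, conf_int = ci, p_value = p,
       x1 = x1, n1 = n1, x2 = x2, n2 = n2, conf_level = conf_level)
}

#' Fisher exact test for a case-control 2x2 table
#'
#' Returns the sample (cross-product) odds ratio with the exact two-sided
#' p-value for carrier counts in cases and controls.
#'
#' @param carriers_case,noncarriers_case,carriers_ctrl,noncarriers_ctrl
#'   non-negative cell counts.
#' @return a list with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
case_control_fisher <- function(carriers_case, noncarriers_case,
                                carriers_ctrl, noncarriers_ctrl) {
  tab <- matrix(c(carriers_case, noncarriers_case,
                  carriers_ctrl, noncarriers_ctrl), nrow = 2,
                dimnames = list(c("carrier", "noncarrier"),
                                c("case", "control")))
  .assert(all(tab >= 0), "counts must be non-negative")
  or <- .sample_or(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Read a trinucleotide mutability table
#'
#' @param path headered TSV with columns `context`, `alt`, optionally
#'   `methylation`, and `mu` (mutation rate).
#' @return a `data.table` keyed by context/alt (and methylation stratum
#'   when present).
#' @export
read_mutability <- function(path) {
  x <- data.table::fread(path, header = TRUE)
  .assert(all(c("context", "alt", "mu") %in% names(x)),
          "mutability table needs context, alt and mu columns")
  .assert(all(x$mu > 0), "mutation rates must be positive")
  x[]
}

#' Mutability-adjusted proportion singleton (MAPS)
#'
#' The proportion of variants in a class observed exactly once (allele
#' count 1) reflects both negative selection and the mutation rate of the
#' underlying sites. MAPS removes the mutational component: a calibration
#' class assumed neutral (synonymous variants by default) is aggregated
#' per mutational context and a count-weighted linear regression of the
#' proportion singleton on the mutation rate supplies the expected
#' proportion for any mix of contexts. Each class's MAPS is its observed
#' proportion singleton minus this expectation; the calibration class
#' itself scores 0 by construction. The confidence interval uses the
#' binomial standard error of the observed proportion. MAPS is a relative
#' metric — comparable within one dataset, not across datasets.
#'
#' @param sites `data.table`/data.frame with columns `class` (annotation
#'   class label), `allele_count` (positive integer), `context` (3-mer),
#'   `alt`, optionally `methylation`, and any extra stratification columns
#'   named in `by`.
#' @param mutability table from [read_mutability()] mapping
#'   context/alt(/methylation) to a rate `mu`.
#' @param calibration_class class used to fit the expectation (default
#'   `"synonymous_variant"`).
#' @param by optional extra grouping columns (e.g. expression bin, LOEUF
#'   decile) computed per class.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return a `data.table` with one row per class (x `by` strata):
#'   `n_sites`, `n_singletons`, `observed_ps`, `expected_ps`, `maps`,
#'   `ci_lo`, `ci_hi`.
#' @export
maps <- function(sites, mutability, calibration_class = "synonymous_variant",
                 by = NULL, conf_level = 0.95) {
  sites <- data.table::as.data.table(sites)
  .assert(all(c("class", "allele_count", "context", "alt") %in% names(sites)),
          "sites need class, allele_count, context and alt columns")
  .assert(all(sites$allele_count >= 1), "allele counts must be >= 1")
  .assert(all(nchar(sites$context) == 3L), "contexts must be 3-mers")
  .assert(calibration_class %in% sites$class,
          "calibration class %s has no sites", calibration_class)

  mut <- data.table::as.data.table(mutability)
  key <- c("context", "alt", intersect("methylation", intersect(names(sites), names(mut))))
  s <- mut[sites, on = key]
  .assert(!anyNA(s$mu), "site context(s) missing from mutability table: %s",
          paste(utils::head(unique(s[is.na(mu), context]), 5), collapse = ", "))
  s[, singleton := allele_count == 1L]

  ## calibration: aggregate per mutational context, weight by site count
  cal <- s[class == calibration_class,
           .(n = .N, ps = mean(singleton)), by = .(mu)]
  if (nrow(cal) < 2L) {
    warning("degenerate calibration (constant mutability); ",
            "using constant expected proportion singleton")
    fit <- NULL
    const_exp <- sum(cal$n * cal$ps) / sum(cal$n)
  } else {
    fit <- stats::lm(ps ~ mu, data = cal, weights = cal$n)
    const_exp <- NA_real_
  }
  ## no clamping: the weighted-least-squares residual identity guarantees
  ## MAPS(calibration) = 0 exactly, which clamping would break
  predict_ps <- function(mu_vec) {
    if (is.null(fit)) return(rep(const_exp, length(mu_vec)))
    as.numeric(stats::predict(fit, newdata = data.frame(mu = mu_vec)))
  }

  group_cols <- c("class", by)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- s[, {
    n <- .N
    obs <- mean(singleton)
    exp_ps <- mean(predict_ps(mu))
    se <- sqrt(obs * (1 - obs) / n)
    m <- obs - exp_ps
    .(n_sites = n, n_singletons = sum(singleton),
      observed_ps = obs, expected_ps = exp_ps, maps = m,
      ci_lo = m - z * se, ci_hi = m + z * se)
  }, by = group_cols]
  data.table::setorderv(out, group_cols)
  out[]
}

#' Conservation versus expression comparison
#'
#' Classifies genomic regions as highly conserved (phyloCSF score above
#' `high_cut`), unconserved (below `low_cut`) or neither, cross-tabulates
#' conservation status against expression bin, and fits a logistic
#' regression of conservation on mean pext with region length as a
#' covariate (length influences both phyloCSF scores and isoform
#' quantification, so the expression effect must survive adjusting for
#' it).
#'
#' @param regions `data.table`/data.frame with columns `score` (phyloCSF),
#'   `length`, `mean_pext`.
#' @param high_cut,low_cut conservation thresholds (defaults 1000, -100).
#' @return a list with `regions` (input plus `status` column), `counts`
#'   (status x expression-bin table), `model` (coefficient table with
#'   `estimate`, `se`, `z`, `p` rows for intercept, mean pext and length)
#'   and logical `separation` (perfect separation detected; coefficients
#'   then untrustworthy and flagged).
#' @export
conservation_expression_comparison <- function(regions, high_cut = 1000,
                                               low_cut = -100) {
  regions <- data.table::copy(data.table::as.data.table(regions))
  .assert(all(c("score", "length", "mean_pext") %in% names(regions)),
          "regions need score, length and mean_pext columns")
  regions[, status := data.table::fcase(
    score > high_cut, "conserved",
    score < low_cut, "unconserved",
    default = "neither")]

  classified <- regions[status != "neither"]
  .assert(nrow(classified) > 0L, "no regions pass the conservation thresholds")
  counts <- table(status = classified$status,
                  bin = assign_bin(classified$mean_pext))

  classified[, conserved := as.integer(status == "conserved")]
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(conserved ~ mean_pext + length, data = classified,
               family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  ## complete separation does not always trigger the glm warning; also
  ## detect it from degenerate fitted probabilities
  fitted_p <- stats::fitted(fit)
  y <- classified$conserved
  if (!separation &&
      all(fitted_p[y == 1] > 1 - 1e-6) && all(fitted_p[y == 0] < 1e-6)) {
    separation <- TRUE
  }
  sm <- summary(fit)$coefficients
  model <- data.table::data.table(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    z = sm[, 3], p = sm[, 4])

  list(regions = regions[], counts = counts, model = model,
       separation = separation)
}
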