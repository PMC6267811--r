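# The statistical battery: weighted expectations, minimum-likelihood
# two-tailed binomial tests per chromosome, the overall Pearson chi-square,
# the two-sample Kolmogorov-Smirnov test on category frequency vectors
# (with the classical corrected asymptotic p-value), coverage of a
# classification scheme, and the common-variant contamination screen.

#' Weighted expected counts
#'
#' Distributes `total_observed` over categories in proportion to
#' non-negative weights: `E_c = total_observed * w_c / sum(w)`. The
#' expectations sum exactly to `total_observed`.
#'
#' @param weights Named non-negative weights (e.g. genes per chromosome or
#'   summed CDS length per chromosome).
#' @param total_observed Total observed count to distribute.
#' @return Named numeric expectations.
#' @export
expected_counts <- function(weights, total_observed) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) <= 0) stop("weights must not all be zero", call. = FALSE)
  total_observed * weights / sum(weights)
}

#' Minimum-likelihood two-tailed binomial p-value
#'
#' The two-tailed p at observation `k` of `n` under success probability
#' `p0`: the total Binomial(n, p0) probability of all outcomes whose
#' probability mass does not exceed the mass at `k` (with a 1 + 1e-7
#' relative slack on the comparison). This is the classical definition
#' shared by [stats::binom.test()], to which the computation is delegated.
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability in (0, 1).
#' @return p-value in (0, 1].
#' @export
binomial_two_tailed <- function(k, n, p0) {
  if (!is.numeric(k) || !is.numeric(n) || k < 0 || n < 1 || k > n ||
      k != round(k) || n != round(n)) {
    stop("invalid k/n: need integers with 0 <= k <= n", call. = FALSE)
  }
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1) {
    stop("invalid p0: need 0 < p0 < 1", call. = FALSE)
  }
  stats::binom.test(k, n, p0)$p.value
}

#' Per-chromosome bias profile
#'
#' For each chromosome, a two-tailed binomial test of the observed variant
#' count against the expectation under each weighting basis (gene counts
#' and summed CDS lengths), with `n` the total number of
#' chromosome-assigned variants. A chromosome is unbiased under a basis
#' when its p-value exceeds `alpha`. The headline unbiased-chromosome count
#' uses the gene basis.
#'
#' @param observed A `category_counts` on the chromosome scheme.
#' @param background List with `genes` and `cds` `category_counts` (from
#'   [build_background()] or assembled directly).
#' @param alpha Significance level (default 0.05).
#' @return List of class `chromosome_profile`: `results` data.frame (one
#'   row per chromosome with observed, both expectations, both p-values and
#'   bias flags), `n_unbiased_genes`, `n_unbiased_cds`, `alpha`.
#' @export
chromosome_bias_profile <- function(observed, background, alpha = 0.05) {
  stopifnot(inherits(observed, "category_counts"),
            observed$scheme == "chromosome")
  wg <- background$genes$counts
  wc <- background$cds$counts
  labels <- names(wg)
  extra <- setdiff(names(observed$counts), labels)
  if (length(extra)) {
    stop("observed chromosome(s) absent from background: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  obs <- stats::setNames(rep(0, length(labels)), labels)
  obs[names(observed$counts)] <- observed$counts
  n <- observed$total_assigned
  eg <- expected_counts(wg, n)
  ec <- expected_counts(wc[labels], n)
  if (n == 0) {
    # vacuous dataset: the single outcome (all zeros) has probability one
    p_gene <- p_cds <- stats::setNames(rep(1, length(labels)), labels)
  } else {
    p_gene <- vapply(labels, function(ch)
      binomial_two_tailed(obs[[ch]], n, wg[[ch]] / sum(wg)), 0)
    p_cds <- vapply(labels, function(ch)
      binomial_two_tailed(obs[[ch]], n, wc[[ch]] / sum(wc)), 0)
  }
  results <- data.frame(
    chromosome = labels,
    observed = as.numeric(obs),
    expected_genes = as.numeric(eg),
    expected_cds = as.numeric(ec),
    p_genes = as.numeric(p_gene),
    p_cds = as.numeric(p_cds),
    biased_genes = p_gene <= alpha,
    biased_cds = p_cds <= alpha,
    stringsAsFactors = FALSE
  )
  rownames(results) <- NULL
  structure(list(results = results,
                 n_unbiased_genes = sum(!results$biased_genes),
                 n_unbiased_cds = sum(!results$biased_cds),
                 alpha = alpha),
            class = "chromosome_profile")
}

#' Pearson chi-square goodness of fit
#'
#' `X2 = sum (O - E)^2 / E` with a p-value from the chi-square distribution
#' on `k - 1` degrees of freedom (expectations derive from fixed
#' proportions, no estimated parameters).
#'
#' @param observed Named observed counts.
#' @param expected Named expectations on the same categories, all > 0.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
pearson_chi_square <- function(observed, expected) {
  if (!is.null(names(observed)) && !is.null(names(expected))) {
    if (!setequal(names(observed), names(expected))) {
      stop("observed and expected categories differ", call. = FALSE)
    }
    expected <- expected[names(observed)]
  } else if (length(observed) != length(expected)) {
    stop("observed and expected categories differ", call. = FALSE)
  }
  if (any(expected <= 0)) {
    stop("all expected counts must be > 0", call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum gap between the two empirical distribution
#' functions over the pooled values. The default p-value is the asymptotic
#' Kolmogorov approximation evaluated at `(e + 0.12 + 0.11/e) * D` with
#' `e = sqrt(n*m/(n+m))` - the classical small-sample-corrected form,
#' applied at every sample size so that reported p-values follow the
#' convention of the era's standard implementations. `p_method = "exact"`
#' switches to the exact conditional distribution (via
#' [stats::ks.test()]), the statistically honest choice at tiny n.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @param p_method "asymptotic" (default) or "exact".
#' @return List with `statistic` (D), `p_value`, `n`, `m`.
#' @export
ks_two_sample <- function(sample_a, sample_b,
                          p_method = c("asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  if (!length(sample_a) || !length(sample_b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n <- length(sample_a); m <- length(sample_b)
  pooled <- sort(unique(c(sample_a, sample_b)))
  d_gaps <- abs(vapply(pooled, function(x) mean(sample_a <= x), 0) -
                  vapply(pooled, function(x) mean(sample_b <= x), 0))
  D <- max(d_gaps)
  p <- if (p_method == "asymptotic") {
    e <- sqrt(n * m / (n + m))
    kolmogorov_sf((e + 0.12 + 0.11 / e) * D)
  } else {
    suppressWarnings(
      stats::ks.test(sample_a, sample_b, exact = TRUE)$p.value)
  }
  list(statistic = D, p_value = p, n = n, m = m)
}

#' KS test between a dataset and background category distribution
#'
#' The two KS samples are per-category relative frequencies: the dataset's
#' category counts normalized by its total assignments (one value per
#' category present in the dataset) versus the background's normalized
#' counts (one value per background category).
#'
#' @param dataset A `category_counts` for the dataset.
#' @param background A `category_counts` for the proteome background at
#'   the same scheme/level.
#' @param alpha Significance level for the bias call (default 0.01).
#' @param p_method Passed to [ks_two_sample()].
#' @return A `distribution_test_result` list: scheme, level, statistic,
#'   p_value, biased, n_dataset, n_background.
#' @export
ks_frequency_test <- function(dataset, background, alpha = 0.01,
                              p_method = c("asymptotic", "exact")) {
  stopifnot(inherits(dataset, "category_counts"),
            inherits(background, "category_counts"))
  if (dataset$total_assigned == 0) {
    stop("dataset has no assignments at ", dataset$scheme, "/", dataset$level,
         call. = FALSE)
  }
  if (background$total_assigned == 0) {
    stop("background has no assignments at ", background$scheme, "/",
         background$level, call. = FALSE)
  }
  freq_a <- as.numeric(dataset$counts) / dataset$total_assigned
  freq_b <- as.numeric(background$counts) / background$total_assigned
  ks <- ks_two_sample(freq_a, freq_b, p_method = p_method)
  structure(list(scheme = dataset$scheme, level = dataset$level,
                 statistic = ks$statistic, p_value = ks$p_value,
                 biased = ks$p_value <= alpha, alpha = alpha,
                 n_dataset = ks$n, n_background = ks$m),
            class = "distribution_test_result")
}

#' Coverage of a classification scheme
#'
#' `coverage = A(DS) / A`: the fraction of all classes of the scheme with
#' at least one representative in the dataset. Dataset labels outside the
#' background are not covered classes; they are counted separately as
#' `excess`.
#'
#' @param dataset_labels Category labels present in the dataset.
#' @param background_labels All category labels of the scheme (non-empty).
#' @return A list of class `coverage_result`: `classes_in_dataset` (A(DS)),
#'   `classes_total` (A), `coverage` fraction, `percent` (2 decimals),
#'   `excess`.
#' @export
coverage <- function(dataset_labels, background_labels) {
  background_labels <- unique(background_labels)
  if (!length(background_labels)) {
    stop("background label set is empty", call. = FALSE)
  }
  dataset_labels <- unique(dataset_labels)
  a_ds <- length(intersect(dataset_labels, background_labels))
  a <- length(background_labels)
  structure(list(classes_in_dataset = as.integer(a_ds),
                 classes_total = as.integer(a),
                 coverage = a_ds / a,
                 percent = percent_of(a_ds, a),
                 excess = length(setdiff(dataset_labels, background_labels))),
            class = "coverage_result")
}

#' Screen a dataset for common (likely benign) variants
#'
#' A record matches when the frequency table holds an entry with identical
#' (canonical accession, position, reference, alternate) whose minor
#' allele frequency lies strictly between `low` and `high` in at least one
#' population. The matched fraction is reported as a percentage of all
#' records.
#'
#' @param records Variant records, mapped to canonical proteins
#'   ([to_canonical()] or better).
#' @param table A `frequency_table`.
#' @param low,high The open MAF window (defaults 0.01 and 0.25).
#' @return A list of class `contamination_result`: `matched`, `total`,
#'   `fraction` (percent), `maf_low`, `maf_high`.
#' @export
benign_contamination <- function(records, table, low = 0.01, high = 0.25) {
  maf_cols <- grep("^maf_", names(table), value = TRUE)
  if (!length(maf_cols)) stop("frequency table has no maf_* columns", call. = FALSE)
  in_window <- rep(FALSE, nrow(table))
  for (col in maf_cols) {
    in_window <- in_window | (table[[col]] > low & table[[col]] < high)
  }
  keys <- paste(table$accession, table$position, table$ref_aa, table$alt_aa)[in_window]
  rec_keys <- paste(records$canonical_protein, records$position,
                    records$ref_aa, records$alt_aa)
  matched <- sum(!is.na(records$canonical_protein) & rec_keys %in% keys)
  total <- nrow(records)
  structure(list(matched = as.integer(matched), total = as.integer(total),
                 fraction = percent_of(matched, total),
                 maf_low = low, maf_high = high),
            class = "contamination_result")
}
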