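# The statistical battery against closed forms and brute-force oracles.

test_that("weighted expectations are exactly proportional and sum to the total", {
  expect_equal(as.numeric(expected_counts(c(a = 1, b = 1, c = 2), 8)),
               c(2, 2, 4))
  expect_equal(as.numeric(expected_counts(c(only = 5), 123)), 123)
  w <- c(a = 3, b = 7, c = 11)
  expect_equal(sum(expected_counts(w, 1e5)), 1e5)
  expect_error(expected_counts(c(a = 0, b = 0), 10), "zero")
  expect_error(expected_counts(c(a = -1, b = 2), 10), "non-negative")
})

test_that("the two-tailed binomial p equals exhaustive enumeration for n <= 20", {
  for (p0 in c(0.1, 0.3, 0.5)) {
    for (n in 1:20) {
      for (k in 0:n) {
        expect_equal(binomial_two_tailed(k, n, p0), enum_binom_p(k, n, p0),
                     tolerance = 1e-12,
                     label = sprintf("k=%d n=%d p0=%g", k, n, p0))
      }
    }
  }
  expect_equal(binomial_two_tailed(1, 2, 0.5), 1)  # modal outcome
  expect_error(binomial_two_tailed(5, 4, 0.5), "k")
  expect_error(binomial_two_tailed(1, 2, 0), "p0")
})

test_that("the chromosome profile equals componentwise binomial tests", {
  withr::with_seed(57, {
    labels <- paste0("c", 1:6)
    wg <- setNames(sample(50:300, 6), labels)
    wc <- setNames(sample(1e4:1e5, 6), labels)
    obs <- setNames(as.numeric(rmultinom(1, 500, wg / sum(wg))), labels)
  })
  observed <- category_counts("chromosome", "chromosome", obs)
  background <- list(genes = category_counts("chromosome", "genes", wg),
                     cds = category_counts("chromosome", "cds", wc))
  prof <- chromosome_bias_profile(observed, background, alpha = 0.05)
  n <- sum(obs)
  for (i in seq_along(labels)) {
    ch <- prof$results$chromosome[i]
    expect_equal(prof$results$p_genes[i],
                 binomial_two_tailed(obs[[ch]], n, wg[[ch]] / sum(wg)))
    expect_equal(prof$results$p_cds[i],
                 binomial_two_tailed(obs[[ch]], n, wc[[ch]] / sum(wc)))
    expect_equal(prof$results$biased_genes[i], prof$results$p_genes[i] <= 0.05)
  }
  expect_equal(prof$n_unbiased_genes, sum(prof$results$p_genes > 0.05))
  # expectations sum back to the observed total
  expect_equal(sum(prof$results$expected_genes), n, tolerance = 1e-9)
  # an exactly proportional integer profile is everywhere unbiased
  prop <- category_counts("chromosome", "chromosome",
                          setNames(as.numeric(wg * 2), labels))
  prof2 <- chromosome_bias_profile(prop, background, alpha = 0.5)
  expect_equal(prof2$n_unbiased_genes, 6)
  expect_error(chromosome_bias_profile(
    category_counts("chromosome", "chromosome", c(zz = 5)), background),
    "zz")
})

test_that("Pearson chi-square matches the closed form and its invariances", {
  obs <- c(a = 10, b = 20, c = 30)
  exp_ <- c(a = 15, b = 15, c = 30)
  got <- pearson_chi_square(obs, exp_)
  expect_equal(got$statistic, 25 / 15 + 25 / 15 + 0)
  expect_equal(got$df, 2)
  expect_equal(got$p_value, pchisq(got$statistic, 2, lower.tail = FALSE))
  # agreement with stats::chisq.test as an independent route
  ct <- suppressWarnings(chisq.test(obs, p = exp_ / sum(exp_)))
  expect_equal(got$statistic, unname(ct$statistic))
  expect_equal(got$p_value, ct$p.value)
  # identical distributions give 0 / p = 1
  same <- pearson_chi_square(obs, obs)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # relabeling invariance and quadratic scaling
  perm <- c("c", "a", "b")
  expect_equal(pearson_chi_square(obs[perm], exp_[perm])$statistic,
               got$statistic)
  expect_equal(pearson_chi_square(obs * 3, exp_ * 3)$statistic,
               3 * got$statistic)
  expect_error(pearson_chi_square(obs, c(a = 0, b = 30, c = 30)), "> 0")
  expect_error(pearson_chi_square(obs, c(a = 1, b = 1)), "differ")
})

test_that("the KS statistic equals the brute-force ECDF gap for samples <= 8", {
  withr::with_seed(71, {
    for (case in 1:200) {
      n <- sample(1:8, 1); m <- sample(1:8, 1)
      # draw from a small value set so ties across and within samples occur
      a <- sample(seq(0, 1, by = 0.125), n, replace = TRUE)
      b <- sample(seq(0, 1, by = 0.125), m, replace = TRUE)
      got <- ks_two_sample(a, b)
      want <- suppressWarnings(unname(stats::ks.test(a, b)$statistic))
      expect_equal(got$statistic, want, tolerance = 1e-12)
    }
  })
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("exact KS p-values are available for honest small-sample use", {
  a <- c(0.1, 0.4, 0.9); b <- c(0.2, 0.5, 0.95)
  exact <- ks_two_sample(a, b, p_method = "exact")
  expect_equal(exact$p_value,
               suppressWarnings(stats::ks.test(a, b, exact = TRUE)$p.value))
  expect_false(isTRUE(all.equal(exact$p_value,
                                ks_two_sample(a, b)$p_value)))
})

test_that("frequency-vector KS tests normalize by total assignments", {
  ds <- category_counts("go", "aspect", c(MF = 30, BP = 50, CC = 20))
  bg <- category_counts("go", "aspect", c(MF = 300, BP = 500, CC = 200))
  res <- ks_frequency_test(ds, bg)
  expect_equal(res$statistic, 0)  # identical profiles after normalization
  expect_equal(res$n_dataset, 3)
  expect_false(res$biased)
  empty <- category_counts("go", "aspect", numeric(0))
  expect_error(ks_frequency_test(empty, bg), "no assignments")
})

test_that("coverage is the covered-class fraction, monotone under union", {
  bg <- paste0("k", 1:50)
  expect_equal(coverage(character(0), bg)$coverage, 0)
  expect_equal(coverage(bg, bg)$coverage, 1)
  expect_equal(coverage(bg, bg)$percent, 100)
  withr::with_seed(83, {
    s1 <- sample(bg, 10); s2 <- sample(bg, 25)
  })
  c1 <- coverage(s1, bg)
  c12 <- coverage(union(s1, s2), bg)
  expect_gte(c12$coverage, c1$coverage)
  expect_gte(c12$coverage, coverage(s2, bg)$coverage)
  # labels outside the scheme are excess, not coverage
  ex <- coverage(c(s1, "alien"), bg)
  expect_equal(ex$classes_in_dataset, 10L)
  expect_equal(ex$excess, 1L)
  expect_error(coverage("a", character(0)), "empty")
})

test_that("the contamination screen is a strict-window exact join", {
  ft <- data.frame(accession = c("PA", "PA", "PB"),
                   position = c(10L, 20L, 5L),
                   ref_aa = c("A", "G", "L"), alt_aa = c("V", "R", "P"),
                   maf_1 = c(0.02, 0.25, 0.0), maf_2 = c(0.0, 0.0, 0.3),
                   stringsAsFactors = FALSE)
  class(ft) <- c("frequency_table", "data.frame")
  recs <- rbind(variant_row("uniprot", "PA", 10),            # matches (maf_1)
                variant_row("uniprot", "PA", 20, "G", "R"),  # 0.25 excluded
                variant_row("uniprot", "PB", 5, "L", "P"),   # 0.3 outside
                variant_row("uniprot", "PA", 10, "A", "L"))  # alt differs
  recs$canonical_protein <- recs$ref_id
  recs$mapping_status <- "protein_mapped"
  res <- benign_contamination(recs, ft)
  expect_equal(res$matched, 1L)
  expect_equal(res$total, 4L)
  expect_equal(res$fraction, 25)
  # brute-force nested-loop join on a random fixture
  ref <- fixture_proteome()
  ds <- generate_variant_dataset(ref, sampling_spec(
    n_variants = 200, seed = 47,
    namespace_weights = c(refseq = 0, ensembl = 0, uniprot = 1)))
  ds$canonical_protein <- ds$ref_id
  ds$mapping_status <- "protein_mapped"
  big <- generate_frequency_table(ref, n_entries = 400, seed = 53)
  got <- benign_contamination(ds, big)
  maf <- as.matrix(big[grep("^maf_", names(big))])
  want <- 0L
  for (i in seq_len(nrow(ds))) {
    hit <- FALSE
    for (j in seq_len(nrow(big))) {
      if (ds$canonical_protein[i] == big$accession[j] &&
          ds$position[i] == big$position[j] &&
          ds$ref_aa[i] == big$ref_aa[j] && ds$alt_aa[i] == big$alt_aa[j] &&
          any(maf[j, ] > 0.01 & maf[j, ] < 0.25)) hit <- TRUE
    }
    want <- want + hit
  }
  expect_equal(got$matched, want)
})

test_that("uniform synthetic data is calibrated: chromosome false-bias rate near alpha", {
  ref <- fixture_proteome()
  bg <- build_background(ref, "chromosome")
  rates <- vapply(1:200, function(s) {
    ds <- generate_variant_dataset(ref, sampling_spec(n_variants = 2000,
                                                      seed = 1000 + s))
    prof <- chromosome_bias_profile(chromosome_counts(ds), bg, alpha = 0.05)
    mean(prof$results$biased_cds)
  }, 0)
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.05), 3 * se + 1e-12)
})
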