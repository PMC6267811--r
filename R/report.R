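# End-to-end assessment of one or several datasets: mapping funnel,
# chromosomal battery, per-scheme per-level KS tests and coverages,
# contamination screen, and the summary score counting unbiased categories.

# The 11 scored categories, in reporting order.
category_keys <- function() {
  c("cath_class", "cath_architecture", "cath_topology", "cath_homology",
    "ec_1", "ec_2", "ec_3", "ec_4", "pfam", "go_term", "go_aspect")
}

#' Assessment configuration
#'
#' @param alpha_chromosome Significance level of the per-chromosome
#'   binomial tests (default 0.05).
#' @param alpha_ks Significance level of the KS category tests (default
#'   0.01).
#' @param ks_p_method "asymptotic" (default) or "exact", see
#'   [ks_two_sample()].
#' @param distinct_per_variant Multiplicity policy for variants hitting
#'   several Pfam families or GO terms (default: count once per category).
#' @return A list of class `assessment_config`.
#' @export
assessment_config <- function(alpha_chromosome = 0.05, alpha_ks = 0.01,
                              ks_p_method = c("asymptotic", "exact"),
                              distinct_per_variant = TRUE) {
  for (a in c(alpha_chromosome, alpha_ks)) {
    if (!is.numeric(a) || a <= 0 || a >= 1) {
      stop_param("alpha", "significance levels must be in (0, 1)")
    }
  }
  structure(list(alpha_chromosome = alpha_chromosome, alpha_ks = alpha_ks,
                 ks_p_method = match.arg(ks_p_method),
                 distinct_per_variant = isTRUE(distinct_per_variant)),
            class = "assessment_config")
}

not_computable <- function(scheme, level, reason) {
  structure(list(scheme = scheme, level = level, statistic = NULL,
                 p_value = NULL, biased = NA, reason = reason),
            class = "distribution_test_result")
}

#' Assess the representativeness of one variant dataset
#'
#' Runs the full pipeline: identifier and structure mapping with tallies,
#' the chromosomal battery (per-chromosome binomial tests under both
#' weightings plus overall chi-square), KS frequency tests and coverage
#' for every level of CATH, EC, Pfam and GO against the proteome
#' backgrounds, the optional contamination screen, and the summary score.
#' Categories that cannot be computed (for example the CATH levels of a
#' dataset with zero structure-mapped variants) are marked with an
#' explicit reason and score 0. Deterministic for fixed inputs.
#'
#' @param records Variant record data.frame (one dataset).
#' @param reference A [proteome_reference()].
#' @param freq_table Optional `frequency_table` for the contamination
#'   screen.
#' @param config An [assessment_config()].
#' @return A list of class `dataset_report`.
#' @export
assess_dataset <- function(records, reference, freq_table = NULL,
                           config = assessment_config()) {
  stopifnot(inherits(reference, "proteome_reference"))
  label <- if (nrow(records)) records$dataset_label[1] else "empty"

  mapped <- map_dataset(records, reference)
  rec <- mapped$records

  chrom_obs <- chromosome_counts(rec, reference)
  chrom_bg <- build_background(reference, "chromosome")
  profile <- chromosome_bias_profile(chrom_obs, chrom_bg,
                                     alpha = config$alpha_chromosome)
  chisq_of <- function(weights) {
    keep <- weights > 0
    obs <- stats::setNames(profile$results$observed, profile$results$chromosome)
    if (sum(obs[keep]) == 0) {  # empty dataset: nothing to compare
      return(list(statistic = NA_real_, p_value = NA_real_,
                  df = sum(keep) - 1L))
    }
    pearson_chi_square(obs[keep], expected_counts(weights[keep], sum(obs[keep])))
  }
  chisq_genes <- chisq_of(chrom_bg$genes$counts)
  chisq_cds <- chisq_of(chrom_bg$cds$counts[names(chrom_bg$genes$counts)])

  cath_codes <- cath_assignments(rec, reference)
  pfam_fams <- pfam_assignments(rec, reference)
  ec_codes <- function_assignments(rec, reference, "ec")
  go_frames <- function_assignments(rec, reference, "go")
  go_terms <- lapply(go_frames, `[[`, "term")
  go_aspects <- lapply(go_frames, `[[`, "aspect")

  backgrounds <- list(cath = build_background(reference, "cath"),
                      pfam = build_background(reference, "pfam"),
                      ec = build_background(reference, "ec"),
                      go = build_background(reference, "go"))

  spec_of <- list(
    cath_class = list("cath", "class", cath_codes),
    cath_architecture = list("cath", "architecture", cath_codes),
    cath_topology = list("cath", "topology", cath_codes),
    cath_homology = list("cath", "homology", cath_codes),
    ec_1 = list("ec", "1", ec_codes), ec_2 = list("ec", "2", ec_codes),
    ec_3 = list("ec", "3", ec_codes), ec_4 = list("ec", "4", ec_codes),
    pfam = list("pfam", "family", pfam_fams),
    go_term = list("go", "term", go_terms),
    go_aspect = list("go", "aspect", go_aspects)
  )

  tests <- list(); coverages <- list(); dataset_counts <- list()
  for (key in category_keys()) {
    sp <- spec_of[[key]]
    scheme <- sp[[1]]; level <- sp[[2]]
    bg <- backgrounds[[scheme]][[level]]
    ds <- level_counts(sp[[3]], scheme, level,
                       distinct_per_variant = config$distinct_per_variant)
    dataset_counts[[key]] <- ds
    if (is.null(bg) || bg$total_assigned == 0) {
      tests[[key]] <- not_computable(scheme, level, "empty background")
      next
    }
    coverages[[key]] <- coverage(names(ds$counts), names(bg$counts))
    if (ds$total_assigned == 0) {
      reason <- if (scheme == "cath" && mapped$tallies$n_structure_mapped == 0) {
        "no structure-mapped variants"
      } else {
        sprintf("no variants with a %s assignment at level %s", scheme, level)
      }
      tests[[key]] <- not_computable(scheme, level, reason)
      next
    }
    tests[[key]] <- ks_frequency_test(ds, bg, alpha = config$alpha_ks,
                                      p_method = config$ks_p_method)
  }

  contamination <- if (!is.null(freq_table)) {
    benign_contamination(rec, freq_table)
  }

  score <- score_dataset(tests, alpha = config$alpha_ks,
                         chromosome_unbiased = profile$n_unbiased_genes)

  structure(list(
    label = label,
    n_records = nrow(rec),
    records = rec,
    tallies = mapped$tallies,
    chromosome = list(counts = chrom_obs, profile = profile,
                      chisq_genes = chisq_genes, chisq_cds = chisq_cds),
    dataset_counts = dataset_counts,
    tests = tests,
    coverages = coverages,
    contamination = contamination,
    score = score,
    config = config
  ), class = "dataset_report")
}

#' Summary score over the 11 category tests
#'
#' Each category (CATH class/architecture/topology/homology, EC levels
#' 1-4, Pfam, GO term, GO aspect) scores 1 when its distribution test is
#' unbiased (p > alpha) and 0 when biased. A category that could not be
#' computed scores 0 and is listed explicitly in `notes` - silent omission
#' would inflate comparability between datasets. The chromosome battery is
#' reported alongside but excluded from the category sum.
#'
#' @param tests Named list of `distribution_test_result`s (keys as in the
#'   report; missing keys count as not computable).
#' @param alpha Significance level for the unbiased call.
#' @param chromosome_unbiased Number of unbiased chromosomes to carry in
#'   the score object.
#' @return A list of class `summary_score`: `chromosome_unbiased_count`,
#'   `category_flags` (named 0/1 vector over the 11 categories),
#'   `score_without_chromosomes`, `notes`.
#' @export
score_dataset <- function(tests, alpha = 0.01, chromosome_unbiased = NA_integer_) {
  keys <- category_keys()
  flags <- stats::setNames(integer(length(keys)), keys)
  notes <- character(0)
  for (key in keys) {
    t <- tests[[key]]
    if (is.null(t) || is.null(t$p_value)) {
      notes <- c(notes, sprintf("%s: not computable (%s); scored 0", key,
                                if (is.null(t)) "absent" else t$reason))
      next
    }
    flags[[key]] <- as.integer(t$p_value > alpha)
  }
  structure(list(chromosome_unbiased_count = chromosome_unbiased,
                 category_flags = flags,
                 score_without_chromosomes = sum(flags),
                 notes = notes),
            class = "summary_score")
}

#' @export
print.dataset_report <- function(x, ...) {
  t <- x$tallies
  cat(sprintf("dataset_report '%s': %d variants\n", x$label, x$n_records))
  cat(sprintf("  protein-mapped   %d (%.2f%%)\n", t$n_protein_mapped,
              t$pct_protein_mapped))
  cat(sprintf("  structure-mapped %d (%.2f%%)\n", t$n_structure_mapped,
              t$pct_structure_mapped))
  cat(sprintf("  unbiased chromosomes (gene basis): %d of %d\n",
              x$chromosome$profile$n_unbiased_genes,
              nrow(x$chromosome$profile$results)))
  if (!is.null(x$contamination)) {
    cat(sprintf("  common-variant contamination: %d/%d (%.2f%%)\n",
                x$contamination$matched, x$contamination$total,
                x$contamination$fraction))
  }
  flags <- x$score$category_flags
  cat("  category flags:", paste(names(flags), flags, sep = "=", collapse = " "),
      "\n")
  cat(sprintf("  score without chromosomes: %d of %d\n",
              x$score$score_without_chromosomes, length(flags)))
  invisible(x)
}

#' Compare several dataset reports
#'
#' Builds the cross-dataset summary table, the scatter table relating the
#' number of unique CATH superfamilies to the log10 number of
#' structure-mapped variants, and Spearman rank correlations between
#' dataset size and coverage for each scheme/level.
#'
#' @param reports List of `dataset_report`s (>= 1).
#' @return A list with `summary` (data.frame, one row per dataset),
#'   `scatter` (data.frame) and `rank_correlation` (named numeric).
#' @export
compare_datasets <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, TRUE, "dataset_report")))
  keys <- category_keys()
  rows <- lapply(reports, function(r) {
    cov <- vapply(keys, function(k) {
      if (is.null(r$coverages[[k]])) NA_real_ else r$coverages[[k]]$percent
    }, 0)
    names(cov) <- paste0("coverage_", keys)
    c(list(dataset = r$label, n_records = r$n_records,
           n_structure_mapped = r$tallies$n_structure_mapped,
           unique_cath_superfamilies =
             length(r$dataset_counts$cath_homology$counts),
           n_unbiased_chromosomes = r$chromosome$profile$n_unbiased_genes,
           score_without_chromosomes = r$score$score_without_chromosomes),
      as.list(cov))
  })
  summary <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  scatter <- data.frame(
    dataset = summary$dataset,
    unique_cath_superfamilies = summary$unique_cath_superfamilies,
    log10_structure_mapped = ifelse(summary$n_structure_mapped > 0,
                                    log10(summary$n_structure_mapped), NA_real_),
    stringsAsFactors = FALSE
  )
  rank_correlation <- vapply(keys, function(k) {
    covs <- summary[[paste0("coverage_", k)]]
    ok <- !is.na(covs)
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(stats::cor(summary$n_records[ok], covs[ok],
                                method = "spearman"))
  }, 0)
  list(summary = summary, scatter = scatter, rank_correlation = rank_correlation)
}
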