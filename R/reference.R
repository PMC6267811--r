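# The in-memory annotation universe every pipeline stage consults.
#
# A proteome_reference bundles plain data.frames:
#   genes         gene_id, chromosome, cds_length (nt)
#   proteins      accession, length (residues), gene_id
#   crossrefs     namespace (refseq|ensembl), foreign_id, canonical_id,
#                 foreign_length, canonical_length
#   structures    one row per chain mapping: structure_id, chain, accession,
#                 sp_beg, sp_end (protein numbering, 1-based inclusive),
#                 res_beg (structure numbering of the residue at sp_beg),
#                 resolution (angstrom, NA when absent), file_order
#   unobserved    structure_id, chain, sp_pos - residues present in the
#                 sequence but not resolved in the structure, in protein
#                 numbering (the Not_Observed sidecar)
#   cath_domains  domain_id, c, a, t, h (integer codes per level)
#   cath_segments domain_id, structure_id, chain, seg_start, seg_end
#                 (structure numbering)
#   pfam          accession, family, start, end (protein numbering)
#   ec            accession, ec_code (1-4 dot-separated levels)
#   go            accession, term, aspect
#   clusters      cluster_id, structure_id, chain, member_order -
#                 95%-identity chain groups; member_order 1 marks the
#                 cluster representative
#
# The boundary between structure numbering and protein numbering is crossed
# only through the structures table: a variant at protein position p sits on
# structure residue res_beg + (p - sp_beg).

#' Construct a proteome reference
#'
#' Assembles the annotation universe used by mapping, annotation and the
#' statistical battery. All registries are plain data.frames (see the
#' column contracts in the package source); missing registries default to
#' empty. Referential integrity is checked with [validate_reference()].
#'
#' @param genes,proteins,crossrefs,structures,unobserved,cath_domains,cath_segments,pfam,ec,go,clusters
#'   Registry data.frames; any may be omitted.
#' @param validate Check cross-registry integrity (default TRUE).
#' @return An object of class `proteome_reference`.
#' @export
proteome_reference <- function(genes = NULL, proteins = NULL, crossrefs = NULL,
                               structures = NULL, unobserved = NULL,
                               cath_domains = NULL, cath_segments = NULL,
                               pfam = NULL, ec = NULL, go = NULL,
                               clusters = NULL, validate = TRUE) {
  empty <- function(...) {
    cols <- c(...)
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
  }
  ref <- structure(list(
    genes         = genes %||% empty("gene_id", "chromosome", "cds_length"),
    proteins      = proteins %||% empty("accession", "length", "gene_id"),
    crossrefs     = crossrefs %||% empty("namespace", "foreign_id", "canonical_id",
                                         "foreign_length", "canonical_length"),
    structures    = structures %||% empty("structure_id", "chain", "accession",
                                          "sp_beg", "sp_end", "res_beg",
                                          "resolution", "file_order"),
    unobserved    = unobserved %||% empty("structure_id", "chain", "sp_pos"),
    cath_domains  = cath_domains %||% empty("domain_id", "c", "a", "t", "h"),
    cath_segments = cath_segments %||% empty("domain_id", "structure_id", "chain",
                                             "seg_start", "seg_end"),
    pfam          = pfam %||% empty("accession", "family", "start", "end"),
    ec            = ec %||% empty("accession", "ec_code"),
    go            = go %||% empty("accession", "term", "aspect"),
    clusters      = clusters %||% empty("cluster_id", "structure_id", "chain",
                                        "member_order")
  ), class = "proteome_reference")
  for (nm in names(ref)) rownames(ref[[nm]]) <- NULL
  if (validate) validate_reference(ref)
  ref
}

#' Validate cross-registry integrity of a proteome reference
#'
#' Checks that every annotation points at an existing protein, that protein
#' lengths agree with gene CDS lengths where both exist, that Pfam and CATH
#' segment bounds lie within their protein/chain, and that cluster members
#' are known chains. Violations are collected and reported together, each
#' naming its registry and offending identifiers.
#'
#' @param ref A `proteome_reference`.
#' @return `ref`, invisibly; stops with the full violation list otherwise.
#' @export
validate_reference <- function(ref) {
  stopifnot(inherits(ref, "proteome_reference"))
  bad <- character(0)
  note <- function(registry, ids) {
    if (length(ids)) {
      bad <<- c(bad, sprintf("%s: unknown or out-of-bounds reference(s): %s",
                             registry, paste(utils::head(unique(ids), 5), collapse = ", ")))
    }
  }
  acc <- ref$proteins$accession
  plen <- stats::setNames(ref$proteins$length, acc)

  note("proteins", ref$proteins$gene_id[!ref$proteins$gene_id %in% ref$genes$gene_id])
  note("crossrefs", ref$crossrefs$canonical_id[!ref$crossrefs$canonical_id %in% acc])
  note("structures", ref$structures$accession[!ref$structures$accession %in% acc])

  if (nrow(ref$structures)) {
    s <- ref$structures
    bad_iv <- s$sp_beg < 1 | s$sp_beg > s$sp_end | s$sp_end > plen[s$accession]
    note("structures", paste0(s$structure_id, "_", s$chain)[bad_iv])
  }
  if (nrow(ref$pfam)) {
    p <- ref$pfam
    unknown <- !p$accession %in% acc
    note("pfam", p$accession[unknown])
    known <- !unknown
    bad_iv <- known & (p$start < 1 | p$start > p$end | p$end > plen[p$accession])
    note("pfam", paste0(p$accession, ":", p$family)[bad_iv])
  }
  note("ec", ref$ec$accession[!ref$ec$accession %in% acc])
  note("go", ref$go$accession[!ref$go$accession %in% acc])

  chain_key <- function(df) paste0(df$structure_id, "_", df$chain)
  known_chains <- chain_key(ref$structures)
  if (nrow(ref$cath_segments)) {
    seg <- ref$cath_segments
    note("cath_segments", seg$domain_id[!seg$domain_id %in% ref$cath_domains$domain_id])
    k <- chain_key(seg)
    unknown <- !k %in% known_chains
    note("cath_segments", k[unknown])
    if (any(!unknown)) {
      s <- ref$structures
      idx <- match(k, known_chains)
      # segment bounds in structure numbering must stay inside the mapped run
      res_end <- s$res_beg[idx] + (s$sp_end[idx] - s$sp_beg[idx])
      bad_iv <- !unknown & (seg$seg_start > seg$seg_end |
                              seg$seg_start < s$res_beg[idx] | seg$seg_end > res_end)
      note("cath_segments", seg$domain_id[bad_iv])
    }
  }
  if (nrow(ref$clusters)) {
    note("clusters", chain_key(ref$clusters)[!chain_key(ref$clusters) %in% known_chains])
  }
  if (nrow(ref$unobserved)) {
    note("unobserved", chain_key(ref$unobserved)[!chain_key(ref$unobserved) %in% known_chains])
  }
  if (length(bad)) {
    stop("reference integrity violations:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(ref)
}

#' @export
print.proteome_reference <- function(x, ...) {
  cat("proteome_reference:",
      nrow(x$genes), "genes,",
      nrow(x$proteins), "proteins,",
      length(unique(x$structures$structure_id)), "structures,",
      nrow(x$cath_domains), "CATH domains,",
      length(unique(x$pfam$family)), "Pfam families,",
      nrow(x$ec), "EC rows,",
      length(unique(x$go$term)), "GO terms\n")
  invisible(x)
}

#' Per-chromosome summary of the VariSNP neutral benchmark
#'
#' The packaged worked example: for each of the 24 human chromosomes
#' (1-22, X, Y), the number of protein-coding genes and total CDS length
#' (Ensembl Biomart, GRCh38) and the observed number of variants in the
#' VariSNP neutral single-nucleotide variant benchmark (446,013 SNVs of
#' which 445,989 carry a chromosome label). These are the inputs of the
#' chromosomal bias analysis in [run_chromosome_example()].
#'
#' @return data.frame with columns `chromosome`, `n_genes`, `cds_length`,
#'   `observed_variants`.
#' @export
chromosome_example_data <- function() {
  path <- system.file("extdata", "varisnp_chromosome_summary.tsv",
                      package = "benchrep", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric", "integer"))
  df
}

#' Run the chromosomal worked example
#'
#' Applies the chromosomal bias battery to the packaged VariSNP summary:
#' per-chromosome two-tailed binomial tests under gene-count and CDS-length
#' weighting, and the overall Pearson chi-square statistic under both
#' weightings.
#'
#' @param alpha Significance level for the per-chromosome tests (default 0.05).
#' @return A list with the `chromosome_bias_profile()` result and the two
#'   chi-square results (`chisq_genes`, `chisq_cds`).
#' @examples
#' ex <- run_chromosome_example()
#' ex$chisq_genes$statistic      # 8657.11
#' ex$profile$n_unbiased_genes   # 7
#' @export
run_chromosome_example <- function(alpha = 0.05) {
  df <- chromosome_example_data()
  observed <- category_counts("chromosome", "chromosome",
                              stats::setNames(df$observed_variants, df$chromosome))
  background <- list(
    genes = category_counts("chromosome", "genes",
                            stats::setNames(df$n_genes, df$chromosome)),
    cds = category_counts("chromosome", "cds",
                          stats::setNames(df$cds_length, df$chromosome))
  )
  profile <- chromosome_bias_profile(observed, background, alpha = alpha)
  n <- sum(df$observed_variants)
  chisq_genes <- pearson_chi_square(
    stats::setNames(df$observed_variants, df$chromosome),
    expected_counts(stats::setNames(df$n_genes, df$chromosome), n))
  chisq_cds <- pearson_chi_square(
    stats::setNames(df$observed_variants, df$chromosome),
    expected_counts(stats::setNames(df$cds_length, df$chromosome), n))
  list(profile = profile, chisq_genes = chisq_genes, chisq_cds = chisq_cds)
}
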