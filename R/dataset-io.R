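# Reading and writing every table the pipeline touches. One internal
# dialect: tab-separated, single header line, 1-based inclusive residue
# coordinates. Readers never silently coerce - every dropped row is
# counted and logged.

#' Describe the columns of a variant table
#'
#' A dialect descriptor names the columns holding the namespace, the
#' reference identifier, the 1-based residue position and the reference and
#' alternate residues, plus the optional chromosome/gene/label columns.
#' The defaults match the tables written by [write_variant_table()].
#'
#' @param namespace_col,id_col,position_col,ref_col,alt_col Mandatory
#'   column names.
#' @param chromosome_col,gene_col,label_col Optional column names (NULL if
#'   absent from the file).
#' @return A list of class `variant_dialect`.
#' @export
variant_dialect <- function(namespace_col = "ref_namespace", id_col = "ref_id",
                            position_col = "position", ref_col = "ref_aa",
                            alt_col = "alt_aa", chromosome_col = "chromosome",
                            gene_col = "gene", label_col = "dataset_label") {
  structure(list(namespace_col = namespace_col, id_col = id_col,
                 position_col = position_col, ref_col = ref_col,
                 alt_col = alt_col, chromosome_col = chromosome_col,
                 gene_col = gene_col, label_col = label_col),
            class = "variant_dialect")
}

#' Read a variant table
#'
#' Reads a delimited table of single amino acid substitutions. Malformed
#' rows - residue letters outside the 20-letter alphabet, non-positive or
#' missing positions, identical reference and alternate residues, unknown
#' namespaces - are dropped; the drop count is logged to stderr and
#' returned alongside the records.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param dialect A [variant_dialect()] naming the columns.
#' @param dataset_label Label stamped on the records when the file has no
#'   label column.
#' @return A list with `records` (the cleaned record data.frame) and
#'   `n_dropped`.
#' @export
read_variant_table <- function(path, dialect = variant_dialect(),
                               dataset_label = basename(path)) {
  stopifnot(file.exists(path), inherits(dialect, "variant_dialect"))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  mandatory <- c(dialect$namespace_col, dialect$id_col, dialect$position_col,
                 dialect$ref_col, dialect$alt_col)
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("variant table ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  opt <- function(col, default) {
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else default
  }
  n_raw <- nrow(raw)
  records <- data.frame(
    dataset_label = opt(dialect$label_col, rep(dataset_label, n_raw)),
    ref_namespace = raw[[dialect$namespace_col]],
    ref_id = raw[[dialect$id_col]],
    position = suppressWarnings(as.integer(raw[[dialect$position_col]])),
    ref_aa = toupper(raw[[dialect$ref_col]]),
    alt_aa = toupper(raw[[dialect$alt_col]]),
    chromosome = opt(dialect$chromosome_col, rep(NA_character_, n_raw)),
    gene = opt(dialect$gene_col, rep(NA_character_, n_raw)),
    canonical_protein = NA_character_,
    mapping_status = "unmapped",
    stringsAsFactors = FALSE
  )
  if (n_raw == 0) return(list(records = records, n_dropped = 0L))
  records$chromosome[records$chromosome %in% c("", "NA")] <- NA_character_
  records$gene[records$gene %in% c("", "NA")] <- NA_character_
  aa <- amino_acids()
  ok <- !is.na(records$position) & records$position >= 1 &
    records$ref_aa %in% aa & records$alt_aa %in% aa &
    records$ref_aa != records$alt_aa &
    records$ref_namespace %in% c("refseq", "ensembl", "uniprot")
  n_dropped <- sum(!ok)
  if (n_dropped) {
    message(sprintf("read_variant_table: dropped %d malformed row(s) of %d in %s",
                    n_dropped, n_raw, path))
  }
  records <- records[ok, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, n_dropped = as.integer(n_dropped))
}

#' Write a variant table
#'
#' @param records Variant record data.frame.
#' @param path Output path (tab-separated, header line).
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  cols <- c("dataset_label", "ref_namespace", "ref_id", "position",
            "ref_aa", "alt_aa", "chromosome", "gene")
  write_tsv(records[, intersect(cols, names(records)), drop = FALSE], path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = colClasses,
                    na.strings = "")
}

bundle_files <- function() {
  c(genes = "genes.tsv", proteins = "proteins.tsv", crossrefs = "crossrefs.tsv",
    structures = "structure_map.tsv", unobserved = "unobserved_residues.tsv",
    cath_domains = "cath_classification.tsv", cath_segments = "cath_boundaries.tsv",
    pfam = "pfam_intervals.tsv", ec = "ec_codes.tsv", go = "go_annotations.tsv",
    clusters = "chain_clusters.tsv")
}

#' Write a proteome reference bundle to a directory
#'
#' One tab-separated file per registry plus a `manifest.json` naming them.
#' The bundle round-trips through [read_reference_bundle()].
#'
#' @param ref A [proteome_reference()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(ref, dir) {
  stopifnot(inherits(ref, "proteome_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- bundle_files()
  for (nm in names(files)) write_tsv(ref[[nm]], file.path(dir, files[[nm]]))
  jsonlite::write_json(list(format = "benchrep-reference-bundle", version = 1L,
                            files = as.list(files)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a proteome reference bundle
#'
#' Reads the registries named by the bundle manifest and validates
#' cross-file referential integrity; dangling annotations (for example a
#' Pfam row pointing at an absent accession, or a CATH segment beyond its
#' chain) abort with the offending identifiers.
#'
#' @param dir Directory holding `manifest.json` and the registry files.
#' @return A validated [proteome_reference()].
#' @export
read_reference_bundle <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no bundle manifest at ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  files <- unlist(manifest$files)
  classes <- list(
    genes = c(gene_id = "character", chromosome = "character", cds_length = "numeric"),
    proteins = c(accession = "character", length = "integer", gene_id = "character"),
    crossrefs = c(namespace = "character", foreign_id = "character",
                  canonical_id = "character", foreign_length = "integer",
                  canonical_length = "integer"),
    structures = c(structure_id = "character", chain = "character",
                   accession = "character", sp_beg = "integer", sp_end = "integer",
                   res_beg = "integer", resolution = "numeric",
                   file_order = "integer"),
    unobserved = c(structure_id = "character", chain = "character",
                   sp_pos = "integer"),
    cath_domains = c(domain_id = "character", c = "integer", a = "integer",
                     t = "integer", h = "integer"),
    cath_segments = c(domain_id = "character", structure_id = "character",
                      chain = "character", seg_start = "integer",
                      seg_end = "integer"),
    pfam = c(accession = "character", family = "character", start = "integer",
             end = "integer"),
    ec = c(accession = "character", ec_code = "character"),
    go = c(accession = "character", term = "character", aspect = "character"),
    clusters = c(cluster_id = "character", structure_id = "character",
                 chain = "character", member_order = "integer")
  )
  regs <- lapply(names(classes), function(nm) {
    path <- file.path(dir, files[[nm]])
    if (!file.exists(path)) stop("bundle file missing: ", path, call. = FALSE)
    df <- read_tsv(path, colClasses = classes[[nm]])
    df
  })
  names(regs) <- names(classes)
  do.call(proteome_reference, c(regs, list(validate = TRUE)))
}

#' Read a frequency table
#'
#' @param path Tab-separated file with columns `accession`, `position`,
#'   `ref_aa`, `alt_aa` and one `maf_*` column per population.
#' @return data.frame of class `frequency_table`.
#' @export
read_frequency_table <- function(path) {
  df <- read_tsv(path)
  need <- c("accession", "position", "ref_aa", "alt_aa")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("frequency table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  maf_cols <- grep("^maf_", names(df), value = TRUE)
  if (!length(maf_cols)) stop("frequency table has no maf_* columns", call. = FALSE)
  bad <- unlist(df[maf_cols]) < 0 | unlist(df[maf_cols]) > 0.5
  if (any(bad, na.rm = TRUE)) {
    stop("frequency table has MAF values outside [0, 0.5]", call. = FALSE)
  }
  class(df) <- c("frequency_table", "data.frame")
  df
}

#' Write a frequency table
#' @param table A `frequency_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) write_tsv(table, path)

#' Write a dataset report to a directory
#'
#' Materializes one tab-separated table per report section (mapping tallies,
#' chromosome profile, distribution tests, coverages, contamination, score)
#' plus a machine-readable `summary.json`. Writing the same report twice
#' yields byte-identical files.
#'
#' @param report A `dataset_report` from [assess_dataset()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written (the manifest), invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dataset_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    write_tsv(df, path)
    files <<- c(files, path)
  }
  t <- report$tallies
  put(data.frame(dataset = report$label, n_records = t$n_total,
                 n_protein_mapped = t$n_protein_mapped,
                 pct_protein_mapped = t$pct_protein_mapped,
                 n_structure_mapped = t$n_structure_mapped,
                 pct_structure_mapped = t$pct_structure_mapped,
                 max_variants_per_protein = t$max_per_protein,
                 protein_with_max = t$max_accession %||% NA_character_,
                 stringsAsFactors = FALSE),
      "mapping.tsv")
  put(report$chromosome$profile$results, "chromosome_profile.tsv")
  tests <- report$tests
  put(data.frame(category = names(tests),
                 statistic = vapply(tests, function(x) x$statistic %||% NA_real_, 0),
                 p_value = vapply(tests, function(x) x$p_value %||% NA_real_, 0),
                 n_dataset = vapply(tests, function(x) x$n_dataset %||% NA_integer_, 0L),
                 n_background = vapply(tests, function(x) x$n_background %||% NA_integer_, 0L),
                 computable = vapply(tests, function(x) is.null(x$reason), TRUE),
                 reason = vapply(tests, function(x) x$reason %||% "", ""),
                 stringsAsFactors = FALSE),
      "distribution_tests.tsv")
  cov <- report$coverages
  put(data.frame(category = names(cov),
                 classes_in_dataset = vapply(cov, function(x) x$classes_in_dataset, 0L),
                 classes_total = vapply(cov, function(x) x$classes_total, 0L),
                 coverage_pct = vapply(cov, function(x) x$percent, 0),
                 stringsAsFactors = FALSE),
      "coverage.tsv")
  if (!is.null(report$contamination)) {
    ct <- report$contamination
    put(data.frame(dataset = report$label, matched = ct$matched,
                   total = ct$total, pct = ct$fraction,
                   maf_low = ct$maf_low, maf_high = ct$maf_high),
        "contamination.tsv")
  }
  put(data.frame(category = names(report$score$category_flags),
                 flag = as.integer(report$score$category_flags),
                 stringsAsFactors = FALSE),
      "score.tsv")
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(report_summary(report), summary_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, summary_path)
  invisible(files)
}

# The machine-readable core of a report; what write_report puts in
# summary.json and read_report_summary returns.
report_summary <- function(report) {
  t <- report$tallies
  list(
    dataset = report$label,
    n_records = t$n_total,
    n_protein_mapped = t$n_protein_mapped,
    pct_protein_mapped = t$pct_protein_mapped,
    n_structure_mapped = t$n_structure_mapped,
    pct_structure_mapped = t$pct_structure_mapped,
    max_variants_per_protein = t$max_per_protein,
    chromosome_chisq_genes = report$chromosome$chisq_genes$statistic,
    chromosome_chisq_cds = report$chromosome$chisq_cds$statistic,
    n_unbiased_chromosomes = report$chromosome$profile$n_unbiased_genes,
    contamination_pct = if (is.null(report$contamination)) NULL else
      report$contamination$fraction,
    category_flags = as.list(report$score$category_flags),
    coverage_pct = lapply(report$coverages, function(x) x$percent),
    score_without_chromosomes = report$score$score_without_chromosomes
  )
}

#' Read back the machine-readable summary of a written report
#' @param dir Directory a report was written to.
#' @return The summary list stored in `summary.json`.
#' @export
read_report_summary <- function(dir) {
  jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = FALSE)
}
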