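# Projection of variants and the reference universe into category spaces:
# chromosome, CATH (class/architecture/topology/homology), Pfam, EC
# (levels 1-4) and GO (term/aspect). Variant-level assignment is
# position-aware for CATH (structure residue inside a domain segment) and
# Pfam (protein position inside a family interval), and protein-level for
# EC and GO.

#' Construct a category count container
#'
#' Counts of variants (or background members) per category at one level of
#' one scheme. The invariant `sum(counts) == total_assigned` always holds;
#' a variant contributing several categories at a level increments each.
#'
#' @param scheme One of chromosome, cath, pfam, ec, go.
#' @param level Level label within the scheme.
#' @param counts Named non-negative counts.
#' @return A list of class `category_counts`.
#' @export
category_counts <- function(scheme, level, counts) {
  stopifnot(scheme %in% c("chromosome", "cath", "pfam", "ec", "go"))
  if (!length(counts)) counts <- stats::setNames(numeric(0), character(0))
  counts <- counts[order(names(counts))]
  if (any(counts < 0)) stop("category counts must be non-negative", call. = FALSE)
  structure(list(scheme = scheme, level = level,
                 counts = counts, total_assigned = sum(counts)),
            class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  cat(sprintf("category_counts [%s/%s]: %d categories, %g assigned\n",
              x$scheme, x$level, length(x$counts), x$total_assigned))
  invisible(x)
}

#' Count variants per chromosome
#'
#' Uses the record's own chromosome label where present; otherwise, when a
#' reference is supplied, looks the chromosome up via the canonical protein
#' and its gene. Records without a resolvable chromosome are excluded.
#'
#' @param records Variant record data.frame.
#' @param reference Optional [proteome_reference()] for the gene lookup.
#' @return A `category_counts` on the chromosome scheme.
#' @export
chromosome_counts <- function(records, reference = NULL) {
  chrom <- if (nrow(records)) records$chromosome else character(0)
  if (!is.null(reference) && nrow(records)) {
    missing <- is.na(chrom) & !is.na(records$canonical_protein)
    if (any(missing)) {
      gene <- reference$proteins$gene_id[
        match(records$canonical_protein[missing], reference$proteins$accession)]
      chrom[missing] <- reference$genes$chromosome[
        match(gene, reference$genes$gene_id)]
    }
  }
  tab <- table(chrom[!is.na(chrom)])
  category_counts("chromosome", "chromosome",
                  stats::setNames(as.integer(tab), names(tab)))
}

#' CATH code at a structure residue
#'
#' Returns the full C.A.T.H code of the unique domain whose segment (chain
#' plus structure-residue range) contains the locus, or NA when the residue
#' lies in an inter-domain gap. Overlapping domain segments on one chain
#' are a corrupt reference and raise an error.
#'
#' @param locus A `residue_locus` from [select_structure_residue()].
#' @param reference A [proteome_reference()].
#' @return A CATH code string or NA.
#' @export
assign_cath <- function(locus, reference) {
  stopifnot(inherits(locus, "residue_locus"))
  seg <- reference$cath_segments
  hit <- seg[seg$structure_id == locus$structure_id & seg$chain == locus$chain &
               seg$seg_start <= locus$struct_resnum &
               seg$seg_end >= locus$struct_resnum, , drop = FALSE]
  if (!nrow(hit)) return(NA_character_)
  if (length(unique(hit$domain_id)) > 1) {
    stop("overlapping CATH domain segments on chain ",
         locus$structure_id, "_", locus$chain, " at residue ",
         locus$struct_resnum, call. = FALSE)
  }
  d <- reference$cath_domains[reference$cath_domains$domain_id == hit$domain_id[1], ]
  paste(d$c, d$a, d$t, d$h, sep = ".")
}

#' Pfam families containing a variant position
#'
#' All families whose `[start, end]` interval on the canonical protein
#' contains the position; the empty vector when none does.
#'
#' @param record A single protein-mapped record (list or one-row
#'   data.frame with `canonical_protein` and `position`).
#' @param reference A [proteome_reference()].
#' @return Character vector of family identifiers.
#' @export
assign_pfam <- function(record, reference) {
  p <- reference$pfam
  hit <- p$accession == record$canonical_protein &
    p$start <= record$position & p$end >= record$position
  p$family[hit]
}

#' Protein-level functional codes for a variant
#'
#' EC and GO annotation is position-independent: a protein-mapped variant
#' inherits all codes of its canonical protein. EC codes retain their
#' native depth (1-4 levels).
#'
#' @param record A single protein-mapped record.
#' @param reference A [proteome_reference()].
#' @param kind "ec" or "go".
#' @return For "ec", a character vector of codes; for "go", a data.frame
#'   with columns `term` and `aspect`.
#' @export
assign_function <- function(record, reference, kind = c("ec", "go")) {
  kind <- match.arg(kind)
  acc <- record$canonical_protein
  if (kind == "ec") {
    reference$ec$ec_code[reference$ec$accession == acc]
  } else {
    g <- reference$go[reference$go$accession == acc, c("term", "aspect")]
    rownames(g) <- NULL
    g
  }
}

# --- dataset-level assignment vectors -------------------------------------

# Full CATH code per structure-mapped record (NA for gaps / non-mapped).
# Indexes segments by chain to avoid scanning the segment table per record.
cath_assignments <- function(records, reference) {
  out <- rep(NA_character_, nrow(records))
  sm <- which(records$mapping_status == "structure_mapped")
  if (!length(sm)) return(out)
  seg <- reference$cath_segments
  d <- reference$cath_domains
  seg$code <- with(d[match(seg$domain_id, d$domain_id), , drop = FALSE],
                   paste(c, a, t, h, sep = "."))
  seg_by_chain <- split(seg, paste0(seg$structure_id, "_", seg$chain))
  rec_chain <- paste0(records$structure_id[sm], "_", records$chain[sm])
  for (j in seq_along(sm)) {
    i <- sm[j]
    s <- seg_by_chain[[rec_chain[j]]]
    if (is.null(s)) next
    hit <- s$seg_start <= records$struct_resnum[i] &
      s$seg_end >= records$struct_resnum[i]
    if (!any(hit)) next
    if (length(unique(s$domain_id[hit])) > 1) {
      stop("overlapping CATH domain segments on chain ", rec_chain[j],
           " at residue ", records$struct_resnum[i], call. = FALSE)
    }
    out[i] <- s$code[hit][1]
  }
  out
}

# List of family-id vectors per record (empty for unmapped records).
pfam_assignments <- function(records, reference) {
  mapped <- records$mapping_status %in% c("protein_mapped", "structure_mapped")
  by_acc <- split(reference$pfam[c("family", "start", "end")],
                  reference$pfam$accession)
  lapply(seq_len(nrow(records)), function(i) {
    if (!mapped[i]) return(character(0))
    p <- by_acc[[records$canonical_protein[i]]]
    if (is.null(p)) return(character(0))
    p$family[p$start <= records$position[i] & p$end >= records$position[i]]
  })
}

# List of EC code vectors / GO (term, aspect) frames per record.
function_assignments <- function(records, reference, kind) {
  mapped <- records$mapping_status %in% c("protein_mapped", "structure_mapped")
  if (kind == "ec") {
    by_acc <- split(reference$ec$ec_code, reference$ec$accession)
    lapply(seq_len(nrow(records)), function(i) {
      if (!mapped[i]) return(character(0))
      by_acc[[records$canonical_protein[i]]] %||% character(0)
    })
  } else {
    empty <- data.frame(term = character(0), aspect = character(0))
    by_acc <- split(reference$go[c("term", "aspect")], reference$go$accession)
    lapply(seq_len(nrow(records)), function(i) {
      if (!mapped[i]) return(empty)
      by_acc[[records$canonical_protein[i]]] %||% empty
    })
  }
}

# Truncate dot-separated codes to `depth` fields; codes shallower than the
# requested depth become NA (incomplete classifications drop out downward).
truncate_codes <- function(codes, depth) {
  if (!length(codes)) return(character(0))
  parts <- strsplit(codes, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < depth) NA_character_ else paste(p[seq_len(depth)], collapse = ".")
  }, "")
}

cath_level_depth <- c(class = 1L, architecture = 2L, topology = 3L, homology = 4L)

#' Tally assignments into category counts at one level
#'
#' `assignments` is one entry per variant: a character vector of full codes
#' (CATH/EC/Pfam families/GO terms or aspects). Codes are truncated to the
#' level (CATH class..homology, EC 1-4); EC codes shallower than the level
#' drop out. A variant contributing multiple categories at the level
#' increments each once (duplicates within a variant collapse when
#' `distinct_per_variant`); variants with no assignment at the level are
#' excluded.
#'
#' @param assignments List (or vector) of per-variant code vectors.
#' @param scheme One of chromosome, cath, pfam, ec, go.
#' @param level Level label (cath: class/architecture/topology/homology;
#'   ec: "1".."4"; go: term/aspect; pfam/chromosome: single level).
#' @param distinct_per_variant Collapse duplicate categories within one
#'   variant (default TRUE).
#' @return A `category_counts`.
#' @export
level_counts <- function(assignments, scheme, level,
                         distinct_per_variant = TRUE) {
  if (!is.list(assignments)) assignments <- as.list(assignments)
  depth <- switch(scheme,
    cath = {
      if (!level %in% names(cath_level_depth)) {
        stop("unknown CATH level: ", level, call. = FALSE)
      }
      cath_level_depth[[level]]
    },
    ec = {
      if (!level %in% c("1", "2", "3", "4")) {
        stop("unknown EC level: ", level, call. = FALSE)
      }
      as.integer(level)
    },
    go = {
      if (!level %in% c("term", "aspect")) {
        stop("unknown GO level: ", level, call. = FALSE)
      }
      NA_integer_
    },
    pfam = ,
    chromosome = NA_integer_,
    stop("unknown scheme: ", scheme, call. = FALSE)
  )
  per_variant <- lapply(assignments, function(codes) {
    codes <- codes[!is.na(codes)]
    if (!is.na(depth)) codes <- truncate_codes(codes, depth)
    codes <- codes[!is.na(codes)]
    if (distinct_per_variant) codes <- unique(codes)
    codes
  })
  tab <- table(unlist(per_variant))
  category_counts(scheme, level, stats::setNames(as.integer(tab), names(tab)))
}

#' Build the proteome-wide background distribution for a scheme
#'
#' The reference against which dataset distributions are tested:
#' * `chromosome`: per-chromosome gene counts and summed CDS lengths (both
#'   weighting bases, as `$genes` and `$cds`);
#' * `cath`: one occurrence per domain on each 95%-identity cluster
#'   representative chain (the first member of each cluster), truncated to
#'   each of the four levels;
#' * `pfam`, `ec`, `go`: one occurrence per annotation row over all
#'   proteins (EC per level with incomplete codes dropping out; GO at term
#'   and aspect level).
#'
#' @param reference A [proteome_reference()].
#' @param scheme One of chromosome, cath, pfam, ec, go.
#' @return A named list of `category_counts`, one per level of the scheme.
#' @export
build_background <- function(reference, scheme = c("chromosome", "cath",
                                                   "pfam", "ec", "go")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    chromosome = {
      g <- reference$genes
      genes <- table(g$chromosome)
      cds <- tapply(g$cds_length, g$chromosome, sum)
      list(
        genes = category_counts("chromosome", "genes",
                                stats::setNames(as.numeric(genes), names(genes))),
        cds = category_counts("chromosome", "cds",
                              stats::setNames(as.numeric(cds), names(cds)))
      )
    },
    cath = {
      cl <- reference$clusters
      reps <- cl[cl$member_order == 1, , drop = FALSE]
      rep_keys <- paste0(reps$structure_id, "_", reps$chain)
      seg <- reference$cath_segments
      on_rep <- paste0(seg$structure_id, "_", seg$chain) %in% rep_keys
      # one occurrence per domain on a representative chain
      dom_ids <- unique(seg$domain_id[on_rep])
      d <- reference$cath_domains
      codes <- with(d[match(dom_ids, d$domain_id), , drop = FALSE],
                    paste(c, a, t, h, sep = "."))
      sapply(names(cath_level_depth), function(lv) {
        level_counts(as.list(codes), "cath", lv, distinct_per_variant = FALSE)
      }, simplify = FALSE)
    },
    pfam = {
      list(family = level_counts(as.list(reference$pfam$family), "pfam", "family",
                                 distinct_per_variant = FALSE))
    },
    ec = {
      sapply(c("1", "2", "3", "4"), function(lv) {
        level_counts(as.list(reference$ec$ec_code), "ec", lv,
                     distinct_per_variant = FALSE)
      }, simplify = FALSE)
    },
    go = {
      list(
        term = level_counts(as.list(reference$go$term), "go", "term",
                            distinct_per_variant = FALSE),
        aspect = level_counts(as.list(reference$go$aspect), "go", "aspect",
                              distinct_per_variant = FALSE)
      )
    })
}
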