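# Identifier resolution and residue-level structure mapping.
#
# Mapping is a strict funnel: all records >= protein_mapped >=
# structure_mapped. RefSeq/Ensembl identifiers resolve through the cross
# reference tables only when the foreign and canonical sequence lengths
# match exactly; a mapped position must fall inside the canonical protein.
# Structure selection walks candidate structures from best (lowest)
# resolution to worst, discards any structure whose residue at the variant
# position is Not_Observed, and within a structure takes the first chain
# (file order) covering the position.

#' Resolve variant records to canonical proteins
#'
#' UniProt-namespace records pass through when the accession exists in the
#' reference. RefSeq and Ensembl records map via the cross-reference tables
#' only when the foreign sequence length equals the canonical sequence
#' length; otherwise they stay unmapped. A mapped record whose position
#' exceeds the canonical protein length is unmapped. Failures are statuses,
#' never errors.
#'
#' @param records Variant record data.frame.
#' @param reference A [proteome_reference()].
#' @return `records` with `canonical_protein` and `mapping_status` updated.
#' @export
to_canonical <- function(records, reference) {
  stopifnot(inherits(reference, "proteome_reference"))
  if (!nrow(records)) return(records)
  acc <- rep(NA_character_, nrow(records))
  sel <- records$ref_namespace == "uniprot"
  acc[sel] <- ifelse(records$ref_id[sel] %in% reference$proteins$accession,
                     records$ref_id[sel], NA_character_)
  for (ns in c("refseq", "ensembl")) {
    sel <- records$ref_namespace == ns
    if (!any(sel)) next
    xr <- reference$crossrefs[reference$crossrefs$namespace == ns, , drop = FALSE]
    i <- match(records$ref_id[sel], xr$foreign_id)
    ok <- !is.na(i) & xr$foreign_length[i] == xr$canonical_length[i]
    acc[sel][ok] <- xr$canonical_id[i[ok]]
  }
  plen <- reference$proteins$length[match(acc, reference$proteins$accession)]
  acc[is.na(plen) | records$position > plen] <- NA_character_
  records$canonical_protein <- acc
  records$mapping_status <- ifelse(is.na(acc), "unmapped", "protein_mapped")
  records
}

#' Select the structure residue for a protein position
#'
#' Candidate structures are those with a chain whose mapped interval for
#' `accession` contains `position`. They are tried from the best (lowest)
#' resolution value upward; structures without a resolution sort after all
#' resolved ones, and ties break by structure identifier. Within the chosen
#' structure the first chain in mapping-file order containing the position
#' is taken, with no further checking. A structure whose residue at the
#' position is Not_Observed is discarded entirely and the next structure is
#' tried.
#'
#' @param accession Canonical protein accession (must exist).
#' @param position 1-based residue position on the protein.
#' @param reference A [proteome_reference()].
#' @return A `residue_locus` list (`structure_id`, `chain`,
#'   `struct_resnum`, `resolution`) or NULL when no candidate survives.
#' @export
select_structure_residue <- function(accession, position, reference) {
  if (!accession %in% reference$proteins$accession) {
    stop("unknown accession: ", accession, call. = FALSE)
  }
  s <- reference$structures
  cand <- s[s$accession == accession & s$sp_beg <= position & s$sp_end >= position,
            , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  # one row per structure: best = lowest resolution, NA last, tie by id
  res_by_struct <- tapply(cand$resolution, cand$structure_id,
                          function(r) if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  struct_order <- names(res_by_struct)[order(is.na(res_by_struct), res_by_struct,
                                             names(res_by_struct))]
  unobs <- reference$unobserved
  for (sid in struct_order) {
    chains <- cand[cand$structure_id == sid, , drop = FALSE]
    chains <- chains[order(chains$file_order), , drop = FALSE]
    chosen <- chains[1, ]
    hit <- nrow(unobs) > 0 && any(unobs$structure_id == sid &
                                    unobs$chain == chosen$chain &
                                    unobs$sp_pos == position)
    if (hit) next  # Not_Observed: discard the whole structure
    return(structure(list(
      structure_id = chosen$structure_id,
      chain = chosen$chain,
      struct_resnum = chosen$res_beg + (position - chosen$sp_beg),
      resolution = chosen$resolution
    ), class = "residue_locus"))
  }
  NULL
}

#' Map a variant dataset to proteins and structures, with tallies
#'
#' Runs [to_canonical()] and then structure selection for every
#' protein-mapped record, and tallies the funnel: counts and percentages
#' (denominator: all records of the dataset) mapped to a protein and to a
#' structure, per-protein variant counts, and the maximum number of
#' variants on one protein.
#'
#' @param records Variant record data.frame (one dataset).
#' @param reference A [proteome_reference()].
#' @return A list of class `mapped_dataset`: `records` (with final
#'   `mapping_status` and, for structure-mapped records, `structure_id`,
#'   `chain`, `struct_resnum` columns) and `tallies`.
#' @export
map_dataset <- function(records, reference) {
  records <- to_canonical(records, reference)
  n <- nrow(records)
  records$structure_id <- rep(NA_character_, n)
  records$chain <- rep(NA_character_, n)
  records$struct_resnum <- rep(NA_integer_, n)
  pm <- which(records$mapping_status == "protein_mapped")
  if (length(pm)) {
    key <- paste(records$canonical_protein[pm], records$position[pm])
    uniq <- !duplicated(key)
    loci <- lapply(which(uniq), function(j) {
      i <- pm[j]
      select_structure_residue(records$canonical_protein[i],
                               records$position[i], reference)
    })
    names(loci) <- key[uniq]
    for (j in seq_along(pm)) {
      locus <- loci[[key[j]]]
      if (!is.null(locus)) {
        i <- pm[j]
        records$mapping_status[i] <- "structure_mapped"
        records$structure_id[i] <- locus$structure_id
        records$chain[i] <- locus$chain
        records$struct_resnum[i] <- locus$struct_resnum
      }
    }
  }
  n_protein <- sum(records$mapping_status %in% c("protein_mapped", "structure_mapped"))
  n_structure <- sum(records$mapping_status == "structure_mapped")
  per_protein <- table(records$canonical_protein[!is.na(records$canonical_protein)])
  max_per_protein <- if (length(per_protein)) max(per_protein) else 0L
  max_accession <- if (length(per_protein)) {
    names(per_protein)[which.max(per_protein)]
  } else NULL
  structure(list(
    records = records,
    tallies = list(
      n_total = n,
      n_protein_mapped = n_protein,
      pct_protein_mapped = percent_of(n_protein, n),
      n_structure_mapped = n_structure,
      pct_structure_mapped = percent_of(n_structure, n),
      per_protein = per_protein,
      max_per_protein = as.integer(max_per_protein),
      max_accession = max_accession
    )
  ), class = "mapped_dataset")
}
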