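# Shared fixtures, all built in code. The default synthetic universe is
# cached per session because several files exercise it.

.fixtures <- new.env(parent = emptyenv())

fixture_proteome <- function(seed = 7) {
  key <- paste0("proteome_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_proteome(proteome_config(seed = seed))
  }
  .fixtures[[key]]
}

# A hand-built micro-universe with known structures for mapping oracles:
#  PA (200 aa, chr1): S1 1.50 A covering 10..150 (res offset +5, pos 50
#      unobserved), S2 2.50 A covering 40..160, S3 no resolution 1..200.
#  PB (300 aa, chrX): no structures.
# Crossrefs: NP_A -> PA (lengths match), NP_B -> PB (length off by one),
# ENS_A -> PA (match).
tiny_mapping_reference <- function() {
  genes <- data.frame(gene_id = c("G1", "G2"), chromosome = c("1", "X"),
                      cds_length = c(603, 903), stringsAsFactors = FALSE)
  proteins <- data.frame(accession = c("PA", "PB"), length = c(200L, 300L),
                         gene_id = c("G1", "G2"), stringsAsFactors = FALSE)
  crossrefs <- data.frame(
    namespace = c("refseq", "refseq", "ensembl"),
    foreign_id = c("NP_A", "NP_B", "ENS_A"),
    canonical_id = c("PA", "PB", "PA"),
    foreign_length = c(200L, 299L, 200L),
    canonical_length = c(200L, 300L, 200L),
    stringsAsFactors = FALSE)
  structures <- data.frame(
    structure_id = c("S1", "S2", "S3"), chain = "A", accession = "PA",
    sp_beg = c(10L, 40L, 1L), sp_end = c(150L, 160L, 200L),
    res_beg = c(15L, 40L, 1L),
    resolution = c(1.5, 2.5, NA), file_order = 1:3,
    stringsAsFactors = FALSE)
  unobserved <- data.frame(structure_id = "S1", chain = "A", sp_pos = 50L,
                           stringsAsFactors = FALSE)
  cath_domains <- data.frame(domain_id = c("D1", "D2"),
                             c = c(1L, 2L), a = c(10L, 60L),
                             t = c(8L, 40L), h = c(10L, 10L),
                             stringsAsFactors = FALSE)
  # S1 chain A (structure numbering 15..155): D1 = 15..80, D2 = 90..155
  cath_segments <- data.frame(domain_id = c("D1", "D2"),
                              structure_id = "S1", chain = "A",
                              seg_start = c(15L, 90L), seg_end = c(80L, 155L),
                              stringsAsFactors = FALSE)
  pfam <- data.frame(accession = c("PA", "PA", "PB"),
                     family = c("PF1", "PF2", "PF3"),
                     start = c(20L, 100L, 5L), end = c(120L, 140L, 60L),
                     stringsAsFactors = FALSE)
  ec <- data.frame(accession = c("PA", "PA"),
                   ec_code = c("1.1.1.1", "2.7.11"), stringsAsFactors = FALSE)
  go <- data.frame(accession = c("PA", "PA", "PB"),
                   term = c("GO:1", "GO:2", "GO:1"),
                   aspect = c("MF", "BP", "MF"), stringsAsFactors = FALSE)
  clusters <- data.frame(cluster_id = c("C1", "C1", "C2"),
                         structure_id = c("S1", "S2", "S3"), chain = "A",
                         member_order = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  proteome_reference(genes = genes, proteins = proteins, crossrefs = crossrefs,
                     structures = structures, unobserved = unobserved,
                     cath_domains = cath_domains, cath_segments = cath_segments,
                     pfam = pfam, ec = ec, go = go, clusters = clusters)
}

variant_row <- function(ns, id, pos, ref = "A", alt = "V", chrom = NA_character_) {
  data.frame(dataset_label = "test", ref_namespace = ns, ref_id = id,
             position = as.integer(pos), ref_aa = ref, alt_aa = alt,
             chromosome = chrom, gene = NA_character_,
             canonical_protein = NA_character_, mapping_status = "unmapped",
             stringsAsFactors = FALSE)
}

# Independent enumeration oracle for the minimum-likelihood two-tailed
# binomial p-value: sum the probabilities of all n+1 outcomes whose mass
# does not exceed the mass at k (relative slack 1 + 1e-7).
enum_binom_p <- function(k, n, p0) {
  mass <- stats::dbinom(0:n, n, p0)
  sum(mass[mass <= mass[k + 1] * (1 + 1e-7)])
}

# Brute-force structure selection: enumerate every (structure, chain)
# mapping row under the stated ordering and discard rules.
brute_select <- function(accession, position, reference) {
  s <- reference$structures
  cand <- s[s$accession == accession & s$sp_beg <= position &
              s$sp_end >= position, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  res <- tapply(cand$resolution, cand$structure_id,
                function(r) if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  for (sid in names(res)[order(is.na(res), res, names(res))]) {
    ch <- cand[cand$structure_id == sid, , drop = FALSE]
    ch <- ch[order(ch$file_order), , drop = FALSE][1, ]
    u <- reference$unobserved
    if (nrow(u) && any(u$structure_id == sid & u$chain == ch$chain &
                       u$sp_pos == position)) next
    return(list(structure_id = sid, chain = ch$chain,
                struct_resnum = ch$res_beg + (position - ch$sp_beg)))
  }
  NULL
}
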