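# Synthetic annotation universe.
#
# Generates a miniature but complete human-proteome stand-in: genes on 24
# chromosomes, one canonical protein per gene, RefSeq/Ensembl cross
# references, partial structure coverage with unobserved residues and
# resolutions, a 4-level CATH hierarchy, Pfam intervals, possibly
# incomplete EC codes, GO terms in three aspects, 95%-identity chain
# clusters, and variant datasets drawn either uniformly over residues or
# concentrated on hotspot proteins. Everything downstream (mapping,
# annotation, statistics, reports) is exercised against these universes.

#' Configuration of the synthetic proteome universe
#'
#' Defaults describe a miniature human-like universe: 300 genes
#' apportioned over chromosomes 1-22, X, Y proportionally to the human
#' per-chromosome protein-coding gene counts; CDS lengths log-normal
#' (median ~1340 nt); 40% of proteins with at least one structure; a CATH
#' hierarchy of 4 classes / 10 architectures / 25 topologies / 40
#' superfamilies (the human proteome has 4/30/508/907); 21% of proteins
#' enzymes, with 20% of EC codes lacking their deepest level(s); GO terms
#' in the three aspects MF/BP/CC.
#'
#' @param n_chromosomes Number of chromosomes (default 24).
#' @param chromosome_labels Labels, default `c(1:22, "X", "Y")`.
#' @param n_genes Total genes apportioned over chromosomes when
#'   `genes_per_chromosome` is not given.
#' @param genes_per_chromosome Integer vector of length `n_chromosomes`;
#'   default apportions `n_genes` by the human gene-count weights
#'   (largest-remainder method).
#' @param cds_meanlog,cds_sdlog Log-normal parameters of CDS length in
#'   nucleotides.
#' @param protein_count Number of proteins (first `protein_count` genes
#'   carry one canonical protein each); default all genes.
#' @param structure_coverage_fraction Fraction of proteins with >= 1
#'   structure.
#' @param unobserved_residue_rate Per-residue probability that a mapped
#'   structure residue is Not_Observed.
#' @param n_cath_classes,n_cath_architectures,n_cath_topologies,n_cath_superfamilies
#'   Sizes of the CATH hierarchy levels.
#' @param n_pfam_families Number of Pfam families.
#' @param enzyme_fraction Fraction of proteins carrying EC codes.
#' @param ec_incomplete_rate Probability an EC code lacks its 4th (and
#'   possibly 3rd) level.
#' @param go_terms_total Number of distinct GO terms.
#' @param go_aspect_labels Exactly 3 distinct aspect labels.
#' @param crossref_mismatch_rate Fraction of cross-reference rows whose
#'   foreign sequence length disagrees with the canonical length
#'   (exercises the length-match mapping rule).
#' @param seed Integer seed; every generator operation derives its own
#'   independent stream from it.
#' @return A validated list of class `proteome_config`.
#' @export
proteome_config <- function(n_chromosomes = 24,
                            chromosome_labels = c(as.character(1:22), "X", "Y"),
                            n_genes = 300,
                            genes_per_chromosome = NULL,
                            cds_meanlog = 7.2,
                            cds_sdlog = 0.55,
                            protein_count = NULL,
                            structure_coverage_fraction = 0.4,
                            unobserved_residue_rate = 0.05,
                            n_cath_classes = 4,
                            n_cath_architectures = 10,
                            n_cath_topologies = 25,
                            n_cath_superfamilies = 40,
                            n_pfam_families = 60,
                            enzyme_fraction = 0.21,
                            ec_incomplete_rate = 0.2,
                            go_terms_total = 150,
                            go_aspect_labels = c("MF", "BP", "CC"),
                            crossref_mismatch_rate = 0.02,
                            seed = 1L) {
  if (length(chromosome_labels) != n_chromosomes ||
      anyDuplicated(chromosome_labels)) {
    stop_param("chromosome_labels", "must be n_chromosomes distinct labels")
  }
  if (is.null(genes_per_chromosome)) {
    if (n_genes < 0) stop_param("n_genes", "must be >= 0")
    w <- human_gene_weights()
    if (n_chromosomes != length(w)) {
      w <- rep(1, n_chromosomes)  # non-human universe: equal weights
    }
    genes_per_chromosome <- apportion(n_genes, w)
  }
  if (length(genes_per_chromosome) != n_chromosomes) {
    stop_param("genes_per_chromosome", "length must equal n_chromosomes")
  }
  if (any(genes_per_chromosome < 0)) {
    stop_param("genes_per_chromosome", "all counts must be >= 0")
  }
  for (p in c("structure_coverage_fraction", "unobserved_residue_rate",
              "enzyme_fraction", "ec_incomplete_rate", "crossref_mismatch_rate")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop_param(p, "must be a fraction in [0, 1]")
    }
  }
  for (p in c("n_cath_classes", "n_cath_architectures", "n_cath_topologies",
              "n_cath_superfamilies", "n_pfam_families", "go_terms_total")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1 || v < 0) stop_param(p, "must be a count >= 0")
  }
  if (n_cath_classes > n_cath_architectures ||
      n_cath_architectures > n_cath_topologies ||
      n_cath_topologies > n_cath_superfamilies) {
    stop_param("n_cath_classes", "hierarchy sizes must be non-decreasing with depth")
  }
  if (length(unique(go_aspect_labels)) != 3) {
    stop_param("go_aspect_labels", "must be exactly 3 distinct labels")
  }
  protein_count <- protein_count %||% sum(genes_per_chromosome)
  if (protein_count < 0 || protein_count > sum(genes_per_chromosome)) {
    stop_param("protein_count", "must be between 0 and the total gene count")
  }
  if (cds_sdlog <= 0) stop_param("cds_sdlog", "must be > 0")
  structure(list(
    n_chromosomes = n_chromosomes,
    chromosome_labels = as.character(chromosome_labels),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    cds_meanlog = cds_meanlog, cds_sdlog = cds_sdlog,
    protein_count = as.integer(protein_count),
    structure_coverage_fraction = structure_coverage_fraction,
    unobserved_residue_rate = unobserved_residue_rate,
    n_cath_classes = as.integer(n_cath_classes),
    n_cath_architectures = as.integer(n_cath_architectures),
    n_cath_topologies = as.integer(n_cath_topologies),
    n_cath_superfamilies = as.integer(n_cath_superfamilies),
    n_pfam_families = as.integer(n_pfam_families),
    enzyme_fraction = enzyme_fraction,
    ec_incomplete_rate = ec_incomplete_rate,
    go_terms_total = as.integer(go_terms_total),
    go_aspect_labels = as.character(go_aspect_labels),
    crossref_mismatch_rate = crossref_mismatch_rate,
    seed = as.integer(seed)
  ), class = "proteome_config")
}

# Human per-chromosome protein-coding gene counts (Ensembl Biomart, GRCh38;
# 19,786 genes total) - the default apportionment weights.
human_gene_weights <- function() {
  c(2037, 1238, 1071, 745, 882, 1035, 901, 668, 770, 727, 1278, 1033,
    324, 614, 589, 858, 1184, 268, 1467, 540, 233, 439, 840, 45)
}

# Largest-remainder apportionment of `total` items over weights `w`.
apportion <- function(total, w) {
  if (total == 0) return(integer(length(w)))
  q <- total * w / sum(w)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Independent substream per generator component: reseeds deterministically
# from (seed, stream index) so adding one component never perturbs another.
with_stream <- function(seed, stream, code) {
  withr::with_seed((as.integer(seed) + 7919L * as.integer(stream)) %% 2147483629L,
                   code)
}

#' Generate a synthetic proteome annotation universe
#'
#' Deterministic for a fixed `config` (including its seed). Every protein
#' has a gene with a chromosome and CDS length; protein length is
#' `floor(CDS/3) - 1` residues (floored at 30). A
#' `structure_coverage_fraction` subset of proteins carries 1-3 structure
#' chain mappings with resolutions (occasionally absent, NMR-like),
#' per-residue Not_Observed flags, and CATH domain segments drawn from a
#' generated 4-level hierarchy. Pfam intervals lie within protein bounds
#' and never tile a whole sequence; EC codes attach only to the enzyme
#' subset (some incomplete); every protein has at least one GO term, each
#' term belonging to exactly one aspect; 95%-identity clusters partition
#' the structure chains (chains of the same protein cluster together).
#'
#' @param config A [proteome_config()].
#' @return A [proteome_reference()].
#' @export
generate_proteome <- function(config = proteome_config()) {
  stopifnot(inherits(config, "proteome_config"))
  n_gene_total <- sum(config$genes_per_chromosome)
  if (n_gene_total == 0 || config$protein_count == 0) {
    return(proteome_reference())
  }

  genes <- data.frame(
    gene_id = sprintf("GENE%05d", seq_len(n_gene_total)),
    chromosome = rep(config$chromosome_labels, config$genes_per_chromosome),
    cds_length = NA_real_,
    stringsAsFactors = FALSE
  )
  genes$cds_length <- with_stream(config$seed, 1, {
    # CDS in nt, multiple of 3, floor keeps protein length >= 30
    cds <- 3 * pmax(31, round(stats::rlnorm(n_gene_total, config$cds_meanlog,
                                            config$cds_sdlog) / 3))
    as.numeric(cds)
  })

  prot_idx <- seq_len(config$protein_count)
  proteins <- data.frame(
    accession = sprintf("P%05d", prot_idx),
    length = as.integer(pmax(30, floor(genes$cds_length[prot_idx] / 3) - 1)),
    gene_id = genes$gene_id[prot_idx],
    stringsAsFactors = FALSE
  )
  n_prot <- nrow(proteins)

  crossrefs <- with_stream(config$seed, 2, {
    mk <- function(ns, fmt) {
      foreign_length <- proteins$length
      off <- stats::rbinom(n_prot, 1, config$crossref_mismatch_rate) *
        sample(c(-2L, -1L, 1L, 2L), n_prot, replace = TRUE)
      data.frame(namespace = ns,
                 foreign_id = sprintf(fmt, prot_idx),
                 canonical_id = proteins$accession,
                 foreign_length = as.integer(foreign_length + off),
                 canonical_length = proteins$length,
                 stringsAsFactors = FALSE)
    }
    rbind(mk("refseq", "NP_%06d"), mk("ensembl", "ENSP%08d"))
  })

  cath <- with_stream(config$seed, 3, make_cath_hierarchy(config))

  str_parts <- with_stream(config$seed, 4, {
    n_cov <- round(config$structure_coverage_fraction * n_prot)
    covered <- sort(sample.int(n_prot, n_cov))
    structures <- list(); unobserved <- list(); seg_rows <- list(); dom_rows <- list()
    file_order <- 0L; sid <- 0L; dom_n <- 0L
    sf_codes <- cath$codes
    sf_weights <- if (length(sf_codes)) 1 / seq_along(sf_codes) else numeric(0)
    for (i in covered) {
      len <- proteins$length[i]
      for (k in seq_len(sample(1:3, 1, prob = c(0.6, 0.3, 0.1)))) {
        sid <- sid + 1L
        structure_id <- sprintf("S%03X", sid)
        if (k == 1L) {
          # the first structure of a covered protein spans the whole chain,
          # so full coverage + zero unobserved rate maps every residue;
          # additional structures cover partial runs as real PDB entries do
          cover_len <- len
        } else {
          cover_len <- max(25L, min(len, round(len * stats::runif(1, 0.35, 1))))
        }
        sp_beg <- sample.int(len - cover_len + 1L, 1)
        sp_end <- sp_beg + cover_len - 1L
        res_beg <- sp_beg + sample(-5:20, 1)
        resolution <- if (stats::runif(1) < 0.1) NA_real_ else round(stats::runif(1, 1, 3.5), 2)
        chains <- if (stats::runif(1) < 0.15) c("A", "B") else "A"
        for (ch in chains) {
          file_order <- file_order + 1L
          structures[[file_order]] <- data.frame(
            structure_id = structure_id, chain = ch,
            accession = proteins$accession[i],
            sp_beg = sp_beg, sp_end = sp_end, res_beg = res_beg,
            resolution = resolution, file_order = file_order,
            stringsAsFactors = FALSE)
          miss <- which(stats::runif(cover_len) < config$unobserved_residue_rate)
          if (length(miss)) {
            unobserved[[length(unobserved) + 1L]] <- data.frame(
              structure_id = structure_id, chain = ch,
              sp_pos = sp_beg + miss - 1L, stringsAsFactors = FALSE)
          }
          if (length(sf_codes)) {
            # split the covered run into 1-2 CATH domains with a gap between
            res_end <- res_beg + cover_len - 1L
            n_dom <- if (cover_len >= 80 && stats::runif(1) < 0.4) 2L else 1L
            cuts <- if (n_dom == 2L) {
              mid <- res_beg + cover_len %/% 2
              gap <- sample(1:5, 1)
              list(c(res_beg, mid - gap), c(mid + 1L, res_end))
            } else {
              trim <- sample(0:3, 2, replace = TRUE)
              list(c(res_beg + trim[1], res_end - trim[2]))
            }
            for (cut in cuts) {
              dom_n <- dom_n + 1L
              code_i <- sample.int(length(sf_codes), 1, prob = sf_weights)
              dom_rows[[dom_n]] <- data.frame(
                domain_id = sprintf("D%05d", dom_n),
                c = cath$c[code_i], a = cath$a[code_i],
                t = cath$t[code_i], h = cath$h[code_i],
                stringsAsFactors = FALSE)
              seg_rows[[dom_n]] <- data.frame(
                domain_id = sprintf("D%05d", dom_n),
                structure_id = structure_id, chain = ch,
                seg_start = cut[1], seg_end = cut[2],
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    list(structures = do.call(rbind, structures),
         unobserved = if (length(unobserved)) do.call(rbind, unobserved) else NULL,
         cath_domains = if (length(dom_rows)) do.call(rbind, dom_rows) else NULL,
         cath_segments = if (length(seg_rows)) do.call(rbind, seg_rows) else NULL)
  })

  clusters <- NULL
  if (!is.null(str_parts$structures)) {
    s <- str_parts$structures
    grp <- match(s$accession, unique(s$accession))  # same-protein chains cluster
    ord <- stats::ave(seq_len(nrow(s)), grp, FUN = seq_along)
    clusters <- data.frame(cluster_id = sprintf("CL%04d", grp),
                           structure_id = s$structure_id, chain = s$chain,
                           member_order = as.integer(ord),
                           stringsAsFactors = FALSE)
  }

  pfam <- with_stream(config$seed, 5, {
    if (config$n_pfam_families == 0) return(NULL)
    fam_ids <- sprintf("PF%05d", seq_len(config$n_pfam_families))
    fam_w <- 1 / seq_len(config$n_pfam_families)
    rows <- list()
    for (i in seq_len(n_prot)) {
      k <- sample(0:3, 1, prob = c(0.15, 0.45, 0.3, 0.1))
      if (k == 0) next
      len <- proteins$length[i]
      for (j in seq_len(k)) {
        w <- max(10L, round(len * stats::runif(1, 0.1, 0.35)))
        w <- min(w, len - 1L)  # a single domain never tiles the sequence
        st <- sample.int(len - w, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          accession = proteins$accession[i],
          family = sample(fam_ids, 1, prob = fam_w),
          start = st, end = st + w - 1L, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  ec <- with_stream(config$seed, 6, {
    is_enzyme <- stats::runif(n_prot) < config$enzyme_fraction
    if (!any(is_enzyme)) return(NULL)
    rows <- list()
    for (i in which(is_enzyme)) {
      for (j in seq_len(1 + (stats::runif(1) < 0.1))) {
        lv <- c(sample.int(6, 1), sample.int(8, 1), sample.int(12, 1),
                sample.int(50, 1))
        depth <- if (stats::runif(1) < config$ec_incomplete_rate) {
          sample(2:3, 1, prob = c(0.3, 0.7))
        } else 4L
        rows[[length(rows) + 1L]] <- data.frame(
          accession = proteins$accession[i],
          ec_code = paste(lv[seq_len(depth)], collapse = "."),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  go <- with_stream(config$seed, 7, {
    n_terms <- max(3L, config$go_terms_total)
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    aspect_of <- c(config$go_aspect_labels,  # each aspect populated
                   sample(config$go_aspect_labels, n_terms - 3, replace = TRUE))
    term_w <- 1 / seq_len(n_terms)
    rows <- lapply(seq_len(n_prot), function(i) {
      k <- min(n_terms, 1 + stats::rpois(1, 3))
      t_i <- sample.int(n_terms, k, prob = term_w)
      data.frame(accession = proteins$accession[i], term = terms[t_i],
                 aspect = aspect_of[t_i], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  proteome_reference(
    genes = genes, proteins = proteins, crossrefs = crossrefs,
    structures = str_parts$structures, unobserved = str_parts$unobserved,
    cath_domains = str_parts$cath_domains, cath_segments = str_parts$cath_segments,
    pfam = pfam, ec = ec, go = go, clusters = clusters
  )
}

# Random 4-level hierarchy: every architecture has a class, every topology
# an architecture, every superfamily a topology; the first members of each
# level guarantee every parent is used.
make_cath_hierarchy <- function(config) {
  n_c <- config$n_cath_classes; n_a <- config$n_cath_architectures
  n_t <- config$n_cath_topologies; n_h <- config$n_cath_superfamilies
  if (n_h == 0) return(list(codes = character(0)))
  pick_parent <- function(n_child, n_parent) {
    c(seq_len(min(n_parent, n_child)),
      if (n_child > n_parent) sample.int(n_parent, n_child - n_parent, replace = TRUE))
  }
  a_class <- pick_parent(n_a, n_c)
  t_arch <- pick_parent(n_t, n_a)
  h_topo <- pick_parent(n_h, n_t)
  h <- seq_len(n_h)
  t <- h_topo
  a <- t_arch[t]
  cl <- a_class[a]
  list(codes = paste(cl, a, t, h, sep = "."), c = cl, a = a, t = t, h = h)
}

#' Sampling specification for synthetic variant datasets
#'
#' `mode = "uniform"` draws residues uniformly over all residues of all
#' proteins (an unbiased dataset). `mode = "hotspot"` first draws a protein
#' with probability proportional to `rank^-hotspot_concentration` (rank in
#' registry order) and then a residue uniformly within it, emulating the
#' extreme over-study of disease genes (a handful of proteins absorbing
#' thousands of variants).
#'
#' @param mode "uniform" or "hotspot".
#' @param n_variants Number of variant records to draw (>= 1).
#' @param hotspot_concentration Zipf exponent >= 0; 0 is uniform over
#'   proteins.
#' @param pathogenic_label Logical tag carried in the dataset label.
#' @param namespace_weights Sampling weights for the reference namespace of
#'   each record, named refseq/ensembl/uniprot.
#' @param dataset_label Label stamped on every record.
#' @param seed Integer seed.
#' @return A list of class `sampling_spec`.
#' @export
sampling_spec <- function(mode = c("uniform", "hotspot"), n_variants = 1000,
                          hotspot_concentration = 0, pathogenic_label = FALSE,
                          namespace_weights = c(refseq = 0.25, ensembl = 0.25,
                                                uniprot = 0.5),
                          dataset_label = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(n_variants) || n_variants < 1) {
    stop_param("n_variants", "must be >= 1")
  }
  if (!is.numeric(hotspot_concentration) || hotspot_concentration < 0) {
    stop_param("hotspot_concentration", "must be >= 0")
  }
  if (!all(c("refseq", "ensembl", "uniprot") %in% names(namespace_weights)) ||
      any(namespace_weights < 0) || sum(namespace_weights) <= 0) {
    stop_param("namespace_weights", "need non-negative refseq/ensembl/uniprot weights")
  }
  structure(list(
    mode = mode, n_variants = as.integer(n_variants),
    hotspot_concentration = hotspot_concentration,
    pathogenic_label = isTRUE(pathogenic_label),
    namespace_weights = namespace_weights[c("refseq", "ensembl", "uniprot")],
    dataset_label = dataset_label %||%
      paste0(mode, if (isTRUE(pathogenic_label)) "_pathogenic" else "_neutral"),
    seed = as.integer(seed)
  ), class = "sampling_spec")
}

#' Draw a synthetic variant dataset from a proteome
#'
#' Produces a variant record table (see [read_variant_table()] for the
#' column contract) whose identifiers refer to the given proteome through
#' the namespace chosen per record. Deterministic for a fixed spec.
#'
#' @param proteome A non-empty [proteome_reference()].
#' @param spec A [sampling_spec()].
#' @return data.frame of variant records.
#' @export
generate_variant_dataset <- function(proteome, spec) {
  stopifnot(inherits(proteome, "proteome_reference"), inherits(spec, "sampling_spec"))
  n_prot <- nrow(proteome$proteins)
  if (n_prot == 0) stop("cannot sample variants from an empty proteome", call. = FALSE)
  aa <- amino_acids()
  with_stream(spec$seed, 11, {
    prob <- switch(spec$mode,
      uniform = proteome$proteins$length / sum(proteome$proteins$length),
      hotspot = {
        p <- seq_len(n_prot)^(-spec$hotspot_concentration)
        p / sum(p)
      })
    pi <- sample.int(n_prot, spec$n_variants, replace = TRUE, prob = prob)
    len <- proteome$proteins$length[pi]
    pos <- 1L + floor(stats::runif(spec$n_variants) * len)
    ref_aa <- sample(aa, spec$n_variants, replace = TRUE)
    # alternate residue drawn from the 19 others
    shift <- sample.int(19L, spec$n_variants, replace = TRUE)
    alt_aa <- aa[(match(ref_aa, aa) - 1L + shift) %% 20L + 1L]
    ns <- sample(names(spec$namespace_weights), spec$n_variants, replace = TRUE,
                 prob = spec$namespace_weights)
    acc <- proteome$proteins$accession[pi]
    ref_id <- acc
    for (foreign in c("refseq", "ensembl")) {
      sel <- ns == foreign
      if (any(sel)) {
        xr <- proteome$crossrefs[proteome$crossrefs$namespace == foreign, ]
        ref_id[sel] <- xr$foreign_id[match(acc[sel], xr$canonical_id)]
      }
    }
    gene <- proteome$proteins$gene_id[pi]
    chrom <- proteome$genes$chromosome[match(gene, proteome$genes$gene_id)]
    data.frame(
      dataset_label = spec$dataset_label,
      ref_namespace = ns, ref_id = ref_id,
      position = as.integer(pos), ref_aa = ref_aa, alt_aa = alt_aa,
      chromosome = chrom, gene = gene,
      canonical_protein = NA_character_, mapping_status = "unmapped",
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic allele-frequency table
#'
#' Emulates an ExAC-style table of protein substitutions with per-population
#' minor allele frequencies (MAFs) in `[0, 0.5]`. A `fraction_in_window`
#' share of entries has at least one population MAF strictly inside
#' `(0.01, 0.25)` - the window of the benign-contamination screen; the
#' remaining entries lie entirely outside it.
#'
#' @param proteome A non-empty [proteome_reference()].
#' @param n_entries Number of entries.
#' @param n_populations Number of geographical populations (default 7).
#' @param fraction_in_window Fraction of entries inside the benign window.
#' @param seed Integer seed.
#' @return data.frame of class `frequency_table` with columns `accession`,
#'   `position`, `ref_aa`, `alt_aa`, `maf_1` ... `maf_K`.
#' @export
generate_frequency_table <- function(proteome, n_entries = 500,
                                     n_populations = 7,
                                     fraction_in_window = 0.6, seed = 1L) {
  stopifnot(inherits(proteome, "proteome_reference"))
  if (!is.numeric(n_populations) || n_populations < 1) {
    stop_param("n_populations", "must be >= 1")
  }
  if (fraction_in_window < 0 || fraction_in_window > 1) {
    stop_param("fraction_in_window", "must be in [0, 1]")
  }
  cols <- sprintf("maf_%d", seq_len(n_populations))
  if (n_entries == 0 || nrow(proteome$proteins) == 0) {
    out <- cbind(data.frame(accession = character(0), position = integer(0),
                            ref_aa = character(0), alt_aa = character(0),
                            stringsAsFactors = FALSE),
                 stats::setNames(as.data.frame(rep(list(numeric(0)), n_populations)),
                                 cols))
    class(out) <- c("frequency_table", "data.frame")
    return(out)
  }
  aa <- amino_acids()
  with_stream(seed, 13, {
    n_prot <- nrow(proteome$proteins)
    pi <- sample.int(n_prot, n_entries, replace = TRUE,
                     prob = proteome$proteins$length)
    pos <- 1L + floor(stats::runif(n_entries) * proteome$proteins$length[pi])
    ref_aa <- sample(aa, n_entries, replace = TRUE)
    shift <- sample.int(19L, n_entries, replace = TRUE)
    alt_aa <- aa[(match(ref_aa, aa) - 1L + shift) %% 20L + 1L]
    in_window <- stats::runif(n_entries) < fraction_in_window
    maf <- matrix(0, n_entries, n_populations, dimnames = list(NULL, cols))
    for (j in seq_len(n_populations)) {
      # rare by default; occasionally common (>= 0.25), never inside the window
      maf[, j] <- ifelse(stats::runif(n_entries) < 0.9,
                         stats::runif(n_entries, 0, 0.01),
                         stats::runif(n_entries, 0.25, 0.5))
    }
    if (any(in_window)) {
      jpop <- sample.int(n_populations, sum(in_window), replace = TRUE)
      maf[cbind(which(in_window), jpop)] <- stats::runif(sum(in_window), 0.011, 0.249)
    }
    out <- cbind(data.frame(accession = proteome$proteins$accession[pi],
                            position = as.integer(pos),
                            ref_aa = ref_aa, alt_aa = alt_aa,
                            stringsAsFactors = FALSE),
                 as.data.frame(maf))
    class(out) <- c("frequency_table", "data.frame")
    out
  })
}
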