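# Category projection: CATH/Pfam/EC/GO assignment, level counts, backgrounds.

test_that("chromosome counts are additive and fall back to the gene lookup", {
  a <- rbind(variant_row("uniprot", "PA", 1, chrom = "X"),
             variant_row("uniprot", "PA", 2, chrom = "X"))
  b <- rbind(variant_row("uniprot", "PA", 3, chrom = "1"),
             variant_row("uniprot", "PA", 4, chrom = NA))
  ca <- chromosome_counts(a)
  expect_equal(as.numeric(ca$counts["X"]), 2)
  expect_equal(ca$total_assigned, 2)
  cab <- chromosome_counts(rbind(a, b))  # additivity over concatenation
  expect_equal(as.numeric(cab$counts[c("1", "X")]), c(1, 2))
  expect_equal(cab$total_assigned, 3)
  # lookup via canonical protein and gene when the label is missing
  ref <- tiny_mapping_reference()
  r <- to_canonical(variant_row("uniprot", "PB", 10), ref)
  r$chromosome <- NA_character_
  expect_equal(names(chromosome_counts(r, ref)$counts), "X")
})

test_that("CATH assignment is the unique containing segment, brute-force checked", {
  ref <- tiny_mapping_reference()
  locus <- select_structure_residue("PA", 20, ref)  # residue 25 on S1
  expect_equal(assign_cath(locus, ref), "1.10.8.10")
  # inter-domain gap (structure residues 81..89) yields no code
  gap <- structure(list(structure_id = "S1", chain = "A", struct_resnum = 85,
                        resolution = 1.5), class = "residue_locus")
  expect_true(is.na(assign_cath(gap, ref)))
  # overlapping segments are a corrupt reference
  broken <- ref
  broken$cath_segments$seg_start[2] <- 70L
  lo <- structure(list(structure_id = "S1", chain = "A", struct_resnum = 75,
                       resolution = 1.5), class = "residue_locus")
  expect_error(assign_cath(lo, broken), "overlapping")

  # a 5-domain chain: every residue agrees with an interval scan
  segs <- data.frame(domain_id = sprintf("D%d", 1:5), structure_id = "S3",
                     chain = "A", seg_start = c(1L, 30L, 80L, 120L, 171L),
                     seg_end = c(25L, 70L, 110L, 160L, 200L))
  doms <- data.frame(domain_id = sprintf("D%d", 1:5), c = 1:5, a = 1:5,
                     t = 1:5, h = 1:5)
  ref5 <- tiny_mapping_reference()
  ref5$cath_domains <- doms
  ref5$cath_segments <- segs
  for (res in seq(1, 200, by = 7)) {
    lo <- structure(list(structure_id = "S3", chain = "A", struct_resnum = res,
                         resolution = NA), class = "residue_locus")
    hits <- which(segs$seg_start <= res & segs$seg_end >= res)
    want <- if (length(hits)) paste(rep(hits, 4), collapse = ".") else NA_character_
    expect_equal(assign_cath(lo, ref5), want)
  }
})

test_that("Pfam assignment returns every containing interval", {
  ref <- tiny_mapping_reference()
  rec <- list(canonical_protein = "PA", position = 110)  # PF1 and PF2 overlap
  expect_setequal(assign_pfam(rec, ref), c("PF1", "PF2"))
  expect_equal(assign_pfam(list(canonical_protein = "PA", position = 150), ref),
               character(0))
  expect_equal(assign_pfam(list(canonical_protein = "PA", position = 50), ref),
               "PF1")
  # brute force over all positions of PA
  p <- ref$pfam[ref$pfam$accession == "PA", ]
  for (pos in seq(1, 200, by = 11)) {
    want <- p$family[p$start <= pos & p$end >= pos]
    expect_setequal(assign_pfam(list(canonical_protein = "PA", position = pos),
                                ref), want)
  }
})

test_that("functional lookup is protein-level and preserves EC depth", {
  ref <- tiny_mapping_reference()
  rec <- list(canonical_protein = "PA", position = 3)
  expect_setequal(assign_function(rec, ref, "ec"), c("1.1.1.1", "2.7.11"))
  expect_equal(assign_function(list(canonical_protein = "PB", position = 1),
                               ref, "ec"), character(0))
  g <- assign_function(rec, ref, "go")
  expect_equal(nrow(g), 2)
  expect_setequal(g$aspect, c("MF", "BP"))
})

test_that("level counts truncate codes and exclude incomplete classifications", {
  cc <- level_counts(list("1.10.8.10", "1.10.8.10", "2.60.40.10"),
                     "cath", "class")
  expect_equal(as.numeric(cc$counts[c("1", "2")]), c(2, 1))
  expect_equal(cc$total_assigned, 3)
  # the incomplete EC code exists at level 3 but not at level 4
  l4 <- level_counts(list("1.1.1.1", "1.1.1"), "ec", "4")
  expect_equal(names(l4$counts), "1.1.1.1")
  expect_equal(l4$total_assigned, 1)
  l3 <- level_counts(list("1.1.1.1", "1.1.1"), "ec", "3")
  expect_equal(as.numeric(l3$counts["1.1.1"]), 2)
  # multiplicity policy: one count per distinct category per variant
  multi <- level_counts(list(c("PF1", "PF1", "PF2")), "pfam", "family")
  expect_equal(as.numeric(multi$counts[c("PF1", "PF2")]), c(1, 1))
  multi2 <- level_counts(list(c("PF1", "PF1", "PF2")), "pfam", "family",
                         distinct_per_variant = FALSE)
  expect_equal(as.numeric(multi2$counts["PF1"]), 2)
  expect_error(level_counts(list("1.2"), "ec", "5"), "unknown EC level")
  expect_error(level_counts(list("x"), "cath", "domain"), "unknown CATH level")
})

test_that("level counts equal brute-force truncate-and-tally on random codes", {
  withr::with_seed(41, {
    codes <- replicate(200, paste(sample(1:4, 1), sample(1:20, 1),
                                  sample(1:50, 1), sample(1:200, 1), sep = "."),
                       simplify = TRUE)
  })
  assignments <- as.list(codes)
  for (lv in c("class", "architecture", "topology", "homology")) {
    depth <- c(class = 1, architecture = 2, topology = 3, homology = 4)[[lv]]
    trunc <- vapply(strsplit(codes, ".", fixed = TRUE),
                    function(p) paste(p[seq_len(depth)], collapse = "."), "")
    want <- table(trunc)
    got <- level_counts(assignments, "cath", lv)
    expect_equal(as.numeric(got$counts[names(want)]), as.numeric(want))
    expect_equal(got$total_assigned, 200)
  }
})

test_that("EC totals shrink with depth while CATH totals are level-invariant", {
  ref <- fixture_proteome()
  ec_totals <- vapply(c("1", "2", "3", "4"), function(lv) {
    level_counts(as.list(ref$ec$ec_code), "ec", lv)$total_assigned
  }, 0)
  expect_true(all(diff(ec_totals) <= 0))
  bg <- build_background(ref, "cath")
  expect_equal(length(unique(vapply(bg, `[[`, 0, "total_assigned"))), 1)
})

test_that("backgrounds equal a direct recount of the raw registries", {
  ref <- fixture_proteome()
  # CATH: one occurrence per domain on each cluster-representative chain
  reps <- ref$clusters[ref$clusters$member_order == 1, ]
  rep_key <- paste0(reps$structure_id, "_", reps$chain)
  seg_key <- paste0(ref$cath_segments$structure_id, "_", ref$cath_segments$chain)
  doms <- unique(ref$cath_segments$domain_id[seg_key %in% rep_key])
  d <- ref$cath_domains[match(doms, ref$cath_domains$domain_id), ]
  want <- table(paste(d$c, d$a, d$t, d$h, sep = "."))
  got <- build_background(ref, "cath")$homology
  expect_equal(as.numeric(got$counts[names(want)]), as.numeric(want))
  expect_equal(got$total_assigned, length(doms))
  # superfamily label count is bounded by the configured hierarchy size
  expect_lte(length(got$counts), 40)
  # Pfam / EC / GO: one occurrence per annotation row
  expect_equal(build_background(ref, "pfam")$family$total_assigned,
               nrow(ref$pfam))
  expect_equal(build_background(ref, "go")$term$total_assigned, nrow(ref$go))
  got_go <- build_background(ref, "go")$aspect
  expect_equal(as.numeric(got_go$counts[names(table(ref$go$aspect))]),
               as.numeric(table(ref$go$aspect)))
  # chromosome: gene counts and summed CDS lengths side by side
  bg <- build_background(ref, "chromosome")
  expect_equal(sum(bg$genes$counts), nrow(ref$genes))
  expect_equal(sum(bg$cds$counts), sum(ref$genes$cds_length))
})

test_that("uniform dataset frequency profiles approach the background with n", {
  ref <- fixture_proteome()
  bg <- build_background(ref, "chromosome")
  wfreq <- bg$cds$counts / sum(bg$cds$counts)
  tv_chrom <- vapply(c(100, 1000, 10000), function(n) {
    ds <- generate_variant_dataset(ref, sampling_spec(n_variants = n, seed = 99))
    cc <- chromosome_counts(ds)
    f <- setNames(rep(0, length(wfreq)), names(wfreq))
    f[names(cc$counts)] <- cc$counts / cc$total_assigned
    sum(abs(f - wfreq)) / 2
  }, 0)
  expect_true(all(diff(tv_chrom) < 0))
  bgp <- build_background(ref, "pfam")$family
  bfreq <- bgp$counts / bgp$total_assigned
  tv_pfam <- vapply(c(100, 1000, 10000), function(n) {
    ds <- generate_variant_dataset(ref, sampling_spec(
      n_variants = n, seed = 99,
      namespace_weights = c(refseq = 0, ensembl = 0, uniprot = 1)))
    ds <- to_canonical(ds, ref)
    lc <- level_counts(benchrep:::pfam_assignments(ds, ref), "pfam", "family")
    f <- setNames(rep(0, length(bfreq)), names(bfreq))
    f[names(lc$counts)] <- lc$counts / lc$total_assigned
    sum(abs(f - bfreq)) / 2
  }, 0)
  expect_true(all(diff(tv_pfam) < 0))
})
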