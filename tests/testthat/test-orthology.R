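# two small annotations whose proteins are related one-to-one, plus controls
make_species_pair <- function(extra_dup_a = FALSE) {
  set.seed(17)
  truth <- generate_truth(sim_config(n_ortholog_pairs = 6, divergence = 0.05,
                                     n_lineage_specific_tss = 0,
                                     n_intergenic_tss = 0, seed = 17))
  a <- truth$annotations$species_a
  b <- truth$annotations$species_b
  if (extra_dup_a) {
    dup <- a$orfs[1, ]
    dup$gene_id <- "SA_dup"
    a$orfs <- rbind(a$orfs, dup)
  }
  list(a = a, b = b, truth = truth)
}

test_that("global alignment identity matches hand counts", {
  expect_equal(global_align("ACDE", "ACDE")$identity, 100)
  expect_equal(global_align("ACDE", "ACDF")$identity, 75)
  aln <- global_align("ACGTACGT", "ACGAACGT", type = "dna")
  expect_equal(aln$identity, 100 * 7 / 8)
  expect_error(global_align("", "ACD"), "empty")
})

test_that("alignments degap to the input sequences", {
  set.seed(3)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  for (k in 1:5) {
    s1 <- paste(sample(aa, sample(20:60, 1), TRUE), collapse = "")
    s2 <- paste(sample(aa, sample(20:60, 1), TRUE), collapse = "")
    aln <- global_align(s1, s2)
    expect_equal(gsub("-", "", aln$aligned_a), s1)
    expect_equal(gsub("-", "", aln$aligned_b), s2)
  }
})

test_that("reciprocal best hits give single-copy pairs; duplicates are excluded", {
  sp <- make_species_pair()
  set.seed(42)
  ortho <- build_single_copy_orthologs(sp$a, sp$b)
  expect_equal(nrow(ortho$table), 6L)
  expect_equal(ortho$table$gene_b[match(sp$truth$ortholog_genes$gene_a,
                                        ortho$table$gene_a)],
               sp$truth$ortholog_genes$gene_b)
  expect_true(all(ortho$table$protein_identity >= 30))

  # an identical duplicate of gene 1 ties the best hit: the family is no
  # longer single-copy and drops out, the remaining pairs survive
  spd <- make_species_pair(extra_dup_a = TRUE)
  set.seed(42)
  ortho_d <- build_single_copy_orthologs(spd$a, spd$b)
  expect_equal(nrow(ortho_d$table), 5L)
  expect_false("SA0001" %in% ortho_d$table$gene_a)
  expect_false("SA_dup" %in% ortho_d$table$gene_a)

  dup_ids <- spd$a
  dup_ids$orfs$gene_id[7] <- "SA0001"
  expect_error(build_single_copy_orthologs(dup_ids, spd$b), "duplicate")
})

test_that("RBBH detection is symmetric in the two species", {
  sp <- make_species_pair()
  set.seed(1); fwd <- build_single_copy_orthologs(sp$a, sp$b)
  set.seed(1); rev <- build_single_copy_orthologs(sp$b, sp$a)
  expect_equal(fwd$table$gene_a[order(fwd$table$gene_a)],
               rev$table$gene_b[order(rev$table$gene_b)])
  expect_equal(fwd$table$gene_b[order(fwd$table$gene_a)],
               rev$table$gene_a[order(rev$table$gene_b)])
})

test_that("unrelated proteins stay below the null-calibrated score threshold", {
  sp <- make_species_pair()
  a <- sp$a
  set.seed(9)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  rogue <- a$orfs[1, ]
  rogue$gene_id <- "SA_rogue"
  rogue$protein <- paste(sample(aa, 150, TRUE), collapse = "")
  rogue$cds <- NA_character_
  a$orfs <- rbind(a$orfs, rogue)
  # the rogue gene has no homolog: with one extra unpaired gene the pair set
  # is unchanged
  set.seed(42)
  ortho <- build_single_copy_orthologs(a, sp$b)
  expect_equal(nrow(ortho$table), 6L)
  expect_false("SA_rogue" %in% ortho$table$gene_a)
})

test_that("codon alignments expand protein columns three-fold around gaps", {
  aln <- list(aligned_a = "AC-D", aligned_b = "ACED")
  cds_a <- "GCTTGTGATTAA"          # A C D stop
  cds_b <- "GCTTGTGAAGATTAA"      # A C E D stop
  cod <- orthotss:::expand_codon_alignment(aln, cds_a, cds_b)
  expect_equal(nchar(cod$aligned_a), 12L)
  expect_equal(substr(cod$aligned_a, 7, 9), "---")
  expect_equal(gsub("-", "", cod$aligned_a), substr(cds_a, 1, 9))
  expect_equal(gsub("-", "", cod$aligned_b), substr(cds_b, 1, 12))
  expect_error(orthotss:::expand_codon_alignment(aln, "GCTTGT", cds_b),
               "mismatch")
})

test_that("coordinate maps shift by partner gaps and reject outside positions", {
  sp <- make_species_pair()
  set.seed(42)
  ortho <- build_single_copy_orthologs(sp$a, sp$b)
  pair <- ortho$pairs[[1]]
  map <- codon_alignment_map(pair)

  # substitution-only divergence gives gap-free alignments: CDS position k
  # maps to codon column k in both species
  orf_a <- pair$orf_a
  pos3 <- if (orf_a$strand == "+") orf_a$start + 2L else orf_a$end - 2L
  expect_equal(map_coordinate_to_column(map, "a", pos3, "cds"), 3L)
  # a position outside the CDS is not mappable
  out_pos <- if (orf_a$strand == "+") orf_a$start - 1L else orf_a$end + 1L
  expect_true(is.na(map_coordinate_to_column(map, "a", out_pos, "cds")))
  # a genic TSS beyond the UTR window is not mappable
  far <- if (orf_a$strand == "+") orf_a$start - 1001L else orf_a$end + 1001L
  expect_true(is.na(map_coordinate_to_column(map, "a", far, "utr")))

  # a synthetic gapped alignment shifts columns by the partner's gap length
  gpair <- pair
  gpair$protein_alignment$aligned_a <-
    paste0("-----", substr(pair$protein_alignment$aligned_a, 1,
                           nchar(pair$protein_alignment$aligned_a)))
  gpair$protein_alignment$aligned_b <-
    paste0("AAAAA", substr(pair$protein_alignment$aligned_b, 1,
                           nchar(pair$protein_alignment$aligned_b)))
  gmap <- codon_alignment_map(gpair)
  expect_equal(map_coordinate_to_column(gmap, "a", pos3, "cds"),
               3L + 15L)
})

test_that("mean protein identity decreases with divergence", {
  idents <- vapply(c(0, 0.05, 0.1, 0.2), function(d) {
    truth <- generate_truth(sim_config(n_ortholog_pairs = 12, divergence = d,
                                       n_lineage_specific_tss = 0,
                                       n_intergenic_tss = 0, seed = 5))
    mean(truth$ortholog_genes$protein_identity)
  }, numeric(1))
  expect_equal(idents[1], 100)
  expect_true(all(diff(idents) < 0))
})
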