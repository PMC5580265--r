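test_that("the generator is deterministic and respects its invariants", {
  cfg <- sim_config(n_ortholog_pairs = 12, seed = 8)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$tss, t2$tss)
  expect_identical(as.character(t1$annotations$species_a$genome),
                   as.character(t2$annotations$species_a$genome))
  expect_identical(t1$ortholog_genes, t2$ortholog_genes)

  libs1 <- simulate_libraries(t1, cfg)
  libs2 <- simulate_libraries(t2, cfg)
  expect_identical(libs1$info, libs2$info)
  expect_identical(libs1$libraries[[1]]$ends, libs2$libraries[[1]]$ends)

  # partner references are reciprocal and positions lie in bounds
  tss <- t1$tss
  withp <- tss[!is.na(tss$partner_site), ]
  back <- setNames(tss$partner_site, tss$site_id)
  expect_true(all(back[withp$partner_site] == withp$site_id))
  expect_true(all(tss$position >= 1 & tss$position <= t1$replicon_length))
  # every planted extreme pair has positive levels and a same-sign fold change
  cc <- t1$consistent_candidates
  lev <- tss[match(c(cc$site_a, cc$site_b), tss$site_id), ]
  expect_true(all(lev$level_branchless > 0 & lev$level_true_branching > 0))
  fa <- tss$fc[match(cc$site_a, tss$site_id)]
  fb <- tss$fc[match(cc$site_b, tss$site_id)]
  expect_true(all(sign(fa) == sign(fb)))
})

test_that("zero divergence yields identical proteomes", {
  truth <- generate_truth(sim_config(n_ortholog_pairs = 8, divergence = 0,
                                     seed = 2))
  expect_true(all(truth$ortholog_genes$protein_identity == 100))
  expect_identical(as.character(truth$annotations$species_a$genome),
                   as.character(truth$annotations$species_b$genome))
})

test_that("invalid fractions are rejected", {
  expect_error(sim_config(divergence = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(fraction_ortho_tss = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(tex_enrichment = 0), "tex_enrichment")
})

test_that("the orthologous fraction of planted loci follows its parameter", {
  cfg <- sim_config(n_ortholog_pairs = 200, fraction_ortho_tss = 0.5,
                    n_lineage_specific_tss = 0, n_intergenic_tss = 0,
                    seed = 19)
  loci <- planted_loci(generate_truth(cfg))
  n <- nrow(loci)
  phat <- mean(loci$ortho)
  half_width <- 2.576 * sqrt(0.25 / n)  # binomial 99% CI at p = 0.5
  expect_gt(phat, 0.5 - half_width)
  expect_lt(phat, 0.5 + half_width)
})

test_that("fixed library sizes are honoured exactly", {
  cfg <- sim_config(n_ortholog_pairs = 5, library_sizes = rep(1000L, 4),
                    seed = 4)
  libs <- simulate_libraries(generate_truth(cfg), cfg)
  expect_true(all(libs$info$n_ends == 1000L))
})

test_that("the zero-noise limit reproduces the planted step profile exactly", {
  cfg <- sim_config(n_ortholog_pairs = 5, background_noise_rate = 0,
                    tex_enrichment = Inf, jitter_sd = 0, count_noise = FALSE,
                    decoy_fraction = 0, multimap_fraction = 0, seed = 6)
  truth <- generate_truth(cfg)
  libs <- simulate_libraries(truth, cfg)
  lib <- libs$libraries[["species_a.branchless.plus"]]
  sites <- truth$tss[truth$tss$species == "species_a", ]
  expected <- round(sites$level_branchless)
  got <- lib$ends$count[match(paste(sites$strand, sites$position),
                              paste(lib$ends$strand, lib$ends$pos))]
  got[is.na(got)] <- 0
  expect_equal(got, expected)
  expect_equal(nrow(lib$ends), sum(expected > 0))
  # the TEX(-) library is empty at infinite enrichment and zero background
  expect_equal(nrow(libs$libraries[["species_a.branchless.minus"]]$ends), 0L)
})

test_that("TEX(-) signal at a planted TSS is the level over the enrichment ratio", {
  # one strong TSS per gene, height fixed at 50, flat fold change
  lam_ratio <- vapply(1:100, function(s) {
    cfg <- sim_config(n_ortholog_pairs = 3, p_gtss = 1, p_itss = 0,
                      p_atss = 0, n_lineage_specific_tss = 0,
                      n_intergenic_tss = 0, step_height_range = c(50, 50),
                      planted_extreme_fraction = 0, tex_enrichment = 10,
                      background_noise_rate = 0, jitter_sd = 0,
                      decoy_fraction = 0, multimap_fraction = 0, seed = s)
    truth <- generate_truth(cfg)
    libs <- simulate_libraries(truth, cfg)
    lib <- libs$libraries[["species_a.branchless.minus"]]
    sites <- truth$tss[truth$tss$species == "species_a", ]
    got <- lib$ends$count[match(paste(sites$strand, sites$position),
                                paste(lib$ends$strand, lib$ends$pos))]
    got[is.na(got)] <- 0
    sum(got) / sum(sites$level_branchless)
  }, numeric(1))
  # Monte-Carlo mean of the TEX(-)/level ratio approaches 1/10
  # (per-seed sampling sd ~ 0.026, so the 100-seed mean has sd ~ 0.003)
  expect_lt(abs(mean(lam_ratio) - 0.1), 0.01)
})
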