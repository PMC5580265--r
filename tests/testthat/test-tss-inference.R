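flat_track <- function(value, n = 100) {
  make_track(list("chr|+" = rep(value, n), "chr|-" = rep(value, n)))
}

test_that("TSS calling requires both a coverage step and TEX enrichment", {
  # flat coverage has no steps
  expect_equal(nrow(call_tss(flat_track(20), flat_track(1))), 0L)

  # 0 -> 50 step with TEX(-) at 4: step 50, enrichment 51/5
  p <- rep(0, 100); p[40:60] <- 50
  m <- rep(0, 100); m[40:60] <- 4
  res <- call_tss(make_track(list("chr|+" = p)),
                  make_track(list("chr|+" = m)),
                  min_step = 10, min_enrich = 2)
  expect_equal(res$position, 40)
  expect_equal(res$step_height, 50)
  expect_equal(res$enrichment, 51 / 5)

  # equal TEX(+) and TEX(-) signal marks a processed 5' end, not a TSS
  p2 <- rep(0, 100); p2[40:60] <- 50
  res2 <- call_tss(make_track(list("chr|+" = p2)),
                   make_track(list("chr|+" = p2)),
                   min_step = 10, min_enrich = 2)
  expect_equal(nrow(res2), 0L)

  # on the minus strand the upstream neighbour is position + 1
  pm <- rep(0, 100); pm[20:45] <- 30
  res3 <- call_tss(make_track(list("chr|-" = pm)),
                   make_track(list("chr|-" = rep(0, 100))),
                   min_step = 10, min_enrich = 2)
  expect_equal(res3$position, 45)
  expect_equal(res3$strand, "-")

  expect_error(call_tss(make_track(list("chr|+" = rep(0, 10))),
                        make_track(list("chr|-" = rep(0, 10)))),
               "different replicons")
})

test_that("chain-linkage clustering keeps the highest step, ties to the smaller coordinate", {
  tss <- data.frame(replicon = "chr", position = c(100L, 120L),
                    strand = "+", step_height = c(10, 30),
                    enrichment = 5, level = c(10, 30))
  out <- cluster_tss(tss, distance = 30)
  expect_equal(out$position, 120L)

  # transitive chaining: 100-125-150 is one cluster although 100 and 150
  # are 50 bp apart
  tss3 <- data.frame(replicon = "chr", position = c(100L, 125L, 150L),
                     strand = "+", step_height = c(5, 40, 10),
                     enrichment = 5, level = 1)
  expect_equal(cluster_tss(tss3, distance = 30)$position, 125L)

  # equal heights resolve to the smaller coordinate
  tie <- data.frame(replicon = "chr", position = c(200L, 210L), strand = "+",
                    step_height = c(7, 7), enrichment = 5, level = 1)
  expect_equal(cluster_tss(tie, distance = 30)$position, 200L)

  # opposite strands never cluster
  ds <- data.frame(replicon = "chr", position = 300L, strand = c("+", "-"),
                   step_height = c(3, 9), enrichment = 5, level = 1)
  expect_equal(nrow(cluster_tss(ds, distance = 30)), 2L)
})

test_that("clustered TSSs respect the minimum-distance property", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    tss <- data.frame(replicon = "chr",
                      position = sample(1:500, n),
                      strand = sample(c("+", "-"), n, TRUE),
                      step_height = runif(n, 1, 50),
                      enrichment = 5, level = 1)
    out <- cluster_tss(tss, distance = 30)
    for (s in c("+", "-")) {
      p <- sort(out$position[out$strand == s])
      if (length(p) > 1) expect_true(all(diff(p) > 30))
    }
  }
})

test_that("condition unification records per-condition levels at the representative", {
  cov_a <- rep(0, 300); cov_a[200] <- 40
  cov_b <- rep(0, 300); cov_b[210] <- 20
  tr_a <- make_track(list("chr|+" = cov_a))
  tr_b <- make_track(list("chr|+" = cov_b))
  tss_a <- data.frame(replicon = "chr", position = 200L, strand = "+",
                      step_height = 40, enrichment = 10, level = 40)
  tss_b <- data.frame(replicon = "chr", position = 210L, strand = "+",
                      step_height = 20, enrichment = 10, level = 20)
  uni <- unify_conditions(list(branchless = tss_a, true_branching = tss_b),
                          list(branchless = tr_a, true_branching = tr_b),
                          window = 35)
  expect_equal(nrow(uni), 1L)
  expect_equal(uni$position, 200L)
  expect_equal(uni$level_branchless, 40)
  # the weaker condition's level is read from its own coverage at 200
  expect_equal(uni$level_true_branching, 0)

  # a TSS detected only in one condition still gets the other's coverage
  cov_b2 <- cov_b; cov_b2[200] <- 7
  uni2 <- unify_conditions(list(branchless = tss_a,
                                true_branching = tss_a[0, ]),
                           list(branchless = tr_a,
                                true_branching = make_track(list("chr|+" = cov_b2))))
  expect_equal(uni2$level_true_branching, 7)
})

test_that("condition unification is idempotent", {
  set.seed(31)
  n <- 40
  pos <- sort(sample(1:2000, n))
  mk <- function(sel) data.frame(replicon = "chr", position = pos[sel],
                                 strand = "+", step_height = runif(sum(sel), 5, 50),
                                 enrichment = 5, level = 1)
  cov <- list("chr|+" = runif(2000, 0, 10))
  tr <- make_track(cov)
  sel <- runif(n) < 0.6
  uni <- unify_conditions(list(branchless = mk(sel), true_branching = mk(!sel)),
                          list(branchless = tr, true_branching = tr))
  again <- unify_conditions(
    list(branchless = uni[, c("replicon", "position", "strand",
                              "step_height", "enrichment")],
         true_branching = uni[0, c("replicon", "position", "strand",
                                   "step_height", "enrichment")]),
    list(branchless = tr, true_branching = tr))
  expect_equal(again$position, uni$position)
  p <- sort(uni$position)
  expect_true(all(diff(p) > 35))
})
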