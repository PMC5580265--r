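# Shared fixtures and independent oracles for the test suite.

# Build a coverage track object from per-key vectors, as produced by
# coverage_from_alignments(), for hand-crafted caller inputs.
make_track <- function(cov, library_id = "lib") {
  list(library_id = library_id, size = NA_integer_, norm_factor = 1,
       cov = cov)
}

# A minimal alignment-record data frame with sensible defaults.
make_records <- function(read_id, start, end,
                         read_length = 50L, replicon = "chr",
                         strand = "+", mismatches = 0L, gaps = 0L,
                         evalue = 1e-20, score = 100) {
  data.frame(read_id = read_id, read_length = read_length,
             replicon = replicon, start = start, end = end, strand = strand,
             mismatches = mismatches, gaps = gaps, evalue = evalue,
             score = score, stringsAsFactors = FALSE)
}

# A hand-built two-gene annotation on a fixed 1.2 kb genome; CDSs are real
# in-frame ORFs so codon maps and translations are consistent.
toy_annotation <- function() {
  set.seed(99)
  sense <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                         paste0), c("A","C","G","T"), paste0)),
                   c("TAA", "TAG", "TGA"))
  mk_cds <- function(naa) paste0("ATG", paste(sample(sense, naa, TRUE),
                                              collapse = ""), "TAA")
  cds1 <- mk_cds(40)   # 126 nt
  cds2 <- mk_cds(50)   # 156 nt
  spacer <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  s1 <- spacer(300); s2 <- spacer(250); s3 <- spacer(368)
  genome <- Biostrings::DNAString(paste0(
    s1, cds1, s2,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds2))),
    s3))
  orfs <- data.frame(
    gene_id = c("g1", "g2"), replicon = "chr",
    start = c(301, 301 + 126 + 250),
    end = c(301 + 125, 301 + 126 + 250 + 155),
    strand = c("+", "-"),
    cds = c(cds1, cds2),
    protein = orthotss:::translate_cds(c(cds1, cds2)),
    stringsAsFactors = FALSE
  )
  structure(list(species = "toy", replicon = "chr", genome = genome,
                 orfs = orfs), class = "genome_annotation")
}

# Independent two-sided Fisher oracle: full hypergeometric enumeration over
# all tables with the observed margins (the standard exact definition).
fisher_enum_p <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(k, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Memoized default-scale synthetic study shared by the heavier tests.
default_study_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$study)) {
      cfg <- sim_config(seed = 202L)
      truth <- generate_truth(cfg)
      libs <- simulate_libraries(truth, cfg)
      study <- run_comparative_study(truth, libs)
      env$truth <- truth
      env$study <- study
    }
    list(truth = env$truth, study = env$study)
  }
})
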