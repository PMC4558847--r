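test_that("k-mer distances match brute-force k-mer set comparison", {
  seqs <- list(s1 = "ACGTACGT", s2 = "ACGTACGA", s3 = "TTTTTTTT")
  D <- kmer_distance_matrix(seqs, k = 3)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  expect_equal(D, t(D))
  # brute force for (s1, s2), k = 3
  km <- function(s, k) {
    n <- nchar(s)
    table(substring(s, 1:(n - k + 1), k:n))
  }
  c1 <- km(seqs$s1, 3); c2 <- km(seqs$s2, 3)
  shared <- sum(pmin(c1[intersect(names(c1), names(c2))],
                     c2[intersect(names(c1), names(c2))]))
  expect_equal(D["s1", "s2"], 1 - shared / (8 - 3 + 1))
  # identical sequences at distance 0, disjoint k-mer sets at distance 1
  expect_equal(kmer_distance_matrix(list(a = "ACGT", b = "ACGT"), 2)["a", "b"], 0)
  expect_equal(D["s1", "s3"], 1)
  expect_error(kmer_distance_matrix(list(a = "AC", b = "ACGT"), 3), ">= k")
})

test_that("guide trees recover generating topologies from clean distances", {
  # additive matrix from a known 4-leaf tree ((a,b),(c,d))
  tr <- read_newick("((a:0.1,b:0.2):0.15,(c:0.3,d:0.1):0.05);")
  D <- ape::cophenetic.phylo(tr)
  gt <- build_guide_tree(D, "nj")
  expect_equal(rf_distance(gt, tr), 0L)
  # ultrametric matrix + UPGMA recovers the rooted topology
  tru <- read_newick("((a:0.1,b:0.1):0.2,(c:0.25,d:0.25):0.05);")
  Du <- ape::cophenetic.phylo(tru)
  gu <- build_guide_tree(Du, "upgma")
  expect_equal(rf_distance(gu, tru), 0L)
  # 3 taxa: the unique unrooted topology
  g3 <- build_guide_tree(ape::cophenetic.phylo(read_newick("(a:1,b:1,c:1);")), "nj")
  expect_length(g3$tip.label, 3L)
  expect_error(build_guide_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("two-sequence alignment attains the brute-force affine optimum", {
  m <- paper_gtr()
  cfg <- aligner_config(k = 3)
  S <- msabias:::score_matrix(m, cfg$ref_distance)
  set.seed(12)
  for (rep in 1:6) {
    s1 <- sample(m$states, sample(5:9, 1), replace = TRUE)
    s2 <- sample(m$states, sample(5:9, 1), replace = TRUE)
    al <- progressive_align(list(a = s1, b = s2), m, cfg)
    # score the produced alignment
    rows <- al$msa$aln
    sc <- 0; ingap <- FALSE
    for (j in seq_len(ncol(rows))) {
      if (rows[1, j] == "-" || rows[2, j] == "-") {
        sc <- sc + if (ingap) cfg$gap_extend else cfg$gap_open
        ingap <- TRUE
      } else {
        sc <- sc + S[rows[1, j], rows[2, j]]
        ingap <- FALSE
      }
    }
    opt <- pairwise_align_oracle(s1, s2, S, cfg$gap_open, cfg$gap_extend)
    expect_equal(sc, opt)
  }
})

test_that("zero-indel simulations are aligned exactly and deterministically", {
  m <- paper_gtr(); g <- study_gamma()
  tr <- make_balanced_tree(1)
  sim <- simulate_sequences(tr, m, g, indel_params(rel_rate = 0),
                            root_length = 200, seed = 5)
  al1 <- progressive_align(sim$seqs, m)
  expect_identical(al1$msa$aln[rownames(sim$alignment$aln), ],
                   sim$alignment$aln)
  al2 <- progressive_align(sim$seqs, m)
  expect_identical(al1$msa$aln, al2$msa$aln)
  expect_identical(degap(al1$msa), sim$seqs[rownames(al1$msa$aln)])
  expect_error(progressive_align(sim$seqs[1], m), "at least 2")
})

test_that("alignment accuracy degrades with divergence on average", {
  m <- build_empirical_aa(); g <- study_gamma()
  R <- 12
  tp_rate <- sapply(c(0.5, 2, 6), function(L) {
    tr <- make_balanced_tree(L)
    mean(sapply(seq_len(R), function(r) {
      sim <- simulate_sequences(tr, m, g, root_length = 150,
                                seed = 1000 * L + r)
      al <- progressive_align(sim$seqs, m)$msa
      sc <- homology_scores(al, sim$alignment)
      sc$tp / (sc$tp + sc$fn)
    }))
  })
  expect_true(all(diff(tp_rate) < 0))
})

test_that("guide trees are accurate for slowly evolving amino-acid data", {
  m <- build_empirical_aa(); g <- study_gamma()
  tr <- make_balanced_tree(0.5)
  hits <- sapply(1:20, function(r) {
    sim <- simulate_sequences(tr, m, g, root_length = 408, seed = 300 + r)
    al <- progressive_align(sim$seqs, m)
    rf_distance(al$guide_tree, tr) == 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("subalignment extraction keeps degap identity and drops gap columns", {
  m <- paper_gtr(); g <- study_gamma()
  core <- make_balanced_tree(6)
  st <- embed_in_supertree(core, 64, seed = 2)
  sim <- simulate_sequences(st, m, g, root_length = 150, seed = 61)
  sub <- extract_subalignment(sim$alignment, core$tip.label)
  expect_setequal(rownames(sub$aln), core$tip.label)
  expect_identical(degap(sub), sim$seqs[rownames(sub$aln)])
  expect_true(all(colSums(sub$aln != "-") > 0))
  expect_lte(ncol(sub$aln), ncol(sim$alignment$aln))
  # full taxon set: unchanged
  full <- extract_subalignment(sim$alignment, rownames(sim$alignment$aln))
  expect_identical(full$aln, sim$alignment$aln)
  expect_error(extract_subalignment(sim$alignment, "nope"), "unknown")
})

test_that("the external-aligner adapter round-trips and reports failures", {
  msa <- msa_from_strings(list(a = "AC-GT", b = "ACTGT"), type = "nt")
  f <- tempfile(fileext = ".fasta")
  write_msa(msa, f)
  seqs <- lapply(degap(msa), paste, collapse = "")
  out <- external_align(seqs, paste0("cp ", f, " {output} && true {input}"),
                        type = "nt", name = "identity")
  expect_identical(out$aln, msa$aln)
  expect_equal(out$source, "external:identity")
  expect_error(external_align(seqs, "/no/such/binary {input} {output}"),
               "failed|no output")
  expect_error(external_align(seqs, "cp {input}"), "placeholder")
  # unequal row lengths in the tool output are a parse error
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-GT", ">b", "ACTG"), bad)
  expect_error(external_align(seqs, paste0("cp ", bad, " {output} && true {input}")),
               "equal length")
  unlink(c(f, bad))
})
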