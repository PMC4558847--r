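test_that("pruning matches closed forms and missing-data semantics", {
  jc <- jc_model()
  g1 <- discretize_gamma(1, 1)
  # two taxa, one site, both "a": lnL = log(pi_a * P_aa(t_total))
  msa <- msa_from_strings(list(x = "a", y = "a"))
  tr <- read_newick("(x:0.3,y:0.4);")
  fit <- phylo_loglik(msa, tr, jc, g1)
  Paa <- 1 / 4 + (3 / 4) * exp(-4 * 0.7 / 3)
  expect_equal(fit$logLik, log(0.25 * Paa), tolerance = 1e-10)
  # a column gapped in all but one taxon contributes log pi_x
  m2 <- msa_from_strings(list(x = "ca", y = "-a"))
  f2 <- phylo_loglik(m2, tr, jc, g1)
  expect_equal(f2$site_lnl[1], log(0.25), tolerance = 1e-12)
  expect_equal(f2$logLik, sum(f2$site_lnl), tolerance = 1e-10)
  expect_error(phylo_loglik(msa_from_strings(list(x = "a", z = "a")), tr, jc, g1),
               "match")
})

test_that("pruning agrees with the exhaustive state-enumeration oracle", {
  m <- paper_gtr(); g <- discretize_gamma(1.8, 2)
  tr <- read_newick("((x:0.2,y:0.5):0.1,(z:0.4,w:0.3):0.2);")
  msa <- msa_from_strings(list(x = "ac", y = "a-", z = "gt", w = "ac"))
  fit <- phylo_loglik(msa, tr, m, g)
  expect_equal(fit$logLik, loglik_oracle(msa, tr, m, g), tolerance = 1e-9)
  # amino-acid model, single category
  w <- build_empirical_aa()
  gw <- discretize_gamma(1, 1)
  msaa <- msa_from_strings(list(x = "AR", y = "AK", z = "-R", w = "AR"),
                           type = "aa")
  fw <- phylo_loglik(msaa, tr, w, gw)
  expect_equal(fw$logLik, loglik_oracle(msaa, tr, w, gw), tolerance = 1e-9)
})

test_that("the likelihood obeys the pulley principle", {
  m <- paper_gtr(); g <- study_gamma()
  tr <- make_balanced_tree(2)
  sim <- simulate_sequences(tr, m, g, root_length = 80, seed = 9)
  base <- phylo_loglik(sim$alignment, tr, m, g)$logLik
  for (og in c("t1", "t5")) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    ll <- phylo_loglik(sim$alignment, rr, m, g)$logLik
    expect_equal(ll, base, tolerance = 1e-8)
  }
})

test_that("branch-length optimization behaves sensibly", {
  m <- paper_gtr(); g <- study_gamma()
  tr4 <- read_newick("((x:0.1,y:0.1):0.1,z:0.1,w:0.1);")
  # identical sequences: all branch lengths collapse to ~0
  msa_same <- msa_from_strings(list(x = strrep("acgt", 10), y = strrep("acgt", 10),
                                    z = strrep("acgt", 10), w = strrep("acgt", 10)))
  fit0 <- fit_branch_lengths(msa_same, tr4, m, g, estimate_shape = FALSE,
                             estimate_rates = FALSE)
  expect_lt(sum(fit0$tree$edge.length), 1e-4)
  # robustness to the starting point, and lnL >= lnL at the truth
  tr <- make_balanced_tree(2)
  sim <- simulate_sequences(tr, m, g, indel_params(rel_rate = 0),
                            root_length = 500, seed = 17)
  fit_truth_start <- fit_branch_lengths(sim$alignment, tr, m, g,
                                        estimate_shape = FALSE,
                                        estimate_rates = FALSE)
  flat <- tr; flat$edge.length <- rep(0.1, nrow(tr$edge))
  fit_flat_start <- fit_branch_lengths(sim$alignment, flat, m, g,
                                       estimate_shape = FALSE,
                                       estimate_rates = FALSE)
  expect_equal(fit_truth_start$logLik, fit_flat_start$logLik, tolerance = 1e-4)
  ll_truth <- phylo_loglik(sim$alignment, tr, m, g)$logLik
  expect_gte(fit_truth_start$logLik, ll_truth - 1e-6)
  # per-site log-likelihoods sum to the total
  expect_equal(sum(fit_truth_start$site_lnl), fit_truth_start$logLik,
               tolerance = 1e-6)
  expect_length(fit_truth_start$site_lnl, ncol(sim$alignment$aln))
})

test_that("topology selection applies the equal-weight tie rule", {
  # synthetic tie: three candidates, two within 1e-2 lnL
  m <- paper_gtr(); g <- study_gamma()
  pt <- make_polytomy_tree()
  cands <- resolve_polytomy(pt)
  sim <- simulate_sequences(pt, m, g, indel_params(rel_rate = 0),
                            root_length = 120, seed = 71)
  sel <- select_topology(sim$alignment, cands, m, g, estimate_rates = FALSE)
  expect_equal(sum(sel$weights), 1, tolerance = 1e-9)
  expect_true(all(sel$weights %in% c(0, 1 / length(sel$winners))))
  # direct check of the rule on stubbed likelihoods via the internal logic
  ll <- c(-1000.000, -1000.005, -1200)
  top <- ll >= max(ll) - 1e-2
  expect_equal(as.numeric(top) / sum(top), c(0.5, 0.5, 0))
  # single candidate gets weight 1
  sel1 <- select_topology(sim$alignment, cands[1], m, g, estimate_rates = FALSE)
  expect_equal(sel1$weights, 1)
})

test_that("strong signal puts all weight on the generating resolution", {
  m <- paper_gtr(); g <- study_gamma()
  pt <- make_polytomy_tree()
  cands <- resolve_polytomy(pt)
  # simulate on resolution 2 with a long internal branch
  gen <- cands[[2]]
  gen$edge.length[gen$edge.length == 0] <- 0.5
  wins <- sapply(1:10, function(r) {
    sim <- simulate_sequences(gen, m, g, indel_params(rel_rate = 0),
                              root_length = 2000, seed = 600 + r)
    sel <- select_topology(sim$alignment, cands, m, g, estimate_rates = FALSE)
    sel$weights[2]
  })
  expect_equal(mean(wins), 1)
})

test_that("Fitch parsimony matches enumeration and is rooting-invariant", {
  msa <- msa_from_strings(list(A1 = "a", A2 = "a", B1 = "c", B2 = "c"))
  tr <- read_newick("((A1:1,A2:1):1,(B1:1,B2:1):1);")
  expect_equal(fitch_parsimony(msa, tr), 1L)
  # identical sequences: zero changes
  same <- msa_from_strings(list(A1 = "acg", A2 = "acg", B1 = "acg", B2 = "acg"))
  expect_equal(fitch_parsimony(same, tr), 0L)
  # exhaustive oracle on a random small alignment
  set.seed(13)
  aln <- matrix(sample(c("a", "c", "g", "t"), 4 * 6, TRUE), 4, 6,
                dimnames = list(c("A1", "A2", "B1", "B2"), NULL))
  msar <- new_msa(aln, "nt", "true")
  oracle <- 0
  for (s in seq_len(ncol(aln))) {
    best <- Inf
    for (i1 in 1:4) for (i2 in 1:4) {
      st <- c("a", "c", "g", "t")
      cost <- sum(st[i1] != aln[c("A1", "A2"), s]) +
        sum(st[i2] != aln[c("B1", "B2"), s]) + (i1 != i2)
      best <- min(best, cost)
    }
    oracle <- oracle + best
  }
  expect_equal(fitch_parsimony(msar, tr), oracle)
  # rerooting does not change the score
  rr <- ape::root(tr, outgroup = "B1", resolve.root = TRUE)
  expect_equal(fitch_parsimony(msar, rr), fitch_parsimony(msar, tr))
  # mp_select splits exact ties equally
  sel <- mp_select(same, list(tr, rr))
  expect_equal(sel$weights, c(0.5, 0.5))
})

test_that("observed frequencies count non-gap residues with a floor", {
  msa <- msa_from_strings(list(x = "aacc", y = "aa-c"))
  f <- observed_frequencies(msa)
  expect_equal(unname(f[c("a", "c")]), c(4, 3) / 7, tolerance = 1e-5)
  expect_true(all(f > 0))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  allA <- msa_from_strings(list(x = "aaaa", y = "aaaa"))
  fA <- observed_frequencies(allA)
  expect_gt(fA[["a"]], 0.999)
  expect_true(all(fA[c("c", "g", "t")] > 0))
})
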