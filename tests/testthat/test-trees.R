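test_that("balanced tree has 13 equal branches in the documented classes", {
  tr <- make_balanced_tree(6)
  expect_equal(length(tr$tip.label), 8L)
  expect_equal(nrow(tr$edge), 13L)
  expect_equal(unname(tr$edge.length), rep(6 / 13, 13))
  expect_equal(sum(tr$edge.length), 6, tolerance = 1e-10)
  cls <- table(attr(tr, "branch_class"))
  expect_equal(as.integer(cls[c("external", "middle", "root")]), c(8L, 4L, 1L))
  expect_equal(unname(make_balanced_tree(13)$edge.length), rep(1, 13))
})

test_that("polytomy tree has the stated depths and total length", {
  tr <- make_polytomy_tree(0.06, 0.7)
  root <- ape::Ntip(tr) + 1L
  expect_equal(sum(tr$edge[, 1] == root), 4L)  # degree-4 multifurcation
  d <- ape::cophenetic.phylo(tr)
  # root-to-tip = half of within-cherry-pair distance + stem; use path depths
  depth <- node_depths_to_tips(tr)
  expect_equal(sort(unique(round(depth, 10))), c(0.12, 1.4))
  expect_equal(sum(tr$edge.length), 3 * 0.06 * 2 + 3 * 0.7 * 2,
               tolerance = 1e-10)
  te <- make_polytomy_tree(0.1, 0.1)
  expect_equal(unique(round(node_depths_to_tips(te), 10)), 0.2)
})

test_that("polytomy resolutions are distinct, RF-2 apart, with one LBA tree", {
  tr <- make_polytomy_tree()
  res <- resolve_polytomy(tr)
  expect_length(res, 3L)
  expect_equal(rf_distance(res[[1]], res[[2]]), 2L)
  expect_equal(rf_distance(res[[1]], res[[3]]), 2L)
  expect_equal(rf_distance(res[[2]], res[[3]]), 2L)
  lba_flags <- vapply(res, attr, logical(1), "is_lba")
  expect_equal(sum(lba_flags), 1L)
  # the LBA candidate has the long cherries (t5..t8) on one side of the
  # new internal branch
  lba <- res[[attr(res, "lba")]]
  keep <- ape::keep.tip(lba, c("t5", "t6", "t7", "t8"))
  expect_s3_class(keep, "phylo")
  expect_error(resolve_polytomy(make_balanced_tree(1)), "multifurcation")
})

test_that("Felsenstein-zone trees have the requested subtree depths", {
  tr <- make_felsenstein_tree(0.025, 1.375, 0.025, 8)
  expect_length(tr$tip.label, 8L)
  # depths from the base node: {alpha, beta} on one side of the internal
  # branch and {alpha, beta} + internal on the other
  depth <- sort(unique(round(node_depths_to_tips(tr), 10)))
  expect_equal(depth, sort(c(0.025, 1.375, 0.025 + 0.025, 1.375 + 0.025)))
  labs <- attr(tr, "subtree_taxa")
  for (i in 1:4) {
    st <- ape::keep.tip(tr, labs[[i]])
    expect_equal(length(st$tip.label), 2L)
  }
  t32 <- make_felsenstein_tree(0.1, 0.5, 0.05, 32)
  expect_length(t32$tip.label, 32L)
  labs32 <- attr(t32, "subtree_taxa")
  expect_true(all(lengths(labs32) == 8L))
  # all depths equal: paths from the base are {depth, depth + internal}
  te <- make_felsenstein_tree(0.3, 0.3, 0.3, 8)
  expect_equal(sort(unique(round(node_depths_to_tips(te), 10))), c(0.3, 0.6))
  expect_error(make_felsenstein_tree(0.1, 0.5, 0.1, 16), "ntaxa")
})

test_that("Felsenstein candidates separate / group the long subtrees", {
  tr <- make_felsenstein_tree(0.05, 1.0, 0.05, 8)
  cands <- felsenstein_candidates(tr)
  expect_length(cands, 3L)
  expect_equal(attr(cands, "correct"), 1L)
  lba <- attr(cands, "lba")
  expect_false(is.na(lba))
  expect_false(lba == 1L)
  expect_equal(rf_distance(cands[[1]], tr), 0L)
  expect_equal(rf_distance(cands[[lba]], tr), 2L)
})

test_that("supertree embedding preserves the core tree exactly", {
  core <- make_balanced_tree(6)
  st <- embed_in_supertree(core, 64, seed = 11)
  expect_length(st$tip.label, 64L)
  ind <- induced_subtree(st, core$tip.label)
  expect_equal(rf_distance(ind, core), 0L)
  D0 <- ape::cophenetic.phylo(core)
  D1 <- ape::cophenetic.phylo(ind)[rownames(D0), colnames(D0)]
  expect_equal(D1, D0, tolerance = 1e-9)
  # determinism
  st2 <- embed_in_supertree(core, 64, seed = 11)
  expect_identical(write_newick(st), write_newick(st2))
  expect_error(embed_in_supertree(core, 100, seed = 1), "64 or 512")
})

test_that("RF distance is a metric on study trees and matches enumeration", {
  b <- make_balanced_tree(1)
  expect_equal(rf_distance(b, b), 0L)
  cat8 <- read_newick("(t1:1,(t2:1,(t3:1,(t4:1,(t5:1,(t6:1,(t7:1,t8:1):1):1):1):1):1):1);")
  # brute-force bipartition oracle
  bip <- function(tr) {
    ut <- ape::unroot(tr)
    ntip <- ape::Ntip(ut)
    keys <- character(0)
    for (e in seq_len(nrow(ut$edge))) {
      nd <- ut$edge[e, 2]
      if (nd <= ntip) next
      tips <- sort(ut$tip.label[unlist(tips_below_oracle(ut, nd))])
      other <- sort(setdiff(ut$tip.label, tips))
      side <- if (paste(tips, collapse = ",") < paste(other, collapse = ","))
        tips else other
      keys <- c(keys, paste(side, collapse = ","))
    }
    keys
  }
  expected <- length(setdiff(bip(cat8), bip(b))) + length(setdiff(bip(b), bip(cat8)))
  expect_equal(rf_distance(cat8, b), expected)
  # symmetry + triangle inequality on the three polytomy resolutions
  res <- resolve_polytomy(make_polytomy_tree())
  for (i in 1:3) for (j in 1:3) {
    expect_equal(rf_distance(res[[i]], res[[j]]), rf_distance(res[[j]], res[[i]]))
    for (k in 1:3)
      expect_lte(rf_distance(res[[i]], res[[j]]),
                 rf_distance(res[[i]], res[[k]]) + rf_distance(res[[k]], res[[j]]))
  }
  expect_error(rf_distance(b, cat8_relabelled <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")),
               "leaf sets")
})

test_that("Newick round-trip preserves topology, labels and lengths", {
  txt <- "((A:1,B:1):1,(C:1,D:1):1);"
  tr <- read_newick(txt)
  expect_length(tr$tip.label, 4L)
  expect_equal(sum(tr$edge.length), 6)
  rt <- read_newick(write_newick(tr))
  expect_equal(rf_distance(rt, tr), 0L)
  expect_equal(sort(rt$tip.label), sort(tr$tip.label))
  expect_error(suppressWarnings(read_newick("((A:1,B:1)")), "malformed")
})
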