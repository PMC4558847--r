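#' Experiment configuration
#'
#' Bundles the knobs shared by the experiment drivers.  Defaults mirror the
#' study conditions: 200 replicates, amino-acid root length 408 (nucleotide
#' runs use 3x the amino-acid root length), indel rate 0.05 with Zipf shape
#' 1.7 truncated at 20 aa / 60 nt, Gamma shape 1.8 with 4 categories.
#'
#' @param experiment one of \code{"divergence"}, \code{"otu_scaling"},
#'   \code{"polytomy"}, \code{"felsenstein"}.
#' @param type data type, \code{"nt"} or \code{"aa"}.
#' @param replicates replicate count per condition (default 200).
#' @param seed master seed; every replicate derives its own seed from it,
#'   so arms share identical simulated data and re-runs are identical.
#' @param tree_lengths grid of total tree lengths for the divergence
#'   experiment.
#' @param root_lengths root sequence length grid in amino-acid units
#'   (nucleotide runs use 3x these values).
#' @param otu_counts OTU grid for the scaling experiment.
#' @param alpha_grid,beta_grid short/long subtree depth grids for the
#'   Felsenstein-zone experiment.
#' @param ntaxa taxa for the Felsenstein-zone trees (8 or 32).
#' @param aligners arms to run: subset of \code{c("true", "builtin")}.
#' @param indel_rate relative indel rate (0 disables indels).
#' @param n_bootstrap RELL replicates for SH tests.
#' @param estimate_rates optimize exchangeabilities during ML fits
#'   (default: yes for nucleotide data).
#' @return a list of class \code{experiment_config}.
#' @export
experiment_config <- function(experiment = c("divergence", "otu_scaling",
                                             "polytomy", "felsenstein"),
                              type = c("nt", "aa"),
                              replicates = 200L,
                              seed = 1L,
                              tree_lengths = c(0.5, 1, 2, 3, 4, 5, 6),
                              root_lengths = c(102L, 204L, 408L, 816L),
                              otu_counts = c(8L, 64L, 512L),
                              alpha_grid = seq(0.025, 0.25, by = 0.025),
                              beta_grid = seq(0.25, 1.375, by = 0.125),
                              ntaxa = 8L,
                              aligners = c("true", "builtin"),
                              indel_rate = 0.05,
                              n_bootstrap = 1000L,
                              estimate_rates = NULL) {
  experiment <- match.arg(experiment)
  type <- match.arg(type)
  stopifnot(replicates >= 1)
  aligners <- match.arg(aligners, c("true", "builtin"), several.ok = TRUE)
  if (is.null(estimate_rates)) estimate_rates <- type == "nt"
  structure(list(experiment = experiment, type = type,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 tree_lengths = tree_lengths, root_lengths = root_lengths,
                 otu_counts = otu_counts, alpha_grid = alpha_grid,
                 beta_grid = beta_grid, ntaxa = as.integer(ntaxa),
                 aligners = aligners, indel_rate = indel_rate,
                 n_bootstrap = as.integer(n_bootstrap),
                 estimate_rates = estimate_rates),
            class = "experiment_config")
}

# study substitution model + gamma + indels for a config
config_model <- function(config) {
  model <- if (config$type == "nt") build_gtr() else build_empirical_aa()
  list(model = model,
       gamma = discretize_gamma(1.8, 4),
       indels = indel_params(rel_rate = config$indel_rate,
                             max_length = if (config$type == "aa") 20L else 60L))
}

config_root_length <- function(config, root_aa) {
  if (config$type == "aa") as.integer(root_aa) else 3L * as.integer(root_aa)
}

# deterministic per-replicate seed below 2^31
derive_seed <- function(master, condition, rep) {
  (as.integer(master) + 100003L * (condition - 1L) + rep) %% 2147483647L
}

# the MSA of one arm for a replicate's simulation
arm_msa <- function(arm, sim, model) {
  if (arm == "true") return(sim$alignment)
  progressive_align(sim$seqs, model)$msa
}

#' Divergence-bias experiment on the balanced tree
#'
#' For each tree length and replicate: simulate on the 8-taxon balanced
#' tree, align (per arm), fit branch lengths by ML on the generating
#' topology, and record the inferred tree length, per-branch-class
#' estimates, alignment distance from the truth, and the cumulative
#' branch-length error sum(|estimate - truth|).
#'
#' @param config an \code{experiment_config} (experiment "divergence").
#' @param root_aa root length in amino-acid units (default 408).
#' @return list with \code{replicates} (one row per replicate x condition x
#'   arm x branch summary) and \code{summary} (one row per condition x arm:
#'   median inferred tree length, branch-class quartiles, mean MSA distance,
#'   mean cumulative error).
#' @export
run_divergence <- function(config, root_aa = 408L) {
  mg <- config_model(config)
  root_len <- config_root_length(config, root_aa)
  rows <- list()
  for (ci in seq_along(config$tree_lengths)) {
    L <- config$tree_lengths[ci]
    tree <- make_balanced_tree(L)
    for (r in seq_len(config$replicates)) {
      sim <- simulate_sequences(tree, mg$model, mg$gamma, mg$indels,
                                root_len, derive_seed(config$seed, ci, r))
      for (arm in config$aligners) {
        msa <- arm_msa(arm, sim, mg$model)
        fit <- fit_branch_lengths(msa, tree, mg$model, mg$gamma,
                                  estimate_rates = config$estimate_rates)
        bt <- branch_estimates(fit$tree, tree)
        rows[[length(rows) + 1L]] <- data.frame(
          tree_length = L, replicate = r, arm = arm,
          inferred_tree_length = sum(fit$tree$edge.length),
          cumulative_error = sum(abs(bt$estimate - bt$truth)),
          msa_dist = if (arm == "true") 0 else msa_distance(msa, sim$alignment),
          shape = fit$shape,
          t(setNames(vapply(split(bt$estimate, bt$class), mean, numeric(1)),
                     paste0("mean_", names(split(bt$estimate, bt$class))))))
      }
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, list(reps$tree_length, reps$arm),
                                      drop = TRUE), function(d) {
    data.frame(tree_length = d$tree_length[1], arm = d$arm[1],
               median_tree_length = median(d$inferred_tree_length),
               mean_msa_dist = mean(d$msa_dist),
               mean_cumulative_error = mean(d$cumulative_error))
  }))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}

# match estimated branch lengths to true branches via canonical splits
branch_estimates <- function(est_tree, true_tree) {
  cls <- attr(true_tree, "branch_class")
  if (is.null(cls)) cls <- classify_balanced_edges(true_tree)
  key <- function(tr, e) {
    tips <- tr$tip.label[tips_below(tr, tr$edge[e, 2])]
    side <- sort(tips)
    other <- sort(setdiff(tr$tip.label, tips))
    paste(if (paste(side, collapse = ",") < paste(other, collapse = ","))
      side else other, collapse = ",")
  }
  tk <- vapply(seq_len(nrow(true_tree$edge)), key, character(1), tr = true_tree)
  ek <- vapply(seq_len(nrow(est_tree$edge)), key, character(1), tr = est_tree)
  m <- match(tk, ek)
  data.frame(class = cls, truth = true_tree$edge.length,
             estimate = est_tree$edge.length[m])
}

#' Branch-class quartile summary
#'
#' Lower quartile, median and upper quartile of estimated branch lengths
#' per (condition, branch class), with the simulated value, from the
#' replicate-level output of \code{\link{run_divergence}}.
#'
#' @param divergence_result the list returned by \code{run_divergence}.
#' @return data frame, one row per tree length x arm x branch class.
#' @export
branch_class_summary <- function(divergence_result) {
  d <- divergence_result$replicates
  cls <- c("external", "middle", "root")
  out <- list()
  for (g in split(d, list(d$tree_length, d$arm), drop = TRUE)) {
    for (cl in cls) {
      col <- paste0("mean_", cl)
      if (!col %in% names(g)) next
      q <- quantile(g[[col]], c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        tree_length = g$tree_length[1], arm = g$arm[1], class = cl,
        expected = g$tree_length[1] / 13,
        lq = q[1], median = q[2], uq = q[3])
    }
  }
  do.call(rbind, out)
}

#' OTU-scaling experiment
#'
#' Embeds the 8-taxon balanced core tree (tree length 6) in supertrees of
#' 8, 64 or 512 OTUs, simulates on the full tree, aligns all sequences,
#' extracts the core-taxon subalignment, and fits the core tree by ML.
#' The true-alignment arm is invariant to the number of OTUs by
#' construction; guide-tree-based alignment is not.
#'
#' @param config an \code{experiment_config} (experiment "otu_scaling").
#' @param core_tree_length total length of the embedded core tree
#'   (default 6).
#' @param root_aa root length in amino-acid units (default 408).
#' @return list with \code{replicates} and \code{summary} (per OTU count x
#'   arm: median core tree length, mean alignment length).
#' @export
run_otu_scaling <- function(config, core_tree_length = 6, root_aa = 408L) {
  mg <- config_model(config)
  root_len <- config_root_length(config, root_aa)
  core <- make_balanced_tree(core_tree_length)
  rows <- list()
  for (ci in seq_along(config$otu_counts)) {
    n <- config$otu_counts[ci]
    tree <- if (n == 8L) core
            else embed_in_supertree(core, n, seed = config$seed + ci)
    for (r in seq_len(config$replicates)) {
      sim <- simulate_sequences(tree, mg$model, mg$gamma, mg$indels,
                                root_len, derive_seed(config$seed, ci, r))
      for (arm in config$aligners) {
        full <- arm_msa(arm, sim, mg$model)
        sub <- extract_subalignment(full, core$tip.label)
        fit <- fit_branch_lengths(sub, core, mg$model, mg$gamma,
                                  estimate_rates = config$estimate_rates)
        rows[[length(rows) + 1L]] <- data.frame(
          n_otu = n, replicate = r, arm = arm,
          inferred_tree_length = sum(fit$tree$edge.length),
          alignment_length = alignment_length(sub))
      }
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, list(reps$n_otu, reps$arm),
                                      drop = TRUE), function(d)
    data.frame(n_otu = d$n_otu[1], arm = d$arm[1],
               median_tree_length = median(d$inferred_tree_length),
               mean_alignment_length = mean(d$alignment_length))))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}

#' Polytomy-resolution experiment
#'
#' Simulates on the multifurcating study tree, resolves the polytomy into
#' its three candidate topologies, selects among them by ML with the
#' equal-weight tie rule, and applies the RELL SH test to the candidates;
#' records the frequency of the long-branch-attraction resolution and the
#' per-class SH rejection rates, per root length and arm.
#'
#' @param config an \code{experiment_config} (experiment "polytomy").
#' @param short_branch,long_branch polytomy branch lengths (0.06, 0.7).
#' @return list with \code{replicates} (per replicate: candidate weights,
#'   SH p-values) and \code{summary} (per root length x arm: LBA resolution
#'   frequency, per-resolution frequencies, SH rejection rates for LBA and
#'   non-LBA candidates).
#' @export
run_polytomy <- function(config, short_branch = 0.06, long_branch = 0.7) {
  mg <- config_model(config)
  tree <- make_polytomy_tree(short_branch, long_branch)
  cands <- resolve_polytomy(tree)
  lba <- attr(cands, "lba")
  labels <- ifelse(seq_along(cands) == lba, "LBA", "non-LBA")
  rows <- list()
  for (ci in seq_along(config$root_lengths)) {
    root_len <- config_root_length(config, config$root_lengths[ci])
    for (r in seq_len(config$replicates)) {
      seed_r <- derive_seed(config$seed, ci, r)
      sim <- simulate_sequences(tree, mg$model, mg$gamma, mg$indels,
                                root_len, seed_r)
      for (arm in config$aligners) {
        msa <- arm_msa(arm, sim, mg$model)
        sel <- select_topology(msa, cands, mg$model, mg$gamma,
                               estimate_rates = config$estimate_rates)
        slm <- do.call(rbind, lapply(sel$fits, `[[`, "site_lnl"))
        sh <- sh_test(slm, config$n_bootstrap, seed = seed_r)
        rows[[length(rows) + 1L]] <- data.frame(
          root_aa = config$root_lengths[ci], root_length = root_len,
          replicate = r, arm = arm,
          w1 = sel$weights[1], w2 = sel$weights[2], w3 = sel$weights[3],
          lba_weight = sel$weights[lba],
          p1 = sh$p[1], p2 = sh$p[2], p3 = sh$p[3],
          rej_lba = sum(sh$rejected[labels == "LBA"]),
          rej_nonlba = sum(sh$rejected[labels == "non-LBA"]))
      }
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, list(reps$root_aa, reps$arm),
                                      drop = TRUE), function(d)
    data.frame(root_aa = d$root_aa[1], root_length = d$root_length[1],
               arm = d$arm[1],
               lba_freq = mean(d$lba_weight),
               freq1 = mean(d$w1), freq2 = mean(d$w2), freq3 = mean(d$w3),
               sh_reject_lba = mean(d$rej_lba),
               sh_reject_nonlba = mean(d$rej_nonlba) / 2,
               sh_reject_all = mean((d$rej_lba + d$rej_nonlba) / 3))))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ, lba_candidate = lba)
}

#' Felsenstein-zone grid experiment
#'
#' For each (alpha, beta) cell of the subtree-depth grid, simulates on the
#' Felsenstein-zone tree and scores how often each arm recovers the correct
#' topology among the three arrangements of the four subtrees: ML on the
#' true alignment, maximum parsimony on the true alignment, and ML on the
#' built-in aligner's MSA (per \code{config$aligners}).
#'
#' @param config an \code{experiment_config} (experiment "felsenstein").
#' @param root_aa root length in amino-acid units (default 408).
#' @param arms subset of \code{c("true-ML", "true-MP", "builtin-ML")}.
#' @return list with \code{replicates} and \code{summary} (per cell x arm:
#'   frequency of the correct and of the LBA topology).
#' @export
run_felsenstein <- function(config, root_aa = 408L,
                            arms = c("true-ML", "true-MP")) {
  mg <- config_model(config)
  root_len <- config_root_length(config, root_aa)
  rows <- list()
  ci <- 0L
  for (a in config$alpha_grid) for (b in config$beta_grid) {
    ci <- ci + 1L
    tree <- make_felsenstein_tree(a, b, internal_branch = a,
                                  ntaxa = config$ntaxa)
    cands <- felsenstein_candidates(tree)
    lba <- attr(cands, "lba")
    for (r in seq_len(config$replicates)) {
      sim <- simulate_sequences(tree, mg$model, mg$gamma, mg$indels,
                                root_len, derive_seed(config$seed, ci, r))
      for (arm in arms) {
        msa <- if (arm == "builtin-ML") arm_msa("builtin", sim, mg$model)
               else sim$alignment
        sel <- if (arm == "true-MP") mp_select(msa, cands)
               else select_topology(msa, cands, mg$model, mg$gamma,
                                    estimate_rates = config$estimate_rates)
        rows[[length(rows) + 1L]] <- data.frame(
          alpha = a, beta = b, replicate = r, arm = arm,
          w_correct = sel$weights[1], w_lba = sel$weights[lba])
      }
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, list(reps$alpha, reps$beta,
                                                 reps$arm), drop = TRUE),
                                function(d)
    data.frame(alpha = d$alpha[1], beta = d$beta[1], arm = d$arm[1],
               freq_correct = mean(d$w_correct),
               freq_lba = mean(d$w_lba))))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}
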