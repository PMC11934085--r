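#' Engine validation experiments
#'
#' Standardized synthetic-community experiments for validating the inference
#' engine: error-rate calibration on independent communities, per-metric
#' p-value uniformity under the ReBoot null, and recovery of planted
#' associations. These run the full pipeline (read sampling, prevalence
#' filtering, indexing, ensembling, inference) exactly as an analysis would.
#'
#' @name engine_validation
NULL

# full synthetic pipeline from params to an inferred network
synthetic_inference <- function(params, config, depth_scale = 1) {
  truth <- generate_community(params)
  tabs <- sample_reads(truth, depth_scale = depth_scale)
  filt <- lapply(tabs, prevalence_filter)
  idx <- Reduce(ensemble_index, lapply(filt, compute_edna_index))
  list(truth = truth, index = idx, network = infer_network(idx, config))
}

#' @rdname engine_validation
#' @details `null_calibration()` runs the pipeline on fully independent
#'   communities (no planted associations, no environmental gradients) and
#'   reports, per seed, the number of reported edges over the number of
#'   candidate edges — every reported edge is a false discovery here, so the
#'   mean ratio is the empirical false-discovery proxy the q-threshold is
#'   supposed to control.
#' @param n_seeds number of independent replicate communities.
#' @param n_otus,n_samples community dimensions.
#' @param master_seed seed from which per-replicate seeds derive.
#' @param config a [cooc_config()]; its seed field is overridden per
#'   replicate.
#' @return `null_calibration()`: list with `per_seed` (data frame: seed,
#'   n_edges, n_candidates, fdr) and `mean_fdr`.
#' @export
null_calibration <- function(n_seeds = 20, n_otus = 40, n_samples = 60,
                             master_seed = 1, config = cooc_config()) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    seed_i <- pair_seed(master_seed, "calibration", as.character(i))
    params <- community_params(n_otus = n_otus, n_samples = n_samples,
                               n_env_gradients = 0, seed = seed_i)
    config$seed <- seed_i
    run <- synthetic_inference(params, config)
    data.frame(seed = seed_i, n_edges = nrow(run$network$edges),
               n_candidates = run$network$n_candidates,
               fdr = if (run$network$n_candidates)
                 nrow(run$network$edges) / run$network$n_candidates else 0)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, mean_fdr = mean(per_seed$fdr))
}

#' @rdname engine_validation
#' @details `pvalue_uniformity()` tests a sample of OTU pairs with the full
#'   per-metric ReBoot machinery on independent null communities and returns
#'   each metric's Kolmogorov-Smirnov distance from the uniform distribution
#'   — the p-values of a calibrated test on null data are uniform. Pairs are
#'   drawn across several replicate communities because pairs within one
#'   community share its compositional denominator, so their p-values are
#'   positively dependent and a single-community KS statistic measures that
#'   shared fluctuation rather than the marginal calibration of the test.
#' @param n_pairs total number of OTU pairs tested.
#' @param n_communities number of independent replicate communities the
#'   pairs are spread over.
#' @param seed RNG seed.
#' @return `pvalue_uniformity()`: list with `ks` (named per-metric KS
#'   distances) and `pvalues` (metrics x pairs matrix).
#' @export
pvalue_uniformity <- function(n_pairs = 200, n_otus = 40, n_samples = 60,
                              n_communities = 10, seed = 1,
                              config = cooc_config()) {
  mets <- config$metrics
  params_m <- list(kld_pseudocount = config$kld_pseudocount,
                   mi_bins = config$mi_bins)
  per_comm <- ceiling(n_pairs / n_communities)
  pv <- NULL
  for (cm in seq_len(n_communities)) {
    params <- community_params(n_otus = n_otus, n_samples = n_samples,
                               n_env_gradients = 0, rare_fraction = 0,
                               seed = pair_seed(seed, "uniformity",
                                                as.character(cm)))
    truth <- generate_community(params)
    tabs <- sample_reads(truth)
    filt <- lapply(tabs, prevalence_filter)
    idx <- Reduce(ensemble_index, lapply(filt, compute_edna_index))
    ids <- rownames(idx$values)
    pairs <- utils::combn(ids, 2)
    sel <- with_local_seed(params$seed,
                           sample(ncol(pairs), min(per_comm, ncol(pairs))))
    pv_cm <- vapply(sel, function(ci) {
      a <- pairs[1, ci]; b <- pairs[2, ci]
      tst <- reboot_pair_test(idx, a, b, mets, n_perm = config$n_perm,
                              n_boot = config$n_boot,
                              seed = pair_seed(params$seed, a, b),
                              params = params_m)
      tst$metrics$p
    }, numeric(length(mets)))
    pv <- cbind(pv, matrix(pv_cm, nrow = length(mets)))
  }
  pv <- pv[, seq_len(min(n_pairs, ncol(pv))), drop = FALSE]
  rownames(pv) <- mets
  ks <- apply(pv, 1, function(p)
    suppressWarnings(stats::ks.test(p, "punif"))$statistic)
  list(ks = ks, pvalues = pv)
}

#' @rdname engine_validation
#' @details `recovery_experiment()` plants positive and negative pairwise
#'   associations of a given strength in a study-scale community, runs the
#'   pipeline, and scores recall and per-sign accuracy.
#' @param n_pos,n_neg numbers of planted co-presence / exclusion pairs.
#' @param strength planted association strength in \[0, 1\].
#' @return `recovery_experiment()`: the [recovery_metrics()] list augmented
#'   with `recall_copresence`, `recall_exclusion`, `sign_accuracy_copresence`
#'   and `sign_accuracy_exclusion`.
#' @export
recovery_experiment <- function(n_otus = 120, n_samples = 60,
                                n_pos = 20, n_neg = 10, strength = 0.9,
                                seed = 1, config = cooc_config()) {
  planted <- plant_random_edges(n_otus, n_pos, n_neg, strength = strength,
                                seed = seed)
  params <- community_params(n_otus = n_otus, n_samples = n_samples,
                             planted_edges = planted, seed = seed)
  config$seed <- seed
  run <- synthetic_inference(params, config)
  out <- recovery_metrics(run$network, run$truth)
  pe <- run$truth$planted_edges
  inf_key <- pair_key(run$network$edges$otu_a, run$network$edges$otu_b)
  for (s in c("+", "-")) {
    lbl <- if (s == "+") "copresence" else "exclusion"
    sub <- pe[pe$sign == s & pe$otu_a %in% run$network$community &
                pe$otu_b %in% run$network$community, , drop = FALSE]
    skey <- pair_key(sub$otu_a, sub$otu_b)
    hit <- inf_key %in% skey
    out[[paste0("recall_", lbl)]] <-
      if (length(skey)) sum(hit) / length(skey) else NA_real_
    out[[paste0("sign_accuracy_", lbl)]] <-
      if (sum(hit)) mean(run$network$edges$sign[hit] == lbl) else NA_real_
  }
  out$network <- run$network
  out$truth <- run$truth
  out
}
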