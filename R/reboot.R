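#' Inference configuration for co-occurrence networks
#'
#' Bundles every tunable of the ensemble + ReBoot inference pipeline. The
#' defaults follow the source protocol: all five metrics, top/bottom 500
#' edges retained per metric, edges kept when supported by at least two
#' metrics, 100 renormalized permutations and 100 bootstrap resamples per
#' edge and metric, and a Benjamini-Hochberg q-value cutoff of 0.05.
#'
#' @param metrics metrics to use (see [assoc_metric_names()]).
#' @param top_k,bottom_k number of highest/lowest scoring pairs retained per
#'   metric at tail selection.
#' @param min_support minimum number of selecting metrics for a candidate.
#' @param n_perm permutation-null iterations per edge and metric.
#' @param n_boot bootstrap iterations per edge and metric.
#' @param q_threshold BH q-value cutoff for reported edges.
#' @param mi_bins equal-frequency bins for mutual information.
#' @param kld_pseudocount pseudocount for the symmetrized KLD.
#' @param seed master RNG seed; per-(pair) substreams are derived from it by
#'   stable hashing so results do not depend on iteration order.
#' @return A list of class `cooc_config`.
#' @export
cooc_config <- function(metrics = assoc_metric_names(),
                        top_k = 500, bottom_k = 500, min_support = 2,
                        n_perm = 100, n_boot = 100, q_threshold = 0.05,
                        mi_bins = 4, kld_pseudocount = 1e-8, seed = 1) {
  stopifnot(top_k >= 0, bottom_k >= 0, min_support >= 1,
            n_perm >= 2, n_boot >= 2,
            q_threshold > 0, q_threshold <= 1, seed >= 0)
  structure(list(metrics = metrics, top_k = top_k, bottom_k = bottom_k,
                 min_support = min_support, n_perm = n_perm, n_boot = n_boot,
                 q_threshold = q_threshold, mi_bins = mi_bins,
                 kld_pseudocount = kld_pseudocount, seed = as.integer(seed)),
            class = "cooc_config")
}

# deterministic 31-polynomial string hash in [0, 2^31 - 2]
stable_hash_int <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

# per-pair RNG substream seed derived from the master seed
pair_seed <- function(master_seed, otu_a, otu_b) {
  h <- stable_hash_int(paste(otu_a, otu_b, sep = "\r"))
  as.integer((as.double(master_seed) * 2654435 + h) %% 2147483647)
}

# run `expr` under a local RNG seeded with `seed`, restoring global state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# column-wise ranks with ties broken by row order (single radix sort)
col_ranks_first <- function(X) {
  n <- nrow(X)
  o <- order(col(X), X, method = "radix")
  r <- integer(length(X))
  r[o] <- rep(seq_len(n), ncol(X))
  matrix(r, n, ncol(X))
}

# column-wise average (midrank) ranks: mean of the forward and reversed
# first-rankings, which averages each tie group exactly
col_ranks_avg <- function(X) {
  n <- nrow(X)
  rf <- col_ranks_first(X)
  rl <- col_ranks_first(X[n:1, , drop = FALSE])[n:1, , drop = FALSE]
  (rf + rl) / 2
}

# column-wise metric scores on aligned matrices (samples x iterations);
# column t of XA/XB is one permuted/resampled realization of the pair
col_metric_scores <- function(metric, XA, XB, params) {
  switch(metric,
    pearson = {
      A <- sweep(XA, 2, colMeans(XA))
      B <- sweep(XB, 2, colMeans(XB))
      va <- colSums(A * A); vb <- colSums(B * B)
      out <- colSums(A * B) / sqrt(va * vb)
      out[va == 0 | vb == 0] <- NA_real_
      out
    },
    spearman = col_metric_scores("pearson", col_ranks_avg(XA),
                                 col_ranks_avg(XB), params),
    bray_curtis = {
      s <- colSums(XA + XB)
      out <- colSums(abs(XA - XB)) / s
      out[s == 0] <- NA_real_
      out
    },
    kld = {
      PA <- XA + params$kld_pseudocount
      PB <- XB + params$kld_pseudocount
      PA <- sweep(PA, 2, colSums(PA), "/")
      PB <- sweep(PB, 2, colSums(PB), "/")
      colSums(PA * log(PA / PB)) + colSums(PB * log(PB / PA))
    },
    mutual_information = {
      n <- nrow(XA); m <- ncol(XA); B <- params$mi_bins
      const <- (apply(XA, 2, max) == apply(XA, 2, min)) |
        (apply(XB, 2, max) == apply(XB, 2, min))
      ba <- ceiling(col_ranks_first(XA) * B / n)
      bb <- ceiling(col_ranks_first(XB) * B / n)
      colshift <- rep(seq_len(m) - 1L, each = n)
      joint <- matrix(tabulate(ba + B * (bb - 1L) + B * B * colshift,
                               nbins = B * B * m), B * B, m) / n
      px <- matrix(tabulate(ba + B * colshift, nbins = B * m), B, m) / n
      py <- matrix(tabulate(bb + B * colshift, nbins = B * m), B, m) / n
      ind <- joint * log2(joint / (px[rep(seq_len(B), B), , drop = FALSE] *
                                   py[rep(seq_len(B), each = B), ,
                                      drop = FALSE]))
      ind[joint == 0] <- 0
      out <- colSums(ind)
      out[const] <- 0
      out
    },
    stop("unknown metric: ", metric))
}

# a pair's index profiles evaluated through the renormalization functional
# (identity permutation); identical to the stored index values whenever the
# compositional matrix is exactly column-stochastic (single-marker tables)
pair_observed_vectors <- function(index, otu_a, otu_b) {
  comp <- index$comp
  n <- ncol(comp)
  ca <- comp[otu_a, ]; cb <- comp[otu_b, ]
  resid <- colSums(comp) - ca - cb
  idm <- matrix(seq_len(n), ncol = 1)
  re <- reboot_realizations(ca, cb, resid, idm, idm)
  list(xa = re$XA[, 1], xb = re$XB[, 1])
}

# permuted + renormalized index realizations for one OTU pair.
# ca, cb: compositional rows; resid: column sums of comp minus ca minus cb.
# pa_idx, pb_idx: samples x iterations permutation index matrices.
reboot_realizations <- function(ca, cb, resid, pa_idx, pb_idx) {
  n <- length(ca)
  CA <- matrix(ca[pa_idx], nrow = n)
  CB <- matrix(cb[pb_idx], nrow = n)
  D <- resid + CA + CB          # renormalized per-sample totals
  WA <- CA / D
  WB <- CB / D
  # re-apply the index max-scaling per realization
  XA <- WA / rep(apply(WA, 2, max), each = n)
  XB <- WB / rep(apply(WB, 2, max), each = n)
  list(XA = XA, XB = XB)
}

#' ReBoot permutation null for one OTU pair
#'
#' For each iteration the two OTUs' compositional profiles are independently
#' permuted across samples, the per-sample compositional closure is
#' recomputed over the whole community with the permuted rows in place
#' (destroying the pair's dependence while preserving the spurious
#' correlation structure induced by compositionality), the eDNA-index
#' max-scaling is re-applied, and the association score is recomputed. The
#' same permutations are used for every requested metric, so null replicates
#' are aligned across metrics (as Brown's empirical variance estimate
#' requires).
#'
#' @param index an `index_table`.
#' @param otu_a,otu_b OTU identifiers.
#' @param metrics metrics to evaluate.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed for this pair's substream (see [pair_seed()]
#'   derivation inside [infer_network()]).
#' @param params metric parameters (see [default_metric_params()]).
#' @return Numeric matrix `n_perm x length(metrics)` of null scores.
#' @export
reboot_null <- function(index, otu_a, otu_b, metrics = assoc_metric_names(),
                        n_perm = 100, seed = 1,
                        params = default_metric_params()) {
  stopifnot(inherits(index, "index_table"))
  comp <- index$comp
  n <- ncol(comp)
  ca <- comp[otu_a, ]; cb <- comp[otu_b, ]
  resid <- colSums(comp) - ca - cb
  draw <- function(k) matrix(
    unlist(lapply(seq_len(k), function(i) sample.int(n))), nrow = n)
  with_local_seed(seed, {
    pa <- draw(n_perm); pb <- draw(n_perm)
    re <- reboot_realizations(ca, cb, resid, pa, pb)
    out <- vapply(metrics, function(m)
      col_metric_scores(m, re$XA, re$XB, params), numeric(n_perm))
    out <- matrix(out, nrow = n_perm, dimnames = list(NULL, metrics))
    bad <- which(rowSums(is.na(out)) > 0)
    if (length(bad)) {        # resample degenerate iterations once
      pa2 <- draw(length(bad)); pb2 <- draw(length(bad))
      re2 <- reboot_realizations(ca, cb, resid, pa2, pb2)
      out[bad, ] <- vapply(metrics, function(m)
        col_metric_scores(m, re2$XA, re2$XB, params), numeric(length(bad)))
      if (anyNA(out))
        stop(sprintf("metric undefined under permutation for pair %s-%s",
                     otu_a, otu_b))
    }
    out
  })
}

#' Bootstrap score sample for one OTU pair
#'
#' Resamples the samples (columns) with replacement and recomputes each
#' metric on the pair's index profiles (taken on the same renormalized scale
#' as the permutation null, so the stability comparison is like-for-like);
#' used for the stability screen (an edge is kept only when the
#' permutation-null mean falls outside the central 95% of its bootstrap
#' distribution).
#'
#' @inheritParams reboot_null
#' @param n_boot number of bootstrap resamples (default 100).
#' @return Numeric matrix `n_boot x length(metrics)` of bootstrap scores.
#' @export
bootstrap_scores <- function(index, otu_a, otu_b,
                             metrics = assoc_metric_names(),
                             n_boot = 100, seed = 1,
                             params = default_metric_params()) {
  stopifnot(inherits(index, "index_table"))
  obs <- pair_observed_vectors(index, otu_a, otu_b)
  xa <- obs$xa; xb <- obs$xb
  n <- length(xa)
  draw <- function(k) matrix(sample.int(n, n * k, replace = TRUE), nrow = n)
  with_local_seed(seed + 1L, {
    idx <- draw(n_boot)
    XA <- matrix(xa[idx], nrow = n); XB <- matrix(xb[idx], nrow = n)
    out <- vapply(metrics, function(m)
      col_metric_scores(m, XA, XB, params), numeric(n_boot))
    out <- matrix(out, nrow = n_boot, dimnames = list(NULL, metrics))
    bad <- which(rowSums(is.na(out)) > 0)
    if (length(bad)) {
      idx2 <- draw(length(bad))
      XA2 <- matrix(xa[idx2], nrow = n); XB2 <- matrix(xb[idx2], nrow = n)
      out[bad, ] <- vapply(metrics, function(m)
        col_metric_scores(m, XA2, XB2, params), numeric(length(bad)))
      if (anyNA(out))
        stop(sprintf("metric undefined under bootstrap for pair %s-%s",
                     otu_a, otu_b))
    }
    out
  })
}

#' Gaussian-tail p-value and bootstrap stability for one metric
#'
#' The p-value is the two-sided tail probability of the observed score under
#' a Gaussian fitted to the permutation null (mean and SD); a Gaussian fit is
#' used rather than the empirical rank because 100 permutations cap the
#' empirical resolution at ~0.01 while BH correction needs finer
#' granularity. Stability passes when the null mean lies outside the central
#' 95% percentile interval of the bootstrap sample.
#'
#' @param observed observed metric score.
#' @param null_sample numeric vector of permutation-null scores.
#' @param boot_sample numeric vector of bootstrap scores.
#' @return List with `p` (two-sided p-value), `stable` (logical) and the
#'   fitted null `mean` and `sd`.
#' @export
metric_pvalue <- function(observed, null_sample, boot_sample) {
  stopifnot(length(null_sample) > 1, length(boot_sample) > 1)
  mu <- mean(null_sample)
  sdv <- stats::sd(null_sample)
  p <- if (sdv == 0) {
    if (observed == mu) 1 else 1 / (length(null_sample) + 1)
  } else {
    2 * stats::pnorm(-abs((observed - mu) / sdv))
  }
  ci <- stats::quantile(boot_sample, c(0.025, 0.975), names = FALSE)
  list(p = p, stable = (mu < ci[1] || mu > ci[2]), mean = mu, sd = sdv)
}

#' Brown's method with empirical null variance
#'
#' Merges k dependent p-values via the scaled chi-square approximation to
#' `X = -2 sum log(p_i)`: with `E = 2k` and `V` the variance of X, the merged
#' p-value is the upper tail of `c * chisq(f)` at X, where `c = V / (2E)` and
#' `f = 2 E^2 / V`. Instead of the textbook correlation polynomial, `V` is
#' estimated empirically as the variance of X over aligned null p-value
#' replicates (the same permutations scored by every metric), which handles
#' the mixed metric types directly. With independent p-values
#' (`V -> 4k`) the method reduces to Fisher's.
#'
#' @param pvals numeric vector of k per-metric p-values in (0, 1\]; zeros are
#'   clamped to `1 / (n_null + 1)`.
#' @param null_pvals matrix of aligned null p-value replicates
#'   (iterations x k) used to estimate `V`; if `NULL`, Fisher's
#'   independence limit is used.
#' @return List with merged `p`, scale `c`, df `f` and statistic `X`.
#' @export
brown_merge <- function(pvals, null_pvals = NULL) {
  k <- length(pvals)
  stopifnot(k >= 1, all(pvals >= 0), all(pvals <= 1))
  n_null <- if (is.null(null_pvals)) 100 else nrow(null_pvals)
  clamp <- 1 / (n_null + 1)
  pvals <- pmax(pvals, clamp)
  if (k == 1) return(list(p = pvals, c = NA_real_, f = NA_real_,
                          X = -2 * log(pvals)))
  X <- -2 * sum(log(pvals))
  E <- 2 * k
  V <- if (is.null(null_pvals)) 4 * k else {
    stopifnot(ncol(null_pvals) == k)
    Xn <- -2 * rowSums(log(pmax(null_pvals, clamp)))
    stats::var(Xn)
  }
  if (!is.finite(V) || V <= 0) V <- 4 * k   # degenerate null: Fisher limit
  cc <- V / (2 * E)
  f <- 2 * E^2 / V
  list(p = stats::pchisq(X / cc, df = f, lower.tail = FALSE),
       c = cc, f = f, X = X)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH q-values with monotonicity enforcement,
#' order-preserving (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Tail selection of candidate edges
#'
#' Per metric, marks the `top_k` highest-scoring and `bottom_k`
#' lowest-scoring pairs as selected (ties at the boundary resolved in favour
#' of the lexicographically smaller pair id). Directions: correlations keep
#' their sign-based direction in either tail; dissimilarities become
#' co-presence in the bottom tail and exclusion in the top tail (a pair
#' falling in both tails, possible when `top_k + bottom_k` exceeds the
#' number of pairs, contributes unsigned support); mutual information selects
#' from the top tail only and is always unsigned.
#'
#' @param scores pair-score data frame from [score_all_pairs()].
#' @param top_k,bottom_k tail sizes per metric (defaults 500/500).
#' @return The scores data frame with logical columns `in_top`, `in_bottom`,
#'   `selected`, and tail-resolved `direction`.
#' @export
select_tails <- function(scores, top_k = 500, bottom_k = 500) {
  scores$in_top <- FALSE
  scores$in_bottom <- FALSE
  for (m in unique(scores$metric)) {
    rows <- which(scores$metric == m)
    sc <- scores$score[rows]
    ord_top <- rows[order(-sc, scores$otu_a[rows], scores$otu_b[rows])]
    ord_bot <- rows[order(sc, scores$otu_a[rows], scores$otu_b[rows])]
    scores$in_top[ord_top[seq_len(min(top_k, length(rows)))]] <- TRUE
    scores$in_bottom[ord_bot[seq_len(min(bottom_k, length(rows)))]] <- TRUE
  }
  diss <- scores$metric %in% c("bray_curtis", "kld")
  scores$direction[diss & scores$in_bottom & !scores$in_top] <- "copresence"
  scores$direction[diss & scores$in_top & !scores$in_bottom] <- "exclusion"
  scores$direction[diss & scores$in_top & scores$in_bottom] <- "unsigned"
  scores$selected <- ifelse(scores$metric == "mutual_information",
                            scores$in_top, scores$in_top | scores$in_bottom)
  scores
}

#' Consensus filter over metrics
#'
#' Keeps pairs selected by at least `min_support` metrics whose signed
#' directions are unanimous; at least one signed metric is required to give
#' the edge its sign (unsigned support alone — mutual information, or a
#' dissimilarity present in both tails — cannot). Pairs with conflicting
#' signed directions are dropped and logged in the `"dropped"` attribute.
#'
#' @param tails output of [select_tails()].
#' @param min_support minimum number of selecting metrics (default 2).
#' @return data frame of candidate pairs with columns `otu_a`, `otu_b`,
#'   `sign`, `support`, `metrics` (comma-joined); the per-metric selected
#'   rows are attached as attribute `"per_metric"`.
#' @export
consensus_filter <- function(tails, min_support = 2) {
  sel <- tails[tails$selected, , drop = FALSE]
  key <- paste(sel$otu_a, sel$otu_b, sep = "\r")
  keep <- list(); dropped <- list()
  for (k in unique(key)) {
    rows <- sel[key == k, , drop = FALSE]
    support <- nrow(rows)
    signed <- unique(rows$direction[rows$direction != "unsigned"])
    if (support < min_support) {
      dropped[[k]] <- data.frame(otu_a = rows$otu_a[1], otu_b = rows$otu_b[1],
                                 reason = "below_min_support")
    } else if (length(signed) == 0) {
      dropped[[k]] <- data.frame(otu_a = rows$otu_a[1], otu_b = rows$otu_b[1],
                                 reason = "no_signed_metric")
    } else if (length(signed) > 1) {
      dropped[[k]] <- data.frame(otu_a = rows$otu_a[1], otu_b = rows$otu_b[1],
                                 reason = "conflicting_signs")
    } else {
      keep[[k]] <- data.frame(otu_a = rows$otu_a[1], otu_b = rows$otu_b[1],
                              sign = signed, support = support,
                              metrics = paste(rows$metric, collapse = ","))
    }
  }
  out <- if (length(keep)) do.call(rbind, keep) else
    data.frame(otu_a = character(), otu_b = character(), sign = character(),
               support = integer(), metrics = character())
  out <- out[order(out$otu_a, out$otu_b), , drop = FALSE]
  rownames(out) <- NULL
  kept_key <- paste(out$otu_a, out$otu_b, sep = "\r")
  attr(out, "per_metric") <- sel[key %in% kept_key, , drop = FALSE]
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(otu_a = character(), otu_b = character(), reason = character())
  out
}

#' Full significance test for one OTU pair
#'
#' Runs the ReBoot null and the bootstrap for the given metrics, computes the
#' per-metric Gaussian-tail p-values and stability flags, and merges the
#' p-values with [brown_merge()] using the aligned null replicates.
#'
#' @inheritParams reboot_null
#' @param n_boot bootstrap iterations.
#' @param observed named numeric vector of observed scores per metric; if
#'   `NULL`, computed from the index values.
#' @return List with `metrics` (data frame: metric, observed, p, stable,
#'   null_mean, null_sd), `merged_p`, `all_stable`.
#' @export
reboot_pair_test <- function(index, otu_a, otu_b,
                             metrics = assoc_metric_names(),
                             n_perm = 100, n_boot = 100, seed = 1,
                             params = default_metric_params(),
                             observed = NULL) {
  if (is.null(observed)) {
    xa <- index$values[otu_a, ]; xb <- index$values[otu_b, ]
    observed <- vapply(metrics, function(m)
      metric_fun(m, params)(xa, xb), 0)
    names(observed) <- metrics
  }
  # the tested statistic is evaluated through the same renormalization
  # functional as the null, so observed and null scores are exchangeable
  # under independence (they coincide with the plain index scores for
  # single-marker tables)
  ov <- pair_observed_vectors(index, otu_a, otu_b)
  tested <- vapply(metrics, function(m)
    col_metric_scores(m, matrix(ov$xa, ncol = 1),
                      matrix(ov$xb, ncol = 1), params), 0)
  names(tested) <- metrics
  nulls <- reboot_null(index, otu_a, otu_b, metrics, n_perm, seed, params)
  boots <- bootstrap_scores(index, otu_a, otu_b, metrics, n_boot, seed, params)
  per <- lapply(metrics, function(m)
    metric_pvalue(tested[[m]], nulls[, m], boots[, m]))
  names(per) <- metrics
  # aligned null p-value replicates for Brown's empirical variance
  null_p <- vapply(metrics, function(m) {
    mu <- per[[m]]$mean; sdv <- per[[m]]$sd
    if (sdv == 0) rep(1, n_perm) else
      2 * stats::pnorm(-abs((nulls[, m] - mu) / sdv))
  }, numeric(n_perm))
  null_p <- matrix(null_p, nrow = n_perm, dimnames = list(NULL, metrics))
  pv <- vapply(per, `[[`, 0, "p")
  merged <- if (length(metrics) >= 2) brown_merge(pv, null_p)$p else pv[[1]]
  list(metrics = data.frame(
         metric = metrics,
         observed = unname(observed[metrics]),
         p = unname(pv),
         stable = vapply(per, `[[`, TRUE, "stable"),
         null_mean = vapply(per, `[[`, 0, "mean"),
         null_sd = vapply(per, `[[`, 0, "sd")),
       merged_p = unname(merged),
       all_stable = all(vapply(per, `[[`, TRUE, "stable")))
}

#' Infer a signed co-occurrence network
#'
#' The full inference pipeline on one analysis subset: score all pairs with
#' the configured metrics, retain the per-metric score tails, keep pairs
#' supported by at least `min_support` metrics with unanimous sign, test the
#' surviving candidates with the ReBoot permutation-renormalization null and
#' the bootstrap stability screen (an edge failing stability on any
#' supporting metric is discarded), merge per-metric p-values with Brown's
#' method, correct with Benjamini-Hochberg within the network, and retain
#' edges with `q <= q_threshold`.
#'
#' @param index an `index_table` for the (already prevalence-filtered)
#'   community.
#' @param config a [cooc_config()].
#' @return An object of class `cooc_network`: `nodes` (edge endpoints),
#'   `edges` (data frame with sign, support, per-metric scores and p-values,
#'   `merged_p`, `q_value`), `community` (all OTU ids of the input),
#'   `config`, plus candidate/drop provenance.
#' @export
infer_network <- function(index, config = cooc_config()) {
  stopifnot(inherits(index, "index_table"), inherits(config, "cooc_config"))
  params <- list(kld_pseudocount = config$kld_pseudocount,
                 mi_bins = config$mi_bins)
  scores <- score_all_pairs(index, config$metrics, params)
  tails <- select_tails(scores, config$top_k, config$bottom_k)
  cands <- consensus_filter(tails, config$min_support)
  per_metric <- attr(cands, "per_metric")
  results <- vector("list", nrow(cands))
  unstable <- 0L
  for (i in seq_len(nrow(cands))) {
    a <- cands$otu_a[i]; b <- cands$otu_b[i]
    sub <- per_metric[per_metric$otu_a == a & per_metric$otu_b == b, ]
    mets <- sub$metric
    obs <- stats::setNames(sub$score, mets)
    tst <- reboot_pair_test(index, a, b, mets,
                            n_perm = config$n_perm, n_boot = config$n_boot,
                            seed = pair_seed(config$seed, a, b),
                            params = params, observed = obs)
    if (!tst$all_stable) { unstable <- unstable + 1L; next }
    row <- data.frame(otu_a = a, otu_b = b, sign = cands$sign[i],
                      support = cands$support[i], metrics = cands$metrics[i],
                      merged_p = tst$merged_p)
    for (m in config$metrics) {
      row[[paste0("score_", m)]] <-
        if (m %in% mets) obs[[m]] else NA_real_
      row[[paste0("p_", m)]] <-
        if (m %in% mets) tst$metrics$p[tst$metrics$metric == m] else NA_real_
    }
    results[[i]] <- row
  }
  results <- results[!vapply(results, is.null, TRUE)]
  edges <- if (length(results)) do.call(rbind, results) else NULL
  if (!is.null(edges)) {
    edges$q_value <- bh_adjust(edges$merged_p)
    edges <- edges[edges$q_value <= config$q_threshold, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(otu_a = character(), otu_b = character(),
                        sign = character(), support = integer(),
                        metrics = character(), merged_p = numeric(),
                        q_value = numeric())
  }
  structure(list(
    nodes = sort(unique(c(edges$otu_a, edges$otu_b))),
    edges = edges,
    community = rownames(index$values),
    config = config,
    n_candidates = nrow(cands),
    n_unstable = unstable,
    dropped = attr(cands, "dropped")),
    class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf(paste0("<cooc_network> %d nodes, %d edges ",
                     "(%d candidates, %d unstable; community %d OTUs)\n"),
              length(x$nodes), nrow(x$edges), x$n_candidates, x$n_unstable,
              length(x$community)))
  invisible(x)
}

#' Convert networks to igraph
#'
#' @param x a `cooc_network` or `food_web`.
#' @return An igraph graph (undirected for co-occurrence networks, directed
#'   consumer-to-resource for food webs).
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.cooc_network <- function(x) {
  igraph::graph_from_data_frame(
    x$edges[, c("otu_a", "otu_b", setdiff(names(x$edges),
                                          c("otu_a", "otu_b")))],
    directed = FALSE,
    vertices = data.frame(name = x$nodes))
}

#' Write the edge table of a network as TSV
#'
#' Columns: otu_a, otu_b, sign, support, per-metric score and p, merged_p,
#' q_value. Byte-identical across reruns with the same config and seed.
#'
#' @param network a `cooc_network`.
#' @param path output path.
#' @export
write_edge_table <- function(network, path) {
  stopifnot(inherits(network, "cooc_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' @param x a `cooc_network` or `food_web`.
#' @param path output `.graphml` path.
#' @export
write_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(path)
}
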