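#' Pairwise association metrics
#'
#' Five measures of pairwise association between OTU index vectors across
#' samples: Pearson and Spearman correlations, Bray-Curtis dissimilarity,
#' symmetrized Kullback-Leibler (Jeffreys) divergence, and plug-in mutual
#' information on equal-frequency discretizations. Correlations are signed
#' (positive = co-presence, negative = mutual exclusion); the dissimilarities
#' acquire a direction from tail selection (low tail = co-presence, high tail
#' = exclusion); mutual information is unsigned.
#'
#' Undefined scores (constant vectors for the correlations, two all-zero
#' vectors for Bray-Curtis) yield `NA` and are skipped rather than imputed.
#'
#' @param x,y numeric vectors of equal length (index values across samples).
#' @name assoc_metrics
NULL

#' @rdname assoc_metrics
#' @export
assoc_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' @rdname assoc_metrics
#' @export
assoc_spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' @rdname assoc_metrics
#' @export
assoc_bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  s <- sum(x + y)
  if (s == 0) return(NA_real_)
  sum(abs(x - y)) / s
}

#' @rdname assoc_metrics
#' @param pseudocount small positive value added before renormalization so
#'   zero entries have finite divergence; default 1e-8.
#' @export
assoc_kld <- function(x, y, pseudocount = 1e-8) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0),
            pseudocount >= 0)
  p <- x + pseudocount
  q <- y + pseudocount
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q)) + sum(q * log(q / p))
}

# equal-frequency bin labels; ties broken by stable sort on sample order
equal_freq_bins <- function(x, n_bins) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * n_bins / n)
}

#' @rdname assoc_metrics
#' @param n_bins number of equal-frequency bins for the discretization
#'   (>= 2, <= length(x)); default 4, which keeps >= 5 expected observations
#'   per bin at the study's sample sizes (20-60 samples).
#' @return Each metric returns a single numeric score (`NA` if undefined):
#'   correlations in \[-1, 1\], Bray-Curtis in \[0, 1\], KLD >= 0 (nats),
#'   mutual information >= 0 (bits).
#' @export
assoc_mutual_information <- function(x, y, n_bins = 4) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (n_bins > n) stop("n_bins exceeds the number of samples")
  # a constant vector carries no information; forced equal-frequency
  # splitting of identical values would fabricate some
  if (min(x) == max(x) || min(y) == max(y)) return(0)
  bx <- equal_freq_bins(x, n_bins)
  by <- equal_freq_bins(y, n_bins)
  joint <- tabulate(bx + n_bins * (by - 1), nbins = n_bins^2) / n
  px <- tabulate(bx, nbins = n_bins) / n
  py <- tabulate(by, nbins = n_bins) / n
  outer_p <- as.vector(outer(px, py))
  pos <- joint > 0
  sum(joint[pos] * log2(joint[pos] / outer_p[pos]))
}

#' Metric registry
#'
#' Canonical metric names in deterministic order, and the sign convention of
#' each ("signed" metrics carry a direction from the score's sign; the
#' "dissimilarity" metrics are signed by tail; MI is unsigned).
#' @export
assoc_metric_names <- function() {
  c("pearson", "spearman", "bray_curtis", "kld", "mutual_information")
}

metric_fun <- function(metric, params) {
  switch(metric,
    pearson = assoc_pearson,
    spearman = assoc_spearman,
    bray_curtis = assoc_bray_curtis,
    kld = function(x, y) assoc_kld(x, y, params$kld_pseudocount),
    mutual_information = function(x, y)
      assoc_mutual_information(x, y, params$mi_bins),
    stop("unknown metric: ", metric))
}

default_metric_params <- function() list(kld_pseudocount = 1e-8, mi_bins = 4)

#' Score every unordered OTU pair with every metric
#'
#' Pairs are stored in canonical lexicographic order (`otu_a < otu_b`) and
#' emitted in a deterministic order (pairs in lexicographic order, metrics in
#' registry order). Undefined scores are dropped from the result and recorded
#' in the `"skipped"` attribute.
#'
#' @param index an `index_table` (see [compute_edna_index()]).
#' @param metrics character vector of metric names
#'   (subset of [assoc_metric_names()]).
#' @param params list with `kld_pseudocount` and `mi_bins`.
#' @return data frame with columns `otu_a`, `otu_b`, `metric`, `score`,
#'   `direction` (`copresence`/`exclusion` for signed correlations,
#'   `unsigned` otherwise at this stage).
#' @export
score_all_pairs <- function(index, metrics = assoc_metric_names(),
                            params = default_metric_params()) {
  stopifnot(inherits(index, "index_table"))
  bad <- setdiff(metrics, assoc_metric_names())
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  metrics <- assoc_metric_names()[assoc_metric_names() %in% metrics]
  v <- index$values
  ids <- rownames(v)
  if (length(ids) < 2) stop("need >= 2 OTUs to score pairs")
  ord <- order(ids)
  ids <- ids[ord]
  v <- v[ord, , drop = FALSE]
  pairs <- utils::combn(length(ids), 2)
  funs <- lapply(metrics, metric_fun, params = params)
  names(funs) <- metrics
  rows <- vector("list", ncol(pairs) * length(metrics))
  skipped <- list()
  k <- 0
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    xi <- v[i, ]; xj <- v[j, ]
    for (m in metrics) {
      s <- funs[[m]](xi, xj)
      if (is.na(s)) {
        skipped[[length(skipped) + 1]] <-
          data.frame(otu_a = ids[i], otu_b = ids[j], metric = m)
        next
      }
      k <- k + 1
      rows[[k]] <- data.frame(
        otu_a = ids[i], otu_b = ids[j], metric = m, score = s,
        direction = if (m %in% c("pearson", "spearman")) {
          if (s > 0) "copresence" else if (s < 0) "exclusion" else "unsigned"
        } else "unsigned")
    }
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(otu_a = character(), otu_b = character(),
               metric = character(), score = numeric(),
               direction = character())
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(otu_a = character(), otu_b = character(), metric = character())
  out
}

#' @rdname score_all_pairs
#' @param scores a pair-score data frame.
#' @param path output TSV path.
#' @export
write_pair_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
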