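#' Sign composition of a network
#'
#' Fraction of edges that are co-presences (positive associations) versus
#' mutual exclusions (negative associations).
#'
#' @param network a `cooc_network`.
#' @return List with `fraction_copresence`, `fraction_exclusion`,
#'   `n_copresence`, `n_exclusion` (`NA` fractions for an empty network).
#' @export
sign_fractions <- function(network) {
  stopifnot(inherits(network, "cooc_network"))
  n <- nrow(network$edges)
  n_co <- sum(network$edges$sign == "copresence")
  n_ex <- sum(network$edges$sign == "exclusion")
  list(fraction_copresence = if (n) n_co / n else NA_real_,
       fraction_exclusion = if (n) n_ex / n else NA_real_,
       n_copresence = n_co, n_exclusion = n_ex)
}

# edge keys for a cooc_network, a data frame with otu_a/otu_b, or a
# character vector of precomputed keys
edge_keys <- function(x) {
  if (inherits(x, "cooc_network")) pair_key(x$edges$otu_a, x$edges$otu_b)
  else if (is.data.frame(x)) pair_key(x$otu_a, x$otu_b)
  else as.character(x)
}

#' Edge overlap between networks
#'
#' Edge identity across subsets is the unordered OTU pair — sign is ignored
#' for matching (a pair positive in one subset and negative in another still
#' counts as shared); sign agreement is reported separately. Percent shared
#' is the share of the pairwise union, rounded half-up to integer percent
#' for display.
#'
#' @param networks named list (length >= 2) of `cooc_network` objects, edge
#'   data frames with `otu_a`/`otu_b`, or edge-key character vectors.
#' @return List with `pairwise` (data frame: network_a, network_b, shared,
#'   unique_a, unique_b, union, percent_shared, sign_agreement) and
#'   `regions` (membership-pattern counts over all networks).
#' @export
edge_overlap <- function(networks) {
  stopifnot(length(networks) >= 2, !is.null(names(networks)))
  keys <- lapply(networks, edge_keys)
  signs <- lapply(networks, function(x)
    if (inherits(x, "cooc_network"))
      stats::setNames(x$edges$sign, edge_keys(x)) else NULL)
  nm <- names(networks)
  combs <- utils::combn(length(nm), 2)
  pw <- lapply(seq_len(ncol(combs)), function(ci) {
    i <- combs[1, ci]; j <- combs[2, ci]
    a <- unique(keys[[i]]); b <- unique(keys[[j]])
    shared <- intersect(a, b)
    uni <- union(a, b)
    agree <- if (!is.null(signs[[i]]) && !is.null(signs[[j]]) &&
                 length(shared))
      mean(signs[[i]][shared] == signs[[j]][shared]) else NA_real_
    data.frame(network_a = nm[i], network_b = nm[j],
               shared = length(shared),
               unique_a = length(setdiff(a, b)),
               unique_b = length(setdiff(b, a)),
               union = length(uni),
               percent_shared = if (length(uni))
                 round_half_up(100 * length(shared) / length(uni), 0)
               else NA_real_,
               sign_agreement = agree)
  })
  all_keys <- sort(unique(unlist(keys)))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, ncol = length(nm), dimnames = list(NULL, nm))
  pattern <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("region", "count")
  list(pairwise = do.call(rbind, pw), regions = regions)
}

#' Combine edge sets of several networks
#'
#' Union of unordered-pair edge keys with duplicates removed — used to build
#' the "all temporal" / "all spatial" composite edge sets compared across
#' subsetting schemes.
#'
#' @param networks list of `cooc_network`s / edge frames / key vectors.
#' @return Character vector of unique edge keys.
#' @export
combine_edge_sets <- function(networks) {
  sort(unique(unlist(lapply(networks, edge_keys))))
}

#' Abundance-degree correlation
#'
#' Pearson correlation (with its two-sided t-test p-value) between each
#' network node's mean eDNA index over the subset's samples — the
#' analysis-facing abundance measure, not raw reads — and its degree.
#'
#' @param index the subset's `index_table`.
#' @param network a `cooc_network` whose nodes appear in `index`.
#' @return List with `r`, `p` and `n` (`NA` when degree or abundance is
#'   constant or fewer than 3 nodes).
#' @export
abundance_degree_correlation <- function(index, network) {
  stopifnot(inherits(index, "index_table"), inherits(network, "cooc_network"))
  nodes <- network$nodes
  missing_nodes <- setdiff(nodes, rownames(index$values))
  if (length(missing_nodes))
    stop("network nodes absent from index table: ",
         paste(missing_nodes, collapse = ", "))
  if (length(nodes) < 3)
    return(list(r = NA_real_, p = NA_real_, n = length(nodes)))
  abun <- rowMeans(index$values[nodes, , drop = FALSE])
  deg <- igraph::degree(as_igraph(network))[nodes]
  if (stats::sd(abun) == 0 || stats::sd(deg) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(nodes)))
  ct <- stats::cor.test(abun, deg, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(nodes))
}

#' Keystone overlap across networks
#'
#' For every OTU appearing in any keystone list, the set of networks where
#' it ranks as a keystone, plus counts of OTUs shared by exactly m networks.
#'
#' @param lists named list (length >= 2) of keystone tables (from
#'   [keystones()]) or character vectors of OTU ids.
#' @return List with `membership` (data frame: otu_id, networks,
#'   multiplicity) and `by_multiplicity` (data frame: multiplicity, n_otus).
#' @export
keystone_overlap <- function(lists) {
  stopifnot(length(lists) >= 2, !is.null(names(lists)))
  ids <- lapply(lists, function(x)
    if (is.data.frame(x)) x$otu_id else as.character(x))
  all_ids <- sort(unique(unlist(ids)))
  member <- vapply(ids, function(k) all_ids %in% k, logical(length(all_ids)))
  member <- matrix(member, ncol = length(lists),
                   dimnames = list(NULL, names(lists)))
  mult <- rowSums(member)
  membership <- data.frame(
    otu_id = all_ids,
    networks = apply(member, 1, function(r)
      paste(colnames(member)[r], collapse = ",")),
    multiplicity = as.integer(mult))
  bym <- as.data.frame(table(factor(mult, levels = seq_along(lists))),
                       stringsAsFactors = FALSE)
  names(bym) <- c("multiplicity", "n_otus")
  bym$multiplicity <- as.integer(bym$multiplicity)
  list(membership = membership, by_multiplicity = bym)
}

#' Cross-network comparison report
#'
#' Bundles the per-network sign fractions, trophic-match fractions and
#' abundance-degree correlations with the pairwise edge-overlap table and
#' the keystone overlap, as one JSON-serializable list.
#'
#' @param networks named list of `cooc_network`s.
#' @param webs named list of `food_web`s aligned with `networks`.
#' @param indices named list of `index_table`s aligned with `networks`.
#' @param k keystone list size (default 10).
#' @return A list of class `comparison_report`.
#' @export
comparison_report <- function(networks, webs = NULL, indices = NULL,
                              k = 10) {
  stopifnot(!is.null(names(networks)))
  per_network <- lapply(names(networks), function(nm) {
    net <- networks[[nm]]
    out <- sign_fractions(net)
    if (!is.null(webs) && nm %in% names(webs)) {
      tm <- trophic_match(net, webs[[nm]])
      out$n_trophic_edges <- tm$n_trophic
      out$fraction_trophic <- tm$fraction
      out$percent_trophic <- tm$percent
    }
    if (!is.null(indices) && nm %in% names(indices)) {
      ad <- abundance_degree_correlation(indices[[nm]], net)
      out$abundance_degree_r <- ad$r
      out$abundance_degree_p <- ad$p
    }
    out$n_edges <- nrow(net$edges)
    out$n_nodes <- length(net$nodes)
    out
  })
  names(per_network) <- names(networks)
  keylists <- lapply(networks, function(net)
    keystones(centralities(net), k = k, by = "degree")$otu_id)
  structure(list(
    per_network = per_network,
    edge_overlap = if (length(networks) >= 2) edge_overlap(networks)
                   else NULL,
    keystone_overlap = if (length(networks) >= 2) keystone_overlap(keylists)
                       else NULL),
    class = "comparison_report")
}
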