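# In-code fixtures shared across test files.

# small count matrix with dimnames
count_matrix <- function(values, n_otus, n_samples,
                         otus = sprintf("otu%02d", seq_len(n_otus)),
                         samples = sprintf("s%02d", seq_len(n_samples))) {
  matrix(as.integer(values), n_otus, n_samples,
         dimnames = list(otus, samples))
}

# write a TSV OTU table fixture and return its path
write_otu_tsv <- function(lines, dir = withr::local_tempdir()) {
  path <- file.path(dir, "otu.tsv")
  writeLines(lines, path)
  path
}

# index table derived from a count matrix
index_from_counts <- function(counts, marker = "m1") {
  compute_edna_index(otu_table(counts, marker = marker))
}

# a deterministic random community index table for engine tests
random_index <- function(n_otus = 12, n_samples = 30, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_otus * n_samples,
                         lambda = exp(rnorm(n_otus * n_samples, 4, 1))),
                   n_otus, n_samples,
                   dimnames = list(sprintf("otu%02d", seq_len(n_otus)),
                                   sprintf("s%02d", seq_len(n_samples))))
  counts[counts < 0] <- 0L
  index_from_counts(counts)
}

# minimal cooc_network wrapper around an edge data frame (for functions
# that only consume the edge list / node set)
fake_network <- function(edges, community = NULL) {
  if (is.null(edges$sign)) edges$sign <- "copresence"
  nodes <- sort(unique(c(edges$otu_a, edges$otu_b)))
  structure(list(nodes = nodes, edges = edges,
                 community = if (is.null(community)) nodes else community,
                 config = NULL, n_candidates = nrow(edges),
                 n_unstable = 0L,
                 dropped = data.frame()),
            class = "cooc_network")
}

# minimal food_web from a consumer/resource data frame
fake_web <- function(edges, nodes = NULL) {
  ids <- if (is.null(nodes)) sort(unique(unlist(edges))) else nodes
  structure(list(nodes = data.frame(otu_id = as.character(ids),
                                    trophic_level = rep(NA_real_,
                                                        length(ids))),
                 edges = edges, direction = "consumer->resource",
                 n_skipped = 0L),
            class = "food_web")
}

# brute-force Floyd-Warshall distances from a logical adjacency matrix
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# topology statistics recomputed from first principles on an adjacency matrix
brute_topology <- function(adj, directed) {
  if (!directed) adj <- adj | t(adj)
  d <- fw_distances(adj)
  diag(d) <- Inf
  fin <- is.finite(d)
  ecc <- apply(d, 1, function(r) if (any(is.finite(r))) max(r[is.finite(r)]) else 0)
  pos <- ecc[ecc > 0]
  und <- adj | t(adj)
  deg <- rowSums(und)
  local_c <- vapply(seq_len(nrow(adj)), function(i) {
    nb <- which(und[i, ])
    if (length(nb) < 2) return(NA_real_)
    sub <- und[nb, nb, drop = FALSE]
    sum(sub) / (length(nb) * (length(nb) - 1))
  }, 0)
  list(diameter = max(pos), radius = min(pos),
       cpl = mean(d[fin]),
       clustering = mean(local_c, na.rm = TRUE),
       avg_neighbours = mean(deg))
}
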