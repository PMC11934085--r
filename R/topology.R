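#' Round half away from zero
#'
#' Report values are displayed rounded half-up (0.125 -> 0.13 at 2 dp), the
#' convention of the source tables, rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

graph_input <- function(graph) {
  if (inherits(graph, "cooc_network") || inherits(graph, "food_web"))
    as_igraph(graph)
  else if (igraph::is_igraph(graph)) graph
  else stop("expected a cooc_network, food_web or igraph graph")
}

#' Topological characterization of a network
#'
#' Computes the standard report for an undirected co-occurrence network or a
#' directed food web:
#' * `avg_neighbours`: mean over nodes of the number of DISTINCT adjacent
#'   nodes, ignoring edge direction — reciprocal consumer pairs count once,
#'   so for a directed graph with r reciprocal pairs this is `(2E - 2r)/N`;
#'   for a simple undirected graph it is exactly `2E/N`.
#' * `density`: `2E/(N(N-1))` undirected, `E/(N(N-1))` directed.
#' * `diameter`/`radius`: max / min positive node eccentricity, where a
#'   node's eccentricity is its largest shortest-path distance to the nodes
#'   it can reach (directed paths follow edge direction); unreachable pairs
#'   are ignored, which is the only convention under which a directed
#'   food web can have radius 1.
#' * `char_path_length`: mean shortest-path distance over all ordered
#'   reachable pairs.
#' * `clustering_coefficient`: mean local clustering over nodes with
#'   degree >= 2 in the undirected projection.
#'
#' Edgeless graphs get `NA` path statistics and density 0.
#'
#' @param graph a `cooc_network`, `food_web`, or igraph graph.
#' @param directed logical; defaults to the graph's own directedness.
#' @return A list of class `topology_report`.
#' @export
topology_report <- function(graph, directed = NULL) {
  g <- graph_input(graph)
  if (is.null(directed)) directed <- igraph::is_directed(g)
  if (!directed && igraph::is_directed(g))
    g <- igraph::as_undirected(g, mode = "collapse")
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  gu <- igraph::as_undirected(g, mode = "collapse")
  avg_nb <- if (n) mean(igraph::degree(gu)) else NA_real_
  dens <- if (n < 2) 0 else if (directed) e / (n * (n - 1)) else
    2 * e / (n * (n - 1))
  if (e == 0) {
    diam <- rad <- NA_integer_; cpl <- NA_real_; clust <- NA_real_
  } else {
    d <- igraph::distances(g, mode = "out")
    diag(d) <- Inf
    reach <- is.finite(d)
    ecc <- apply(d, 1, function(r) {
      fin <- r[is.finite(r)]
      if (length(fin)) max(fin) else 0
    })
    pos <- ecc[ecc > 0]
    diam <- as.integer(max(pos))
    rad <- as.integer(min(pos))
    cpl <- mean(d[reach])
    loc <- igraph::transitivity(gu, type = "local", isolates = "NaN")
    loc <- loc[!is.nan(loc)]          # nodes with degree >= 2 only
    clust <- if (length(loc)) mean(loc) else NA_real_
  }
  structure(list(n_nodes = n, n_edges = e, avg_neighbours = avg_nb,
                 diameter = diam, radius = rad, char_path_length = cpl,
                 clustering_coefficient = clust, density = dens,
                 directed = directed),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> (%s)\n",
              if (x$directed) "directed" else "undirected"))
  cat(sprintf("  nodes %d  edges %d  avg. neighbours %s  density %s\n",
              x$n_nodes, x$n_edges,
              format(round_half_up(x$avg_neighbours, 3)),
              format(round_half_up(x$density, 2))))
  cat(sprintf("  diameter %s  radius %s  CPL %s  clustering %s\n",
              x$diameter, x$radius,
              format(round_half_up(x$char_path_length, 2)),
              format(round_half_up(x$clustering_coefficient, 2))))
  invisible(x)
}

#' Node centralities
#'
#' Degree is taken on the undirected projection (distinct neighbours).
#' Closeness follows the reachable-only convention: for node i with `r`
#' reachable nodes at total distance `s`, closeness is `(r / s) * (r /
#' (N - 1))`, which is 0 for isolated nodes and 1 for the centre of a star.
#' Betweenness is standard shortest-path betweenness with pair
#' normalization.
#'
#' @param graph a `cooc_network`, `food_web`, or igraph graph.
#' @return data frame: `otu_id`, `degree`, `closeness`, `betweenness`.
#' @export
centralities <- function(graph) {
  g <- graph_input(graph)
  n <- igraph::vcount(g)
  gu <- igraph::as_undirected(g, mode = "collapse")
  deg <- igraph::degree(gu)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  clo <- apply(d, 1, function(r) {
    fin <- r[is.finite(r)]
    if (!length(fin) || n < 2) return(0)
    (length(fin) / sum(fin)) * (length(fin) / (n - 1))
  })
  btw <- if (n > 2)
    igraph::betweenness(g, directed = igraph::is_directed(g),
                        normalized = TRUE)
  else rep(0, n)
  data.frame(otu_id = igraph::V(g)$name, degree = as.integer(deg),
             closeness = as.numeric(clo), betweenness = as.numeric(btw),
             row.names = NULL)
}

#' Keystone candidates by centrality
#'
#' The k most-connected OTUs by the chosen centrality (default: the 10
#' highest-degree nodes). High centrality flags a candidate for
#' disproportionate ecological importance, not proof of it. Ties are broken
#' by closeness, then lexicographic OTU id; the full ordering is returned.
#'
#' @param centrality data frame from [centralities()].
#' @param k number of keystones (default 10; clamped to the node count).
#' @param by `"degree"`, `"closeness"` or `"betweenness"`.
#' @return data frame of the top k rows, ordered; the complete ranking is
#'   attached as attribute `"full_ranking"`.
#' @export
keystones <- function(centrality, k = 10,
                      by = c("degree", "closeness", "betweenness")) {
  by <- match.arg(by)
  stopifnot(k >= 1)
  ord <- order(-centrality[[by]], -centrality$closeness, centrality$otu_id)
  ranked <- centrality[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  out <- ranked[seq_len(min(k, nrow(ranked))), , drop = FALSE]
  attr(out, "full_ranking") <- ranked
  out
}

#' Serialize a topology report
#'
#' @param x a `topology_report`.
#' @return A plain list suitable for JSON output, with display-rounded
#'   values alongside full-precision ones.
#' @export
topology_report_json <- function(x) {
  stopifnot(inherits(x, "topology_report"))
  list(n_nodes = x$n_nodes, n_edges = x$n_edges,
       avg_neighbours = x$avg_neighbours,
       avg_neighbours_display = round_half_up(x$avg_neighbours, 3),
       diameter = x$diameter, radius = x$radius,
       char_path_length = x$char_path_length,
       char_path_length_display = round_half_up(x$char_path_length, 2),
       clustering_coefficient = x$clustering_coefficient,
       clustering_coefficient_display =
         round_half_up(x$clustering_coefficient, 2),
       density = x$density,
       density_display = round_half_up(x$density, 2),
       directed = x$directed)
}
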