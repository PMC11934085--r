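#' Diet records and meta-web food webs
#'
#' A meta-web is the cumulative set of all potential consumer-resource links
#' for a species pool; restricting it to the OTUs actually detected by eDNA
#' (and surviving the prevalence filter) yields the local food web. Diet
#' records come as a TSV edge list with columns `consumer_otu`,
#' `resource_otu`, `source` (a citation key), resolved at the OTU label's
#' taxonomic rank.
#'
#' @param path path to the diet-record TSV.
#' @return data frame of diet records.
#' @export
read_diet_records <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("consumer_otu", "resource_otu")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("diet records missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"source" %in% names(rec)) rec$source <- NA_character_
  rec
}

#' Build the local food web from diet records
#'
#' Keeps records whose consumer and resource are both in the detected
#' community; the node set is the full community (isolated OTUs retained —
#' food-web node counts track detected OTUs, not only connected ones).
#' Duplicate records collapse to one edge. Edges are stored
#' consumer -> resource (predator points to prey); the convention is recorded
#' on the object so path-based metrics stay interpretable.
#'
#' @param records diet-record data frame (see [read_diet_records()]).
#' @param community an [otu_table()] or character vector of OTU ids, already
#'   subset- and prevalence-filtered.
#' @return An object of class `food_web` with fields `nodes` (data frame:
#'   otu_id, trophic_level), `edges` (consumer, resource), `direction`
#'   and `n_skipped` (records with endpoints outside the community).
#' @export
build_metaweb <- function(records, community) {
  ids <- if (inherits(community, "otu_table")) otu_ids(community)
         else as.character(community)
  stopifnot(length(ids) >= 1, !anyDuplicated(ids))
  self_loop <- records$consumer_otu == records$resource_otu
  if (any(self_loop)) {
    warning(sum(self_loop), " self-referential diet record(s) skipped")
    records <- records[!self_loop, , drop = FALSE]
  }
  inside <- records$consumer_otu %in% ids & records$resource_otu %in% ids
  n_skipped <- sum(!inside)
  if (n_skipped)
    warning(n_skipped, " diet record(s) with endpoints outside the community")
  edges <- unique(records[inside, c("consumer_otu", "resource_otu"),
                          drop = FALSE])
  names(edges) <- c("consumer", "resource")
  edges <- edges[order(edges$consumer, edges$resource), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    nodes = data.frame(otu_id = sort(ids), trophic_level = NA_real_),
    edges = edges,
    direction = "consumer->resource",
    n_skipped = n_skipped),
    class = "food_web")
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf("<food_web> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges), x$direction))
  invisible(x)
}

#' @export
as_igraph.food_web <- function(x) {
  igraph::graph_from_data_frame(x$edges, directed = TRUE,
                                vertices = data.frame(
                                  name = x$nodes$otu_id,
                                  trophic_level = x$nodes$trophic_level))
}

#' Assign trophic levels to food-web nodes
#'
#' Primary producers (algae) and fungi go to trophic level 1, invertebrates
#' to level 2; vertebrates (fish, mammal, bird) take their database-derived
#' `trophic_level` from the OTU metadata. An explicit `trophic_level` in the
#' metadata always wins over the group rule.
#'
#' @param web a `food_web`.
#' @param meta OTU-metadata data frame (see [read_otu_metadata()]).
#' @return The `food_web` with every node's trophic level set.
#' @export
assign_trophic_levels <- function(web, meta) {
  stopifnot(inherits(web, "food_web"))
  meta <- validate_otu_metadata(meta)
  idx <- match(web$nodes$otu_id, meta$otu_id)
  if (anyNA(idx))
    stop("nodes missing from OTU metadata: ",
         paste(web$nodes$otu_id[is.na(idx)], collapse = ", "))
  grp <- meta$group[idx]
  explicit <- meta$trophic_level[idx]
  lvl <- ifelse(!is.na(explicit), explicit,
         ifelse(grp %in% c("algae", "fungi"), 1,
         ifelse(grp == "invertebrate", 2, NA_real_)))
  if (anyNA(lvl))
    stop("no trophic level derivable for: ",
         paste(web$nodes$otu_id[is.na(lvl)], collapse = ", "))
  web$nodes$trophic_level <- lvl
  web
}

#' Label co-occurrence edges that match trophic interactions
#'
#' A co-occurrence edge counts as trophic when its unordered OTU pair appears
#' in the food web in either direction. Returns the labelled edge table and
#' the trophic count/fraction; the fraction is invariant to reversing the
#' food-web direction convention.
#'
#' @param network a `cooc_network`.
#' @param web a `food_web` over a shared OTU id space.
#' @return List with `edges` (network edge table plus logical `trophic`),
#'   `n_trophic`, `fraction` and `percent` (half-up integer, as reported).
#' @export
trophic_match <- function(network, web) {
  stopifnot(inherits(network, "cooc_network"), inherits(web, "food_web"))
  net_key <- pair_key(network$edges$otu_a, network$edges$otu_b)
  web_key <- unique(pair_key(web$edges$consumer, web$edges$resource))
  trophic <- net_key %in% web_key
  edges <- network$edges
  edges$trophic <- trophic
  n <- nrow(edges)
  frac <- if (n) sum(trophic) / n else NA_real_
  list(edges = edges, n_trophic = sum(trophic), fraction = frac,
       percent = if (n) round_half_up(100 * frac, 0) else NA_real_)
}

# canonical unordered pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Write a food web's edge list as TSV
#'
#' @param web a `food_web`.
#' @param path output path.
#' @export
write_food_web <- function(web, path) {
  stopifnot(inherits(web, "food_web"))
  utils::write.table(web$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
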