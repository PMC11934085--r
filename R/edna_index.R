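#' The eDNA index: scaled relative abundance
#'
#' Read counts carry only compositional information, and amplification
#' efficiency differs between taxa, so raw counts are not comparable across
#' OTUs. Under the assumption that efficiency is constant within a taxon and
#' primer set, counts are first converted to within-sample proportions and
#' each OTU's proportion is then divided by that OTU's maximum proportion
#' across samples, yielding an index in \[0, 1\] that tracks within-OTU
#' relative abundance across samples.
#'
#' An `index_table` stores the index values plus the column-stochastic
#' compositional matrix they were derived from (field `comp`), which the
#' ReBoot null model renormalizes under permutation, and per-OTU marker
#' provenance.
#'
#' @name edna_index
NULL

new_index_table <- function(values, comp, provenance) {
  stopifnot(is.matrix(values), identical(dim(values), dim(comp)))
  structure(list(values = values, comp = comp, provenance = provenance),
            class = "index_table")
}

#' @export
print.index_table <- function(x, ...) {
  cat(sprintf("<index_table> %d OTUs x %d samples (markers: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(unlist(x$provenance))), collapse = ", ")))
  invisible(x)
}

#' Convert read counts to within-sample proportions
#'
#' Divides each sample column by its column sum. A sample with zero total
#' reads has no compositional information and is rejected; callers should
#' drop such samples first.
#'
#' @param x an [otu_table()] or a non-negative count matrix.
#' @return Matrix of proportions; every column sums to 1.
#' @export
to_proportions <- function(x) {
  counts <- if (inherits(x, "otu_table")) x$counts else x
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("zero-read sample(s): ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(counts, 2, cs, "/")
}

#' Compute the eDNA index from proportions
#'
#' `index[i, j] = p[i, j] / max_j p[i, j]`; an all-zero OTU row stays all
#' zero (0/0 is defined as 0 so the transform is total; such OTUs are
#' normally removed by [prevalence_filter()] beforehand).
#'
#' @param x an [otu_table()] or a proportion matrix (from
#'   [to_proportions()]).
#' @param marker marker label recorded in provenance when `x` is a bare
#'   matrix; taken from the table otherwise.
#' @return An `index_table`.
#' @examples
#' m <- matrix(c(10L, 90L, 40L, 60L), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' idx <- compute_edna_index(otu_table(m))
#' idx$values
#' @export
compute_edna_index <- function(x, marker = NULL) {
  if (inherits(x, "otu_table")) {
    if (is.null(marker)) marker <- x$marker
    p <- to_proportions(x)
  } else {
    if (is.null(marker)) marker <- "marker1"
    p <- x
    if (any(p < 0) || any(p > 1)) stop("proportions must lie in [0, 1]")
  }
  rmax <- apply(p, 1, max)
  vals <- p / ifelse(rmax > 0, rmax, 1)
  prov <- stats::setNames(rep(list(marker), nrow(p)), rownames(p))
  new_index_table(vals, p, prov)
}

# renormalize a non-negative matrix to column sums 1 (columns of zeros kept)
renorm_columns <- function(m) {
  cs <- colSums(m)
  sweep(m, 2, ifelse(cs > 0, cs, 1), "/")
}

#' Ensemble index across two primer sets
#'
#' OTUs detected by both markers get the arithmetic mean of their two index
#' values at each sample; OTUs detected by exactly one marker are copied
#' unchanged. Sample sets must be identical. The compositional matrix of the
#' ensemble is the per-OTU merge of the marker compositions, renormalized to
#' column sums of one.
#'
#' @param a,b `index_table`s over the same samples.
#' @return An `index_table` over the union of OTUs.
#' @export
ensemble_index <- function(a, b) {
  stopifnot(inherits(a, "index_table"), inherits(b, "index_table"))
  if (!setequal(colnames(a$values), colnames(b$values)))
    stop("ensemble_index: sample sets differ")
  b_vals <- b$values[, colnames(a$values), drop = FALSE]
  b_comp <- b$comp[, colnames(a$values), drop = FALSE]
  ids <- union(rownames(a$values), rownames(b$values))
  vals <- matrix(0, length(ids), ncol(a$values),
                 dimnames = list(ids, colnames(a$values)))
  comp <- vals
  prov <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    in_a <- id %in% rownames(a$values)
    in_b <- id %in% rownames(b_vals)
    if (in_a && in_b) {
      vals[id, ] <- (a$values[id, ] + b_vals[id, ]) / 2
      comp[id, ] <- (a$comp[id, ] + b_comp[id, ]) / 2
      prov[[id]] <- union(a$provenance[[id]], b$provenance[[id]])
    } else if (in_a) {
      vals[id, ] <- a$values[id, ]
      comp[id, ] <- a$comp[id, ]
      prov[[id]] <- a$provenance[[id]]
    } else {
      vals[id, ] <- b_vals[id, ]
      comp[id, ] <- b_comp[id, ]
      prov[[id]] <- b$provenance[[id]]
    }
  }
  new_index_table(vals, renorm_columns(comp), prov)
}

#' Concatenate index tables over disjoint OTU sets
#'
#' Row-binds index tables from different marker panels (e.g., vertebrate and
#' broader eukaryote OTUs) into one analysis table. Sample sets must match
#' and OTU ids must be disjoint.
#'
#' @param tables list of `index_table`s.
#' @return A single `index_table`.
#' @export
concat_index_tables <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "index_table")))
  if (length(tables) == 1) return(tables[[1]])
  samples <- colnames(tables[[1]]$values)
  for (t in tables[-1]) {
    if (!setequal(colnames(t$values), samples))
      stop("concat_index_tables: sample sets differ")
  }
  ids <- unlist(lapply(tables, function(t) rownames(t$values)))
  if (anyDuplicated(ids))
    stop("duplicate otu_id across tables: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- do.call(rbind, lapply(tables, function(t)
    t$values[, samples, drop = FALSE]))
  comp <- do.call(rbind, lapply(tables, function(t)
    t$comp[, samples, drop = FALSE]))
  prov <- do.call(c, lapply(tables, function(t) t$provenance))
  new_index_table(vals, renorm_columns(comp), prov)
}

#' Write / read an index table as TSV
#'
#' The value matrix mirrors the OTU-table layout with real-valued cells; the
#' marker provenance goes to a side-car TSV at `<path>.provenance`.
#'
#' @param x an `index_table`.
#' @param path output path for the value matrix.
#' @export
write_index_table <- function(x, path) {
  stopifnot(inherits(x, "index_table"))
  df <- data.frame(otu_id = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- data.frame(
    otu_id = names(x$provenance),
    markers = vapply(x$provenance, paste, "", collapse = ","))
  utils::write.table(prov, paste0(path, ".provenance"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
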