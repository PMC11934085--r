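#' Parameters for a synthetic eDNA community
#'
#' The generator emulates the statistical structure the inference stage
#' assumes: latent log-linear abundances with optional shared environmental
#' gradients, planted pairwise associations of controlled sign and strength,
#' compositional multinomial read sampling through two overlapping
#' primer-set panels with per-OTU amplification efficiencies, and a fraction
#' of rare OTUs whose occupancy is thinned below the prevalence-filter
#' cutoff (so the filter has real work to do).
#'
#' Defaults mirror the study scale: 60 samples, ~120 OTUs split over two
#' markers with ~30% panel overlap, mean depth 1e5 reads per sample.
#'
#' @param n_otus number of OTUs.
#' @param n_samples number of samples (sites).
#' @param n_markers number of primer sets (default 2).
#' @param marker_coverage per-marker fraction of OTUs amplified; with the
#'   defaults (0.8, 0.5) the panels overlap by 30% of OTUs.
#' @param depth mean sequencing depth (reads per sample).
#' @param depth_dispersion lognormal SD of per-sample depth.
#' @param n_env_gradients number of shared environmental gradients; their
#'   per-OTU loadings are drawn `N(0, env_loading_sd)` with random signs, so
#'   they induce realistic abiotic correlation structure. Set to 0 for a
#'   fully independent null community (the calibration null).
#' @param env_loading_sd SD of gradient loadings.
#' @param baseline_sd SD of per-OTU log-abundance baselines (rank-abundance
#'   spread).
#' @param noise_sd SD of the per-OTU, per-sample Gaussian log noise.
#' @param planted_edges data frame with columns `otu_a`, `otu_b`, `sign`
#'   (`"+"`/`"-"`), `strength` in \[0, 1\]; each planted pair shares a latent
#'   factor with loading `1.8 * strength` (equal signs for `"+"`, opposite
#'   for `"-"`), chosen so the latent Pearson correlation is approximately
#'   equal to `strength` at the default noise levels.
#' @param efficiency_sd lognormal SD of per-OTU, per-marker amplification
#'   efficiencies.
#' @param rare_fraction share of (non-planted) OTUs thinned to < 25%
#'   occupancy.
#' @param seed RNG seed; everything downstream is deterministic in it.
#' @return A list of class `community_params`.
#' @export
community_params <- function(n_otus = 120, n_samples = 60, n_markers = 2,
                             marker_coverage = c(0.8, 0.5),
                             depth = 1e5, depth_dispersion = 0.3,
                             n_env_gradients = 2, env_loading_sd = 0.15,
                             baseline_sd = 1.2, noise_sd = 0.5,
                             planted_edges = NULL,
                             efficiency_sd = 0.3, rare_fraction = 0.15,
                             seed = 1) {
  stopifnot(n_otus >= 2, n_samples >= 2, n_markers >= 1,
            length(marker_coverage) == n_markers,
            all(marker_coverage > 0), all(marker_coverage <= 1),
            depth > 0, rare_fraction >= 0, rare_fraction < 1)
  if (!is.null(planted_edges)) {
    stopifnot(all(c("otu_a", "otu_b", "sign", "strength") %in%
                    names(planted_edges)),
              all(planted_edges$sign %in% c("+", "-")),
              all(planted_edges$strength >= 0),
              all(planted_edges$strength <= 1),
              all(planted_edges$otu_a != planted_edges$otu_b))
  }
  structure(list(n_otus = n_otus, n_samples = n_samples,
                 n_markers = n_markers, marker_coverage = marker_coverage,
                 depth = depth, depth_dispersion = depth_dispersion,
                 n_env_gradients = n_env_gradients,
                 env_loading_sd = env_loading_sd,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 planted_edges = planted_edges,
                 efficiency_sd = efficiency_sd,
                 rare_fraction = rare_fraction,
                 seed = as.integer(seed)),
            class = "community_params")
}

#' Helper: plant random association pairs
#'
#' Draws `n_pos` positive and `n_neg` negative planted pairs over disjoint
#' OTUs (each OTU used at most once, keeping planted correlations
#' independent of each other).
#'
#' @param n_otus community size.
#' @param n_pos,n_neg numbers of positive/negative pairs.
#' @param strength shared strength value.
#' @param seed RNG seed.
#' @return A planted-edge data frame for [community_params()].
#' @export
plant_random_edges <- function(n_otus, n_pos, n_neg, strength = 0.9,
                               seed = 1) {
  need <- 2 * (n_pos + n_neg)
  stopifnot(need <= n_otus)
  with_local_seed(seed, {
    ids <- synthetic_otu_ids(n_otus)
    chosen <- sample(ids, need)
    a <- chosen[seq_len(n_pos + n_neg)]
    b <- chosen[(n_pos + n_neg) + seq_len(n_pos + n_neg)]
    data.frame(otu_a = pmin(a, b), otu_b = pmax(a, b),
               sign = rep(c("+", "-"), c(n_pos, n_neg)),
               strength = strength)
  })
}

synthetic_otu_ids <- function(n) sprintf("otu%03d", seq_len(n))

synthetic_sample_ids <- function(n) sprintf("s%02d", seq_len(n))

#' Generate the latent community (ground truth)
#'
#' Latent log-abundance of OTU i in sample j is
#' `baseline_i + sum_g loading_ig * env_gj + sum_e lambda_e(i) * f_ej +
#' eps_ij`, where the `f_e` are the planted pair factors (loading
#' `1.8 * strength`, equal-sign for co-presence, opposite-sign for
#' exclusion) and eps is Gaussian noise. Abundances are the exponentials;
#' rare OTUs get their occupancy thinned to 5-20% of samples.
#'
#' @param params a [community_params()].
#' @return A list of class `synthetic_truth` with the latent `abundance`
#'   matrix, the planted association list, per-marker OTU `panels`,
#'   amplification `efficiencies`, and the generating `params`.
#' @export
generate_community <- function(params) {
  stopifnot(inherits(params, "community_params"))
  p <- params
  ids <- synthetic_otu_ids(p$n_otus)
  samples <- synthetic_sample_ids(p$n_samples)
  if (!is.null(p$planted_edges)) {
    bad <- setdiff(c(p$planted_edges$otu_a, p$planted_edges$otu_b), ids)
    if (length(bad)) stop("planted edge references unknown OTU(s): ",
                          paste(unique(bad), collapse = ", "))
  }
  with_local_seed(p$seed, {
    baseline <- stats::rnorm(p$n_otus, 0, p$baseline_sd)
    lat <- matrix(baseline, p$n_otus, p$n_samples) +
      matrix(stats::rnorm(p$n_otus * p$n_samples, 0, p$noise_sd),
             p$n_otus, p$n_samples)
    if (p$n_env_gradients > 0) {
      env <- matrix(stats::rnorm(p$n_env_gradients * p$n_samples),
                    p$n_env_gradients, p$n_samples)
      load <- matrix(stats::rnorm(p$n_otus * p$n_env_gradients, 0,
                                  p$env_loading_sd),
                     p$n_otus, p$n_env_gradients)
      lat <- lat + load %*% env
    }
    if (!is.null(p$planted_edges)) {
      for (e in seq_len(nrow(p$planted_edges))) {
        ia <- match(p$planted_edges$otu_a[e], ids)
        ib <- match(p$planted_edges$otu_b[e], ids)
        lam <- 1.8 * p$planted_edges$strength[e]
        f <- stats::rnorm(p$n_samples)
        lat[ia, ] <- lat[ia, ] + lam * f
        lat[ib, ] <- lat[ib, ] +
          (if (p$planted_edges$sign[e] == "+") lam else -lam) * f
      }
    }
    abun <- exp(lat)
    dimnames(abun) <- list(ids, samples)
    # thin occupancy of rare, non-planted OTUs below the 25% filter cutoff
    planted_ids <- unique(c(p$planted_edges$otu_a, p$planted_edges$otu_b))
    eligible <- setdiff(ids, planted_ids)
    n_rare <- round(p$rare_fraction * p$n_otus)
    rare <- if (n_rare > 0 && length(eligible))
      sample(eligible, min(n_rare, length(eligible))) else character()
    for (r in rare) {
      occ <- max(1, round(stats::runif(1, 0.05, 0.20) * p$n_samples))
      keep <- sample.int(p$n_samples, occ)
      abun[r, -keep] <- 0
    }
    # marker panels: leading fraction for marker 1, trailing for marker 2,
    # etc. -- deterministic, overlapping
    panels <- lapply(seq_len(p$n_markers), function(m) {
      k <- round(p$marker_coverage[m] * p$n_otus)
      if (m %% 2 == 1) ids[seq_len(k)] else ids[p$n_otus - k + seq_len(k)]
    })
    names(panels) <- paste0("marker", seq_len(p$n_markers))
    eff <- matrix(stats::rlnorm(p$n_otus * p$n_markers, 0, p$efficiency_sd),
                  p$n_otus, p$n_markers,
                  dimnames = list(ids, names(panels)))
    structure(list(abundance = abun,
                   planted_edges = p$planted_edges,
                   rare_otus = rare,
                   panels = panels,
                   efficiencies = eff,
                   params = p),
              class = "synthetic_truth")
  })
}

#' Sample multinomial reads from a synthetic community
#'
#' For each marker and sample, reads are multinomial with probabilities
#' proportional to `abundance * efficiency` over the marker's OTU panel;
#' per-sample depths are lognormal around the configured mean. OTUs outside
#' a panel get structural zeros. Scaling all depths leaves expected
#' proportions unchanged (the compositional property the eDNA index relies
#' on).
#'
#' @param truth a `synthetic_truth` from [generate_community()].
#' @param depth_scale multiplier on the configured depth (for
#'   depth-invariance experiments).
#' @return Named list of [otu_table()]s, one per marker, each over the full
#'   OTU set.
#' @export
sample_reads <- function(truth, depth_scale = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$params
  ids <- rownames(truth$abundance)
  samples <- colnames(truth$abundance)
  with_local_seed(p$seed + 7L, {
    out <- lapply(names(truth$panels), function(mk) {
      panel <- truth$panels[[mk]]
      counts <- matrix(0L, length(ids), length(samples),
                       dimnames = list(ids, samples))
      w <- truth$abundance[panel, , drop = FALSE] *
        truth$efficiencies[panel, mk]
      depths <- pmax(1, round(stats::rlnorm(
        length(samples),
        log(p$depth * depth_scale) - p$depth_dispersion^2 / 2,
        p$depth_dispersion)))
      for (j in seq_along(samples)) {
        pj <- w[, j]
        if (sum(pj) == 0) next
        counts[panel, j] <- as.integer(
          stats::rmultinom(1, depths[j], pj / sum(pj)))
      }
      otu_table(counts, marker = mk)
    })
    names(out) <- names(truth$panels)
    out
  })
}

#' Synthetic sample metadata
#'
#' Assigns months (cycling through the sampling season) and
#' distance-from-shore values (a nearshore cluster under 1 km and an
#' offshore spread of 2.5-16 km, mirroring the study design) so the
#' temporal/spatial subsetting machinery can run on synthetic data.
#'
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @param nearshore_fraction share of samples placed nearshore.
#' @return A sample-metadata data frame.
#' @export
simulate_sample_metadata <- function(n_samples, seed = 1,
                                     nearshore_fraction = 0.22) {
  with_local_seed(seed + 13L, {
    months <- c("June", "July", "August", "September", "October")
    month <- months[1 + (seq_len(n_samples) - 1) %% length(months)]
    n_near <- max(1, round(nearshore_fraction * n_samples))
    near <- sample.int(n_samples, n_near)
    dist <- stats::runif(n_samples, 2500, 16000)
    dist[near] <- stats::runif(n_near, 100, 950)
    data.frame(sample_id = synthetic_sample_ids(n_samples),
               month = month, shore_distance_m = round(dist))
  })
}

#' Synthetic OTU metadata
#'
#' Assigns taxonomic groups (a vertebrate-heavy head of the OTU list and an
#' invertebrate/algae tail, echoing the two-panel design) and trophic levels
#' for vertebrates.
#'
#' @param truth a `synthetic_truth`.
#' @return An OTU-metadata data frame.
#' @export
simulate_otu_metadata <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ids <- rownames(truth$abundance)
  n <- length(ids)
  with_local_seed(truth$params$seed + 23L, {
    grp <- character(n)
    head_n <- round(0.6 * n)
    grp[seq_len(head_n)] <- sample(c("fish", "mammal", "bird"), head_n,
                                   replace = TRUE, prob = c(0.8, 0.1, 0.1))
    grp[(head_n + 1):n] <- sample(c("invertebrate", "algae", "fungi"),
                                  n - head_n, replace = TRUE,
                                  prob = c(0.6, 0.3, 0.1))
    tl <- ifelse(grp %in% c("fish", "mammal", "bird"),
                 round(stats::runif(n, 2.5, 4.5), 1), NA_real_)
    data.frame(otu_id = ids, taxon_name = paste0("Taxon_", ids),
               group = grp, trophic_level = tl)
  })
}

#' Planted meta-web records
#'
#' Converts a fraction of the planted association pairs into
#' consumer -> resource diet records and adds random non-associated records,
#' so trophic-match fractions have a known truth.
#'
#' @param truth a `synthetic_truth`.
#' @param fraction_of_planted fraction of planted pairs turned into records.
#' @param extra_random_edges number of random records disjoint from the
#'   planted pairs.
#' @return A diet-record data frame.
#' @export
planted_metaweb <- function(truth, fraction_of_planted = 1,
                            extra_random_edges = 0) {
  stopifnot(inherits(truth, "synthetic_truth"),
            fraction_of_planted >= 0, fraction_of_planted <= 1)
  pe <- truth$planted_edges
  ids <- rownames(truth$abundance)
  with_local_seed(truth$params$seed + 31L, {
    recs <- NULL
    if (!is.null(pe) && nrow(pe) && fraction_of_planted > 0) {
      take <- seq_len(round(fraction_of_planted * nrow(pe)))
      recs <- data.frame(consumer_otu = pe$otu_a[take],
                         resource_otu = pe$otu_b[take],
                         source = "planted")
    }
    if (extra_random_edges > 0) {
      planted_key <- if (!is.null(pe)) pair_key(pe$otu_a, pe$otu_b)
                     else character()
      got <- 0; extra <- list()
      while (got < extra_random_edges) {
        cand <- sample(ids, 2)
        if (pair_key(cand[1], cand[2]) %in% planted_key) next
        got <- got + 1
        extra[[got]] <- data.frame(consumer_otu = cand[1],
                                   resource_otu = cand[2],
                                   source = "random")
      }
      recs <- rbind(recs, unique(do.call(rbind, extra)))
    }
    if (is.null(recs))
      recs <- data.frame(consumer_otu = character(),
                         resource_otu = character(), source = character())
    recs
  })
}

#' Recovery of planted associations
#'
#' Scores an inferred network against the planted truth. Recall is computed
#' over planted pairs whose both endpoints survived the filters (are in the
#' network's community); sign accuracy is the fraction of recovered planted
#' edges whose inferred sign matches the planted one.
#'
#' @param inferred a `cooc_network`.
#' @param truth a `synthetic_truth` with planted edges.
#' @return List with `precision`, `recall`, `sign_accuracy`, and the counts
#'   behind them (`NA` where a denominator is zero).
#' @export
recovery_metrics <- function(inferred, truth) {
  stopifnot(inherits(inferred, "cooc_network"),
            inherits(truth, "synthetic_truth"))
  pe <- truth$planted_edges
  inf_key <- pair_key(inferred$edges$otu_a, inferred$edges$otu_b)
  if (is.null(pe) || !nrow(pe)) {
    return(list(precision = NA_real_, recall = NA_real_,
                sign_accuracy = NA_real_, n_inferred = length(inf_key),
                n_planted_testable = 0L, n_recovered = 0L))
  }
  testable <- pe[pe$otu_a %in% inferred$community &
                 pe$otu_b %in% inferred$community, , drop = FALSE]
  t_key <- pair_key(testable$otu_a, testable$otu_b)
  recovered <- inf_key %in% t_key
  n_rec <- sum(recovered)
  sign_ok <- NA_real_
  if (n_rec) {
    planted_sign <- stats::setNames(
      ifelse(testable$sign == "+", "copresence", "exclusion"), t_key)
    sign_ok <- mean(inferred$edges$sign[recovered] ==
                      planted_sign[inf_key[recovered]])
  }
  list(precision = if (length(inf_key)) n_rec / length(inf_key) else NA_real_,
       recall = if (length(t_key)) n_rec / length(t_key) else NA_real_,
       sign_accuracy = sign_ok,
       n_inferred = length(inf_key),
       n_planted_testable = length(t_key),
       n_recovered = n_rec)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits per-marker OTU tables, sample and OTU metadata, and diet records in
#' the package's standard TSV formats, so the synthetic path and a real-data
#' path are byte-compatible.
#'
#' @param params a [community_params()].
#' @param dir output directory (created if needed).
#' @param diet_fraction,diet_extra passed to [planted_metaweb()].
#' @return Invisibly, a list of the written file paths plus the `truth`.
#' @export
simulate_dataset <- function(params, dir, diet_fraction = 1,
                             diet_extra = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_community(params)
  tables <- sample_reads(truth)
  paths <- list()
  for (mk in names(tables)) {
    paths[[mk]] <- file.path(dir, paste0("otu_", mk, ".tsv"))
    write_otu_table(tables[[mk]], paths[[mk]])
  }
  smeta <- simulate_sample_metadata(params$n_samples, seed = params$seed)
  paths$sample_metadata <- file.path(dir, "sample_metadata.tsv")
  utils::write.table(smeta, paths$sample_metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ometa <- simulate_otu_metadata(truth)
  paths$otu_metadata <- file.path(dir, "otu_metadata.tsv")
  utils::write.table(ometa, paths$otu_metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  diet <- planted_metaweb(truth, diet_fraction, diet_extra)
  paths$diet_records <- file.path(dir, "diet_records.tsv")
  utils::write.table(diet, paths$diet_records, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(truth = truth)))
}
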