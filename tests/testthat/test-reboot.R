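# synthetic pair-score frame over `n` pairs for one metric
score_frame <- function(scores, metric = "pearson",
                        direction = ifelse(scores > 0, "copresence",
                                           "exclusion")) {
  n <- length(scores)
  data.frame(otu_a = sprintf("a%02d", seq_len(n)),
             otu_b = sprintf("b%02d", seq_len(n)),
             metric = metric, score = scores, direction = direction)
}

test_that("select_tails keeps the top and bottom k with lexicographic tie-breaks", {
  sc <- score_frame(seq(-0.9, 0.9, length.out = 10))
  out <- select_tails(sc, top_k = 3, bottom_k = 3)
  expect_equal(sum(out$selected), 6)
  expect_equal(sum(!out$selected), 4)
  expect_true(all(out$selected[order(-out$score)[1:3]]))

  # tie at the k-th score: lexicographically smaller pair wins
  tied <- score_frame(c(0.5, 0.5, 0.5, 0.1))
  t2 <- select_tails(tied, top_k = 2, bottom_k = 0)
  expect_true(t2$in_top[1] && t2$in_top[2])
  expect_false(t2$in_top[3])

  # more selections than pairs: everything selected
  all_sel <- select_tails(sc, top_k = 500, bottom_k = 500)
  expect_true(all(all_sel$selected))

  # dissimilarity direction by tail; both tails -> unsigned
  dis <- score_frame(c(0.1, 0.2, 0.8, 0.9), metric = "bray_curtis",
                     direction = "unsigned")
  d2 <- select_tails(dis, top_k = 2, bottom_k = 2)
  expect_equal(d2$direction, c("copresence", "copresence",
                               "exclusion", "exclusion"))
  d3 <- select_tails(dis, top_k = 4, bottom_k = 4)
  expect_true(all(d3$direction == "unsigned"))

  # MI selects from the top tail only
  mi <- score_frame(c(0.1, 0.5, 0.9), metric = "mutual_information",
                    direction = "unsigned")
  m2 <- select_tails(mi, top_k = 1, bottom_k = 1)
  expect_equal(sum(m2$selected), 1)
  expect_equal(m2$score[m2$selected], 0.9)
})

test_that("consensus_filter requires support, a sign, and unanimity", {
  mk <- function(metric, direction, score = 0.5)
    data.frame(otu_a = "A", otu_b = "B", metric = metric, score = score,
               direction = direction, in_top = TRUE, in_bottom = FALSE,
               selected = TRUE)
  # unanimous copresence from two correlations -> kept
  ok <- consensus_filter(rbind(mk("pearson", "copresence"),
                               mk("spearman", "copresence")), 2)
  expect_equal(nrow(ok), 1)
  expect_equal(ok$sign, "copresence")
  expect_equal(ok$support, 2L)

  # conflicting signed directions -> dropped
  conflict <- consensus_filter(rbind(mk("pearson", "copresence"),
                                     mk("bray_curtis", "exclusion")), 2)
  expect_equal(nrow(conflict), 0)
  expect_equal(attr(conflict, "dropped")$reason, "conflicting_signs")

  # MI alone: below min_support
  alone <- consensus_filter(mk("mutual_information", "unsigned"), 2)
  expect_equal(nrow(alone), 0)
  expect_equal(attr(alone, "dropped")$reason, "below_min_support")

  # unsigned-only support cannot sign an edge
  unsigned <- consensus_filter(rbind(mk("mutual_information", "unsigned"),
                                     mk("kld", "unsigned")), 2)
  expect_equal(nrow(unsigned), 0)
  expect_equal(attr(unsigned, "dropped")$reason, "no_signed_metric")
})

test_that("reboot_null is deterministic, sized n_perm, and centred for independent pairs", {
  idx <- random_index(8, 30, seed = 10)
  n1 <- reboot_null(idx, "otu01", "otu02", n_perm = 50, seed = 99)
  n2 <- reboot_null(idx, "otu01", "otu02", n_perm = 50, seed = 99)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(50, 5))
  n3 <- reboot_null(idx, "otu01", "otu02", n_perm = 50, seed = 100)
  expect_false(identical(n1, n3))

  # observed score of an independent pair sits inside the null bulk
  obs <- assoc_pearson(idx$values["otu01", ], idx$values["otu02", ])
  expect_gt(obs, quantile(n1[, "pearson"], 0.005))
  expect_lt(obs, quantile(n1[, "pearson"], 0.995))
})

test_that("bootstrap_scores resamples deterministically; perfect correlation stays 1", {
  counts <- count_matrix(0L, 3, 20)
  set.seed(12)
  base <- rpois(20, 50) + 10L
  counts[1, ] <- base          # proportional rows: index vectors identical
  counts[2, ] <- 3L * base
  counts[3, ] <- rpois(20, 40) + 5L
  idx <- index_from_counts(counts)
  b1 <- bootstrap_scores(idx, "otu01", "otu02", metrics = "pearson",
                         n_boot = 40, seed = 7)
  expect_equal(dim(b1), c(40, 1))
  expect_equal(unname(b1[, 1]), rep(1, 40))
  expect_identical(b1, bootstrap_scores(idx, "otu01", "otu02",
                                        metrics = "pearson",
                                        n_boot = 40, seed = 7))
})

test_that("metric_pvalue implements the Gaussian tail and stability rule", {
  null <- c(-0.2, -0.1, 0, 0.1, 0.2)
  boot <- seq(0.5, 0.9, length.out = 50)
  at_mean <- metric_pvalue(0, null, boot)
  expect_equal(at_mean$p, 1)
  expect_true(at_mean$stable)       # null mean 0 outside [0.5, 0.9]

  five_sd <- metric_pvalue(5 * sd(null), null, boot)
  expect_equal(five_sd$p, 2 * pnorm(-5), tolerance = 1e-10)
  expect_equal(five_sd$p, 5.733e-7, tolerance = 1e-3)

  # bootstrap interval containing the null mean -> unstable
  wobbly <- metric_pvalue(0.9, null, seq(-0.5, 0.5, length.out = 50))
  expect_false(wobbly$stable)

  # zero null variance conventions
  expect_equal(metric_pvalue(0.3, rep(0.3, 10), boot)$p, 1)
  expect_equal(metric_pvalue(0.9, rep(0.3, 10), boot)$p, 1 / 11)
})

test_that("brown_merge reduces to Fisher under independence and to the common p under duplication", {
  # Fisher limit: p = (0.5, 0.5), X = 2.773, df 4 -> 0.5966
  fisher <- brown_merge(c(0.5, 0.5), null_pvals = NULL)
  expect_equal(fisher$p, pchisq(-2 * log(0.25), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fisher$p, 0.5966, tolerance = 1e-3)

  # empirical independence: variance of X over independent uniforms ~ 4k
  set.seed(20)
  nulls <- matrix(runif(4000), ncol = 2)
  ind <- brown_merge(c(0.5, 0.5), nulls)
  expect_equal(ind$p, fisher$p, tolerance = 0.05)

  # perfectly dependent duplicated p-values: merged ~ the common p
  u <- runif(2000)
  dup <- matrix(c(u, u), ncol = 2)
  for (p in c(0.01, 0.2, 0.7)) {
    expect_equal(brown_merge(c(p, p), dup)$p, p, tolerance = 0.05)
  }

  # all p = 1 -> merged 1; single p passes through; zeros clamped
  expect_equal(brown_merge(c(1, 1, 1), NULL)$p, 1)
  expect_equal(brown_merge(0.037, NULL)$p, 0.037)
  expect_lt(brown_merge(c(0, 0.5), NULL)$p, 1)
})

test_that("bh_adjust matches the brute-force step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.05, 1.0)), c(0.10, 1.0))

  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
    out <- numeric(n); out[o] <- pmin(q, 1)
    out
  }
  set.seed(30)
  for (rep in 1:1000) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("infer_network is deterministic and monotone in the q threshold", {
  idx <- random_index(10, 25, seed = 31)
  cfg <- cooc_config(n_perm = 40, n_boot = 40, top_k = 20, bottom_k = 20,
                     seed = 5, q_threshold = 0.5)
  net1 <- infer_network(idx, cfg)
  net2 <- infer_network(idx, cfg)
  expect_identical(net1$edges, net2$edges)

  cfg_lo <- cooc_config(n_perm = 40, n_boot = 40, top_k = 20, bottom_k = 20,
                        seed = 5, q_threshold = 0.1)
  net_lo <- infer_network(idx, cfg_lo)
  keys_lo <- paste(net_lo$edges$otu_a, net_lo$edges$otu_b)
  keys_hi <- paste(net1$edges$otu_a, net1$edges$otu_b)
  expect_true(all(keys_lo %in% keys_hi))   # raising q never removes edges

  # edge table columns as specified
  expect_true(all(c("otu_a", "otu_b", "sign", "support", "merged_p",
                    "q_value") %in% names(net1$edges)))
  expect_true(all(net1$edges$q_value <= 0.5))
})

test_that("a strongly coupled pair is detected with the right sign", {
  set.seed(33)
  n <- 40
  f <- rnorm(n)
  counts <- count_matrix(0L, 6, n)
  counts[1, ] <- as.integer(round(exp(3 + 1.6 * f - 0.3)) + 1L)
  counts[2, ] <- as.integer(round(exp(3 + 1.6 * f - 0.1)) + 1L)  # co-present
  counts[3, ] <- as.integer(round(exp(3 - 1.6 * f)) + 1L)        # excluded vs 1
  for (i in 4:6) counts[i, ] <- rpois(n, 60) + 10L
  idx <- index_from_counts(counts)
  net <- infer_network(idx, cooc_config(n_perm = 60, n_boot = 60, seed = 9))
  key <- paste(net$edges$otu_a, net$edges$otu_b)
  expect_true("otu01 otu02" %in% key)
  expect_equal(net$edges$sign[key == "otu01 otu02"], "copresence")
  if ("otu01 otu03" %in% key)
    expect_equal(net$edges$sign[key == "otu01 otu03"], "exclusion")
})
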