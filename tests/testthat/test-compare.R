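test_that("sign_fractions counts co-presences and exclusions", {
  net <- fake_network(data.frame(otu_a = c("A", "B", "C", "D"),
                                 otu_b = c("B", "C", "D", "E"),
                                 sign = c(rep("copresence", 3), "exclusion")))
  sf <- sign_fractions(net)
  expect_equal(sf$fraction_copresence, 0.75)
  expect_equal(sf$fraction_exclusion, 0.25)
  expect_equal(sf$fraction_copresence + sf$fraction_exclusion, 1)

  all_co <- fake_network(data.frame(otu_a = "A", otu_b = "B",
                                    sign = "copresence"))
  expect_equal(sign_fractions(all_co)$fraction_copresence, 1)

  empty <- fake_network(data.frame(otu_a = character(), otu_b = character(),
                                   sign = character()))
  expect_true(is.na(sign_fractions(empty)$fraction_copresence))
})

test_that("edge_overlap counts shared edges over the union, sign-blind", {
  e1 <- data.frame(otu_a = c("A", "A", "B"), otu_b = c("B", "C", "C"),
                   sign = c("copresence", "copresence", "exclusion"))
  e2 <- data.frame(otu_a = c("A", "C"), otu_b = c("B", "D"),
                   sign = c("exclusion", "copresence"))
  ov <- edge_overlap(list(n1 = fake_network(e1), n2 = fake_network(e2)))
  pw <- ov$pairwise
  expect_equal(pw$shared, 1)                  # A-B, despite opposite signs
  expect_equal(pw$union, 4)
  expect_equal(pw$percent_shared, 25)
  expect_equal(pw$sign_agreement, 0)          # signs disagree on A-B

  ident <- edge_overlap(list(a = fake_network(e1), b = fake_network(e1)))
  expect_equal(ident$pairwise$percent_shared, 100)
  disj <- edge_overlap(list(a = fake_network(e1),
                            b = fake_network(data.frame(otu_a = "X",
                                                        otu_b = "Y"))))
  expect_equal(disj$pairwise$percent_shared, 0)

  # symmetry in network order
  ov2 <- edge_overlap(list(n2 = fake_network(e2), n1 = fake_network(e1)))
  expect_equal(ov2$pairwise$shared, pw$shared)
  expect_equal(ov2$pairwise$union, pw$union)
})

test_that("edge overlap reproduces the printed shared-edge arithmetic", {
  # 305- and 413-edge sets sharing 61 edges: union 657 -> 9%
  shared <- sprintf("s%03d a", 1:61)
  e_early <- c(shared, sprintf("e%03d b", 1:244))
  e_late <- c(shared, sprintf("l%03d c", 1:352))
  ov <- edge_overlap(list(early = e_early, late = e_late))
  expect_equal(ov$pairwise$shared, 61)
  expect_equal(ov$pairwise$union, 657)
  expect_equal(ov$pairwise$percent_shared, 9)    # 61/657 = 9.28 -> 9
})

test_that("combine_edge_sets unions edge keys with duplicates removed", {
  a <- fake_network(data.frame(otu_a = c("A", "B"), otu_b = c("B", "C")))
  b <- fake_network(data.frame(otu_a = c("B", "C"), otu_b = c("A", "D")))
  comb <- combine_edge_sets(list(a, b))
  expect_equal(length(comb), 3)    # A-B counted once across both
})

test_that("abundance_degree_correlation matches brute-force covariance and flags degeneracy", {
  set.seed(50)
  n <- 12
  counts <- count_matrix(rpois(n * 10, 40) + 1L, n, 10)
  idx <- index_from_counts(counts)
  ids <- rownames(counts)
  edges <- data.frame(otu_a = ids[1:6], otu_b = ids[7:12])
  edges <- rbind(edges, data.frame(otu_a = ids[1], otu_b = ids[c(3, 5, 8)]))
  net <- fake_network(edges)
  ad <- abundance_degree_correlation(idx, net)
  abun <- rowMeans(idx$values[net$nodes, ])
  deg <- igraph::degree(as_igraph(net))[net$nodes]
  dx <- abun - mean(abun); dy <- deg - mean(deg)
  expect_equal(ad$r, sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2)),
               tolerance = 1e-10)
  expect_true(ad$p >= 0 && ad$p <= 1)

  # all-equal degree -> undefined
  ring <- fake_network(data.frame(otu_a = ids[c(1, 2, 3)],
                                  otu_b = ids[c(2, 3, 1)]))
  expect_true(is.na(abundance_degree_correlation(idx, ring)$r))

  # inverse-rank construction is negative
  neg_net <- fake_network(data.frame(
    otu_a = rep(ids[which.min(abun)], 4),
    otu_b = setdiff(ids, ids[which.min(abun)])[1:4]))
  expect_lt(abundance_degree_correlation(idx, neg_net)$r, 0)
})

test_that("independent abundance and degree rarely exceed |r| = 0.4 at n = 50", {
  set.seed(51)
  hits <- 0
  for (trial in 1:100) {
    abun <- runif(50); deg <- rpois(50, 5) + 1
    r <- suppressWarnings(cor(abun, deg))
    if (abs(r) < 0.4) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("keystone_overlap tracks membership multiplicity", {
  l <- list(w = c("stickleback", "bullhead", "kelp"),
            x = c("stickleback", "bullhead", "copepod"),
            y = c("stickleback", "bullhead", "herring"),
            z = c("stickleback", "bullhead", "sandeel"))
  ko <- keystone_overlap(l)
  shared4 <- ko$membership$otu_id[ko$membership$multiplicity == 4]
  expect_setequal(shared4, c("stickleback", "bullhead"))
  expect_equal(ko$by_multiplicity$n_otus[ko$by_multiplicity$multiplicity == 1],
               4)

  ident <- keystone_overlap(list(a = letters[1:10], b = letters[1:10]))
  expect_equal(sum(ident$membership$multiplicity == 2), 10)
  disj <- keystone_overlap(list(a = letters[1:3], b = letters[4:6]))
  expect_equal(sum(disj$membership$multiplicity > 1), 0)
})
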