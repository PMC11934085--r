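test_that("generate_community is deterministic and validates planted edges", {
  params <- community_params(n_otus = 20, n_samples = 15, seed = 3)
  t1 <- generate_community(params)
  t2 <- generate_community(params)
  expect_identical(t1$abundance, t2$abundance)
  expect_identical(t1$panels, t2$panels)

  bad <- community_params(n_otus = 10, n_samples = 10,
                          planted_edges = data.frame(
                            otu_a = "otu001", otu_b = "nope",
                            sign = "+", strength = 0.5), seed = 1)
  expect_error(generate_community(bad), "unknown OTU")
})

test_that("null communities have latent correlations centred on zero", {
  params <- community_params(n_otus = 40, n_samples = 200,
                             n_env_gradients = 0, rare_fraction = 0,
                             seed = 17)
  truth <- generate_community(params)
  lat <- log(truth$abundance)
  cm <- cor(t(lat))
  offdiag <- cm[upper.tri(cm)]
  expect_gte(length(offdiag), 500)
  expect_lt(abs(mean(offdiag)), 0.05)
})

test_that("planted pairs carry their designed correlation and sign", {
  planted <- data.frame(otu_a = c("otu001", "otu003"),
                        otu_b = c("otu002", "otu004"),
                        sign = c("+", "-"), strength = 0.9)
  params <- community_params(n_otus = 30, n_samples = 200,
                             planted_edges = planted, rare_fraction = 0,
                             seed = 19)
  truth <- generate_community(params)
  lat <- log(truth$abundance)
  r_pos <- cor(lat["otu001", ], lat["otu002", ])
  r_neg <- cor(lat["otu003", ], lat["otu004", ])
  expect_gt(r_pos, 0.6)
  expect_lt(r_neg, -0.6)
})

test_that("sample_reads obeys the multinomial observation model", {
  params <- community_params(n_otus = 15, n_samples = 10, depth = 2000,
                             seed = 23)
  truth <- generate_community(params)
  tabs <- sample_reads(truth)
  expect_equal(length(tabs), 2)
  expect_s3_class(tabs[[1]], "otu_table")
  # OTUs outside a marker's panel get structural zeros
  off_panel <- setdiff(rownames(truth$abundance), truth$panels$marker1)
  expect_true(all(tabs$marker1$counts[off_panel, ] == 0))
  # column sums are the per-sample depths (all panel weights positive here)
  cs <- colSums(tabs$marker1$counts)
  expect_true(all(cs > 0))
  expect_identical(sample_reads(truth)$marker1$counts, tabs$marker1$counts)

  # scaling depth x10 leaves observed proportions approximately unchanged
  deep <- sample_reads(truth, depth_scale = 50)
  p1 <- to_proportions(tabs$marker1$counts[truth$panels$marker1, ])
  p2 <- to_proportions(deep$marker1$counts[truth$panels$marker1, ])
  expect_lt(max(abs(p1 - p2)), 0.1)
  expect_gt(mean(colSums(deep$marker1$counts)) /
              mean(colSums(tabs$marker1$counts)), 25)
})

test_that("amplification efficiency shifts expected read share", {
  params <- community_params(n_otus = 10, n_samples = 50, depth = 5e4,
                             n_env_gradients = 0, rare_fraction = 0,
                             efficiency_sd = 0, seed = 29)
  truth <- generate_community(params)
  base_share <- mean(to_proportions(
    sample_reads(truth)$marker1$counts[truth$panels$marker1, ])["otu001", ])
  truth_hi <- truth
  truth_hi$efficiencies["otu001", "marker1"] <- 10
  hi_share <- mean(to_proportions(
    sample_reads(truth_hi)$marker1$counts[truth$panels$marker1, ])["otu001", ])
  expect_gt(hi_share, 2 * base_share)
})

test_that("rare OTUs fall below the prevalence cutoff", {
  params <- community_params(n_otus = 40, n_samples = 60,
                             rare_fraction = 0.2, seed = 31)
  truth <- generate_community(params)
  expect_gte(length(truth$rare_otus), 1)
  occ <- rowMeans(truth$abundance[truth$rare_otus, , drop = FALSE] > 0)
  expect_true(all(occ < 0.25))
})

test_that("planted_metaweb converts planted pairs into records with known truth", {
  planted <- plant_random_edges(30, 4, 2, strength = 0.8, seed = 7)
  params <- community_params(n_otus = 30, n_samples = 20,
                             planted_edges = planted, seed = 7)
  truth <- generate_community(params)
  rec <- planted_metaweb(truth, fraction_of_planted = 1,
                         extra_random_edges = 0)
  expect_equal(nrow(rec), 6)
  expect_setequal(paste(rec$consumer_otu, rec$resource_otu),
                  paste(planted$otu_a, planted$otu_b))

  rec2 <- planted_metaweb(truth, fraction_of_planted = 0,
                          extra_random_edges = 5)
  expect_equal(nrow(rec2), 5)
  planted_keys <- paste(pmin(planted$otu_a, planted$otu_b),
                        pmax(planted$otu_a, planted$otu_b))
  rec2_keys <- paste(pmin(rec2$consumer_otu, rec2$resource_otu),
                     pmax(rec2$consumer_otu, rec2$resource_otu))
  expect_false(any(rec2_keys %in% planted_keys))
  expect_identical(planted_metaweb(truth, 0, 5), rec2)
})

test_that("recovery_metrics counts hits against the planted truth", {
  planted <- data.frame(otu_a = c("a", "c", "e"), otu_b = c("b", "d", "f"),
                        sign = c("+", "+", "-"), strength = 0.9)
  truth <- structure(list(
    abundance = matrix(1, 6, 2, dimnames = list(letters[1:6], c("s1", "s2"))),
    planted_edges = planted,
    params = list(seed = 1)), class = "synthetic_truth")

  perfect <- fake_network(data.frame(
    otu_a = planted$otu_a, otu_b = planted$otu_b,
    sign = c("copresence", "copresence", "exclusion")),
    community = letters[1:6])
  rm1 <- recovery_metrics(perfect, truth)
  expect_equal(rm1$precision, 1)
  expect_equal(rm1$recall, 1)
  expect_equal(rm1$sign_accuracy, 1)

  empty <- fake_network(data.frame(otu_a = character(),
                                   otu_b = character(),
                                   sign = character()),
                        community = letters[1:6])
  rm2 <- recovery_metrics(empty, truth)
  expect_equal(rm2$recall, 0)
  expect_true(is.na(rm2$precision))

  # half recovered, no false edges: precision 1, recall 0.5 over testable
  half <- fake_network(data.frame(otu_a = "a", otu_b = "b",
                                  sign = "copresence"),
                       community = c("a", "b", "c", "d"))  # e,f filtered out
  rm3 <- recovery_metrics(half, truth)
  expect_equal(rm3$precision, 1)
  expect_equal(rm3$recall, 0.5)     # 1 of the 2 testable planted pairs
})

test_that("simulate_dataset writes a byte-compatible TSV bundle", {
  dir <- withr::local_tempdir()
  params <- community_params(n_otus = 16, n_samples = 12, depth = 2000,
                             seed = 37)
  out <- simulate_dataset(params, dir)
  tab <- read_otu_table(out$marker1, marker = "marker1")
  expect_equal(n_otus(tab), 16)
  meta <- read_sample_metadata(out$sample_metadata)
  expect_equal(nrow(meta), 12)
  ometa <- read_otu_metadata(out$otu_metadata)
  expect_equal(nrow(ometa), 16)
  expect_s3_class(read_diet_records(out$diet_records), "data.frame")
})
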