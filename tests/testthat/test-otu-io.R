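test_that("read_otu_table parses a well-formed TSV and validates bad input", {
  dir <- withr::local_tempdir()
  good <- write_otu_tsv(c("otu_id\ts1\ts2\ts3\ts4",
                          "A\t1\t0\t3\t4",
                          "B\t5\t6\t0\t8",
                          "C\t0\t1\t2\t0"), dir)
  tab <- read_otu_table(good, marker = "12S")
  expect_s3_class(tab, "otu_table")
  expect_equal(n_otus(tab), 3)
  expect_equal(n_samples(tab), 4)
  expect_equal(tab$counts["B", "s4"], 8L)
  expect_equal(tab$marker, "12S")

  bad_neg <- file.path(dir, "neg.tsv")
  writeLines(c("otu_id\ts1\ts2", "A\t1\t-5", "B\t2\t2"), bad_neg)
  expect_error(read_otu_table(bad_neg), "negative count at OTU 'A', sample 's2'")

  empty <- file.path(dir, "empty.tsv")
  writeLines(character(), empty)
  expect_error(read_otu_table(empty), "no data rows")

  ragged <- file.path(dir, "ragged.tsv")
  writeLines(c("otu_id\ts1\ts2", "A\t1\t2", "B\t3"), ragged)
  expect_error(read_otu_table(ragged), "ragged row")

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("otu_id\ts1\ts2", "A\t1\t2", "A\t3\t4"), dup)
  expect_error(read_otu_table(dup), "duplicate OTU ids")

  nonnum <- file.path(dir, "nn.tsv")
  writeLines(c("otu_id\ts1\ts2", "A\t1\t."), nonnum)
  expect_error(read_otu_table(nonnum), "non-numeric count")
})

test_that("write/read round-trips counts and identifiers exactly", {
  set.seed(3)
  counts <- count_matrix(rpois(40, 10), 8, 5)
  tab <- otu_table(counts, marker = "16S")
  path <- file.path(withr::local_tempdir(), "rt.tsv")
  write_otu_table(tab, path)
  back <- read_otu_table(path, marker = "16S")
  expect_identical(back$counts, tab$counts)
  expect_identical(otu_ids(back), otu_ids(tab))
  expect_identical(sample_ids(back), sample_ids(tab))
})

test_that("prevalence filter keeps OTUs at >= 25% occupancy and is idempotent", {
  # 34 samples: present in 8 (0.235) -> removed; in 9 (0.265) -> kept;
  # everywhere -> kept at any threshold <= 1
  counts <- matrix(0L, 3, 34,
                   dimnames = list(c("rare8", "ok9", "everywhere"),
                                   sprintf("s%02d", 1:34)))
  counts["rare8", 1:8] <- 1L
  counts["ok9", 1:9] <- 1L
  counts["everywhere", ] <- 2L
  tab <- otu_table(counts)
  filt <- prevalence_filter(tab, 0.25)
  expect_setequal(otu_ids(filt), c("ok9", "everywhere"))
  expect_equal(attr(filt, "removed_otus"), "rare8")
  expect_equal(n_samples(filt), 34)
  expect_setequal(otu_ids(prevalence_filter(tab, 1)), "everywhere")

  # idempotence
  twice <- prevalence_filter(filt, 0.25)
  expect_identical(twice$counts, filt$counts)

  only_rare <- otu_table(counts["rare8", , drop = FALSE])
  expect_error(prevalence_filter(only_rare, 0.25),
               "empty community after prevalence filter")

  # kept set matches a brute-force occupancy computation on random tables
  set.seed(7)
  for (i in 1:5) {
    m <- count_matrix(rbinom(60, 1, 0.3) * rpois(60, 5), 6, 10)
    t2 <- otu_table(m)
    expected <- rownames(m)[rowSums(m > 0) / 10 >= 0.25]
    if (!length(expected)) next
    expect_setequal(otu_ids(prevalence_filter(t2, 0.25)), expected)
  }
})

test_that("subset_samples restricts by month and shore distance", {
  n <- 57
  counts <- count_matrix(rep(1L, 2 * n), 2, n)
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     month = c(rep("June", 20), rep("July", 14),
                               rep("August", 12), rep("September", 11)),
                     shore_distance_m = c(rep(500, 13), rep(3000, n - 13)))
  tab <- otu_table(counts)
  early <- subset_spec("early", "temporal", months = c("June", "July"))
  expect_equal(n_samples(subset_samples(tab, meta, early)), 34)

  near <- subset_spec("near", "spatial", threshold_m = 1200,
                      side = "nearshore")
  off <- subset_spec("off", "spatial", threshold_m = 1200, side = "offshore")
  expect_equal(n_samples(subset_samples(tab, meta, near)), 13)
  expect_equal(n_samples(subset_samples(tab, meta, off)), n - 13)

  none <- subset_spec("none", "temporal", months = "December")
  expect_error(subset_samples(tab, meta, none), "matches no samples")

  # spatial threshold comparison keeps only the 500 m sample
  m2 <- data.frame(sample_id = c("a", "b"), month = "June",
                   shore_distance_m = c(500, 3000))
  t2 <- otu_table(count_matrix(1:4, 2, 2, samples = c("a", "b")))
  kept <- subset_samples(t2, m2, near)
  expect_equal(sample_ids(kept), "a")

  # an explicit boundary is mandatory for spatial specs
  expect_error(subset_spec("near", "spatial", side = "nearshore"),
               "explicit positive")
  expect_equal(unname(nearshore_presets()), c(1200, 1000))
})

test_that("metadata readers enforce mandatory columns and vocabularies", {
  dir <- withr::local_tempdir()
  sm <- file.path(dir, "sm.tsv")
  writeLines(c("sample_id\tmonth\tshore_distance_m", "s1\tJune\t100"), sm)
  expect_silent(read_sample_metadata(sm))
  writeLines(c("sample_id\tmonth", "s1\tJune"), sm)
  expect_error(read_sample_metadata(sm), "missing columns")

  om <- file.path(dir, "om.tsv")
  writeLines(c("otu_id\ttaxon_name\tgroup\ttrophic_level",
               "A\tGadus\tfish\t4.1", "B\tFucus\talgae\tNA"), om)
  meta <- read_otu_metadata(om)
  expect_equal(meta$trophic_level[1], 4.1)
  writeLines(c("otu_id\ttaxon_name\tgroup", "A\tGadus\tplant"), om)
  expect_error(read_otu_metadata(om), "unknown OTU group")
})
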