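test_that("sample filter keeps samples strictly above the threshold", {
  totals <- c(10000L, 10001L, 9000L, 25000L, 10000L)
  x <- make_depth_experiment(totals)
  out <- filter_samples(x, 10000)
  expect_equal(colnames(out$counts), c("s002", "s004"))
  expect_equal(attr(out, "dropped_samples"), c("s001", "s003", "s005"))

  # all above threshold, and threshold zero: identity
  y <- make_depth_experiment(c(500L, 600L, 700L))
  expect_equal(filter_samples(y, 100)$counts, y$counts)
  expect_equal(filter_samples(y, 0)$counts, y$counts)

  expect_error(filter_samples(y, 1e6), "all samples would be dropped")
})

test_that("sample order of survivors is preserved", {
  x <- make_depth_experiment(c(5000L, 20000L, 30000L, 8000L, 40000L))
  out <- filter_samples(x, 10000)
  expect_equal(colnames(out$counts), c("s002", "s003", "s005"))
  expect_equal(out$samples$sample_id, c("s002", "s003", "s005"))
})

# Hand-built 10-ASV fixture: 2 organelle-labelled, 1 phylum-unassigned,
# 2 below the read threshold, 1 below the prevalence threshold; 4 must
# survive. Applying the rules by hand in their fixed order gives the
# per-step removal counts asserted below.
ten_asv_fixture <- function() {
  counts <- rbind(
    keep1 = c(30, 30, 30, 30), # prevalent, abundant
    chloro = c(50, 50, 50, 50), # organelle (Chloroplast order)
    keep2 = c(20, 20, 20, 20),
    mito = c(40, 40, 40, 40), # organelle (Mitochondria family)
    nophy = c(60, 60, 60, 60), # unassigned phylum
    low1 = c(10, 10, 10, 10), # 40 reads < 50
    keep3 = c(50, 0, 0, 0), # exactly 50 reads, prevalence 1... see below
    low2 = c(49, 0, 0, 0), # 49 reads < 50
    rare = c(60, 0, 0, 0), # abundant but present in 1 sample
    keep4 = c(15, 15, 15, 15)
  )
  colnames(counts) <- paste0("s", 1:4)
  samples <- tibble::tibble(
    sample_id = colnames(counts), dataset_id = "fix",
    group = c("carbon_limited", "carbon_limited", "carbon_rich", "carbon_rich")
  )
  taxonomy <- dplyr::bind_rows(
    tax_row("keep1"), tax_row("chloro", order = "Chloroplast"),
    tax_row("keep2"), tax_row("mito", family = "Mitochondria"),
    tax_row("nophy", phylum = NA), tax_row("low1"),
    tax_row("keep3"), tax_row("low2"), tax_row("rare"), tax_row("keep4")
  )
  asv_experiment(counts, samples, taxonomy)
}

test_that("ASV filters remove in fixed order with correct boundaries", {
  x <- ten_asv_fixture()
  # prevalence 1 keeps keep3 (and rare), so use min_prevalence = 1 first:
  pol <- filter_policy(min_asv_reads = 50, min_prevalence = 1)
  out <- filter_asvs(x, pol)
  # 49 reads removed, exactly 50 retained (strict <)
  expect_true("keep3" %in% rownames(out$counts))
  expect_false("low2" %in% rownames(out$counts))

  # with a prevalence floor of 2 samples, keep3 and rare drop too
  pol2 <- filter_policy(min_asv_reads = 50, min_prevalence = 2)
  out2 <- filter_asvs(x, pol2)
  expect_setequal(rownames(out2$counts), c("keep1", "keep2", "keep4"))
  rep2 <- attr(out2, "filter_report")
  expect_equal(
    rep2$n_asvs[match(
      c("taxonomy_exclusion", "unassigned_phylum", "low_total_reads", "low_prevalence", "retained"),
      rep2$step
    )],
    c(2, 1, 2, 2, 3)
  )
})

test_that("prevalence boundary is strict and can be counted over profiles", {
  counts <- matrix(20L, nrow = 2, ncol = 6,
    dimnames = list(c("a", "b"), paste0("s", 1:6))
  )
  counts["b", 5:6] <- 0L # b present in 4 samples / 2 profiles
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:6), dataset_id = "fix",
    group = rep(c("carbon_limited", "carbon_rich"), 3),
    profile_id = rep(c("p1", "p2", "p3"), each = 2)
  )
  tax <- dplyr::bind_rows(tax_row("a"), tax_row("b"))
  x <- asv_experiment(counts, samples, tax)

  # present in exactly min_prevalence units: retained (removal is "<")
  pol <- filter_policy(min_asv_reads = 0, min_prevalence = 4)
  expect_setequal(rownames(filter_asvs(x, pol)$counts), c("a", "b"))
  pol5 <- filter_policy(min_asv_reads = 0, min_prevalence = 5)
  expect_equal(rownames(filter_asvs(x, pol5)$counts), "a")

  polp <- filter_policy(min_asv_reads = 0, min_prevalence = 3, prevalence_unit = "profile")
  expect_equal(rownames(filter_asvs(x, polp)$counts), "a")
  polp2 <- filter_policy(min_asv_reads = 0, min_prevalence = 2, prevalence_unit = "profile")
  expect_setequal(rownames(filter_asvs(x, polp2)$counts), c("a", "b"))
})

test_that("low-confidence taxonomy is treated as unassigned", {
  counts <- matrix(100L, 2, 4, dimnames = list(c("hi", "lo"), paste0("s", 1:4)))
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:4), dataset_id = "fix",
    group = rep(c("carbon_limited", "carbon_rich"), 2)
  )
  tax <- dplyr::bind_rows(
    tax_row("hi", confidence = 0.9),
    tax_row("lo", confidence = 0.4)
  )
  x <- asv_experiment(counts, samples, tax)
  out <- filter_asvs(x, filter_policy(min_asv_reads = 0))
  expect_equal(rownames(out$counts), "hi")
})

test_that("filtering is idempotent and errors on missing taxonomy", {
  x <- ten_asv_fixture()
  pol <- filter_policy(min_asv_reads = 50, min_prevalence = 2)
  once <- filter_asvs(x, pol)
  twice <- filter_asvs(once, pol)
  expect_equal(twice$counts, once$counts)

  x2 <- ten_asv_fixture()
  x2$taxonomy <- x2$taxonomy[-1, ]
  expect_error(filter_asvs(x2, pol), "taxonomy row missing")
})

test_that("relative abundances are per-sample fractions", {
  counts <- matrix(c(10L, 30L, 60L, 0L, 0L, 5L), nrow = 3,
    dimnames = list(c("a", "b", "c"), c("s1", "s2"))
  )
  samples <- tibble::tibble(
    sample_id = c("s1", "s2"), dataset_id = "fix",
    group = c("carbon_limited", "carbon_rich")
  )
  x <- asv_experiment(counts, samples)
  ra <- relative_abundance(x)
  expect_equal(unname(ra[, "s1"]), c(0.1, 0.3, 0.6))
  # single nonzero ASV gets fraction 1
  expect_equal(unname(ra["c", "s2"]), 1.0)
  expect_equal(unname(colSums(ra)), c(1, 1), tolerance = 1e-12)

  counts0 <- counts
  counts0[, 2] <- 0L
  x0 <- asv_experiment(counts0, samples)
  expect_error(relative_abundance(x0), "zero-total")
})
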