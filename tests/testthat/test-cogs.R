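test_that("per-Mbp normalisation is exact and scale-invariant", {
  expect_equal(normalize_cogs(c(cogA = 10), 5e6), c(cogA = 2))
  expect_equal(normalize_cogs(c(cogA = 0), 3e6), c(cogA = 0))
  expect_equal(normalize_cogs(c(cogA = 20), 10e6), normalize_cogs(c(cogA = 10), 5e6))

  counts <- tibble::tibble(
    accession = c("g1", "g1", "g2"),
    cog = c("cogA", "cogB", "cogA"),
    count = c(10L, 5L, 6L)
  )
  sizes <- tibble::tibble(accession = c("g1", "g2"), genome_size = c(5e6, 3e6))
  norm <- normalize_cogs(counts, sizes)
  expect_equal(norm$per_mbp, c(2, 1, 2))
  expect_error(normalize_cogs(counts, c(g1 = 5e6)), "missing")
})

test_that("category proportions use the total gene denominator and multi-count", {
  counts <- tibble::tibble(
    accession = "g1",
    cog = c("c1", "c2", "c3"),
    count = c(4L, 5L, 1L)
  )
  cog2cat <- tibble::tibble(
    cog = c("c1", "c2", "c3", "c3"),
    category = c("E", "K", "E", "T")
  )
  prop <- category_proportions(counts, cog2cat)
  p <- setNames(prop$proportion, prop$category)
  # 10 genes total; c1 (4) and c3 (1) in E -> 0.5; the multi-category
  # gene also counts in T, so proportions sum above 1
  expect_equal(unname(p["E"]), 0.5)
  expect_equal(unname(p["K"]), 0.5)
  expect_equal(unname(p["T"]), 0.1)
  expect_gt(sum(p), 1)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(sort(prop$category), sort(cog_category_letters()))

  # four genes of ten in one single-category COG -> 0.4
  counts2 <- tibble::tibble(
    accession = "g1", cog = c("c1", "c2"), count = c(4L, 6L)
  )
  map2 <- tibble::tibble(cog = c("c1", "c2"), category = c("E", "K"))
  p2 <- category_proportions(counts2, map2)
  expect_equal(p2$proportion[p2$category == "E"], 0.4)

  # invariant to COG row ordering
  prop_rev <- category_proportions(counts[3:1, ], cog2cat)
  expect_equal(
    dplyr::arrange(prop, category), dplyr::arrange(prop_rev, category)
  )

  empty <- tibble::tibble(accession = "g1", cog = "c1", count = 0L)
  expect_error(category_proportions(empty, cog2cat), "empty COG profile")
})

test_that("hypothesis scores sum member abundances and are additive", {
  norm <- tibble::tibble(
    accession = rep(c("g1", "g2", "g3"), each = 3),
    cog = rep(c("c1", "c2", "c3"), 3),
    per_mbp = c(1, 2, 4, 0.5, 0, 3, 2, 2, 2)
  )
  cog2cat <- tibble::tibble(cog = c("c2", "c3"), category = c("Q", "Q"))
  map <- tibble::tibble(
    hypothesis_id = c("h_one", "h_cat", "h_union", "h_union"),
    label = "x",
    member_type = c("cog", "category", "cog", "category"),
    member_id = c("c1", "Q", "c1", "Q"),
    expected_direction = "oligotroph_enriched"
  )
  sc <- hypothesis_scores(norm, map, cog2cat)
  get <- function(h, g) sc$score[sc$hypothesis_id == h & sc$accession == g]
  # single-COG hypothesis equals that COG's abundance
  expect_equal(get("h_one", "g1"), 1)
  # category member expands to its COG set: c2 + c3
  expect_equal(get("h_cat", "g1"), 6)
  expect_equal(get("h_cat", "g2"), 3)
  # union of disjoint specs = sum of the parts (hand sums per genome)
  for (g in c("g1", "g2", "g3")) {
    expect_equal(get("h_union", g), get("h_one", g) + get("h_cat", g))
  }
})

test_that("the shipped hypothesis map loads and resolves in the synthetic catalogue", {
  map <- default_hypothesis_map()
  expect_true(all(c("h_prox", "h_motility", "h_thiamine") %in% map$hypothesis_id))
  expect_true(all(map$expected_direction %in%
    c("oligotroph_enriched", "copiotroph_enriched")))
  cat <- simulate_genomes(genome_sim_config(n_genomes_per_class = 2, n_cds = 4, seed = 1))
  cog_members <- map$member_id[map$member_type == "cog"]
  expect_true(all(cog_members %in% cat$cog_counts$cog))
  norm <- normalize_cogs(cat$cog_counts, cat$metadata)
  sc <- hypothesis_scores(norm, map, cat$cog2cat)
  expect_equal(nrow(sc), 4 * dplyr::n_distinct(map$hypothesis_id))
})

test_that("profile contrasts: null identity, antisymmetry and planted detection", {
  # identical feature in both classes
  m <- matrix(5, nrow = 8, ncol = 2,
    dimnames = list(paste0("g", 1:8), c("f1", "f2"))
  )
  labels <- rep(c("oligotroph", "copiotroph"), each = 4)
  out <- compare_profiles(m, labels)
  expect_true(all(out$p_raw == 1))
  expect_true(all(out$effect == 0))

  # swapping class labels negates every effect
  set.seed(31)
  m2 <- matrix(rnorm(60 * 5, 10), nrow = 60,
    dimnames = list(sprintf("g%02d", 1:60), paste0("f", 1:5))
  )
  lab <- rep(c("oligotroph", "copiotroph"), each = 30)
  swapped <- ifelse(lab == "oligotroph", "copiotroph", "oligotroph")
  a <- compare_profiles(m2, lab)
  b <- compare_profiles(m2, swapped)
  expect_equal(b$effect, -a$effect)
  expect_equal(b$p_raw, a$p_raw)

  # planted 3x enrichment of one COG in the oligotroph class at n=30/30
  set.seed(32)
  base <- matrix(rpois(60 * 40, 5), nrow = 60,
    dimnames = list(sprintf("g%02d", 1:60), sprintf("cog%03d", 1:40))
  )
  base[lab == "oligotroph", "cog007"] <- rpois(30, 15)
  out3 <- compare_profiles(base, lab)
  hit <- out3[out3$feature == "cog007", ]
  expect_lt(hit$p_adj, 0.05)
  expect_lt(hit$effect, 0)
  expect_equal(hit$direction, "oligotroph_enriched")
})

test_that("consistency screen labels follow the all-datasets rule and partition", {
  cogs <- sprintf("c%03d", 1:10)
  d1 <- outcome_from_directions(cogs, c(
    "oligotroph_enriched", "oligotroph_enriched", "copiotroph_enriched",
    "ns", "oligotroph_enriched", rep("ns", 5)
  ))
  d2 <- outcome_from_directions(cogs, c(
    "oligotroph_enriched", "ns", "copiotroph_enriched",
    "ns", "oligotroph_enriched", rep("ns", 5)
  ))
  d3 <- outcome_from_directions(cogs, c(
    "oligotroph_enriched", "oligotroph_enriched", "copiotroph_enriched",
    "ns", "copiotroph_enriched", rep("ns", 5)
  ))
  scr <- consistency_screen(list(a = d1, b = d2, c = d3))
  res <- tidy(scr)
  lab <- setNames(res$consistent_label, res$cog)
  # significant with the same direction in all three datasets
  expect_equal(unname(lab["c001"]), "oligotroph_consistent")
  expect_equal(unname(lab["c003"]), "copiotroph_consistent")
  # significant in only 2 of 3, or with discordant directions
  expect_equal(unname(lab["c002"]), "inconsistent_or_ns")
  expect_equal(unname(lab["c005"]), "inconsistent_or_ns")
  gl <- glance(scr)
  expect_equal(
    gl$n_oligotroph_consistent + gl$n_copiotroph_consistent + gl$n_remaining,
    gl$n_universe
  )
  expect_error(
    consistency_screen(list(d1, d2[1:9, ], d3)),
    "universe"
  )
})

test_that("label-permuted profiles produce essentially no consistent hits", {
  set.seed(55)
  n_genomes <- 20
  n_cogs <- 120
  mats <- lapply(1:3, function(i) {
    matrix(rpois(n_genomes * n_cogs, 4), nrow = n_genomes,
      dimnames = list(sprintf("g%02d", 1:n_genomes), sprintf("c%03d", 1:n_cogs))
    )
  })
  labels <- rep(c("oligotroph", "copiotroph"), each = n_genomes / 2)
  hits <- vapply(1:100, function(rep) {
    outs <- lapply(mats, function(m) {
      compare_profiles(m, sample(labels))
    })
    scr <- consistency_screen(outs)
    sum(scr$summary$n_cogs[1:2])
  }, numeric(1))
  # expected consistent-hit rate under the null is far below 1% of the universe
  expect_lte(mean(hits), 0.01 * n_cogs)
})

test_that("presence/absence mode tests occurrence rather than abundance", {
  set.seed(61)
  lab <- rep(c("oligotroph", "copiotroph"), each = 12)
  # same occurrence pattern, very different abundances
  m <- matrix(rpois(24, 3) + 1, nrow = 24, dimnames = list(sprintf("g%02d", 1:24), "f1"))
  m[lab == "copiotroph", 1] <- m[lab == "copiotroph", 1] * 50
  ab <- compare_profiles(m, lab)
  pa <- compare_profiles(m, lab, presence_absence = TRUE)
  expect_lt(ab$p_raw, 0.01)
  expect_equal(pa$p_raw, 1) # present everywhere in both classes
  expect_equal(pa$effect, 0)
})
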