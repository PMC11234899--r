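test_that("identity is exact on identical, reverse-complement and mutated pairs", {
  q <- random_dna(250, seed = 1)
  expect_equal(sequence_identity(q, q), list(identity = 1, strand = "+"))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  res <- sequence_identity(q, rc)
  expect_equal(res$identity, 1)
  expect_equal(res$strand, "-")

  # two substitutions over 250 nt -> 248/250
  frag <- strsplit(q, "")[[1]]
  frag[c(30, 200)] <- vapply(frag[c(30, 200)], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  res <- sequence_identity(paste(frag, collapse = ""), q)
  expect_equal(res$identity, 248 / 250)
  expect_equal(res$strand, "+")
})

test_that("terminal gaps on the longer reference are free", {
  set.seed(2)
  core <- random_dna(250)
  ref <- paste0(random_dna(300), core, random_dna(250))
  expect_equal(sequence_identity(core, ref)$identity, 1)
})

test_that("identity is strand-symmetric and rejects bad alphabets", {
  set.seed(3)
  q <- random_dna(120)
  r <- paste0(random_dna(40), q, random_dna(40))
  fwd <- sequence_identity(q, r)
  rev <- sequence_identity(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(q))), r
  )
  expect_equal(rev$identity, fwd$identity)
  expect_setequal(c(fwd$strand, rev$strand), c("-", "+"))

  expect_error(sequence_identity("ACGU", "ACGT"), "alphabet")
  expect_error(sequence_identity("", "ACGT"), "non-empty")
})

test_that("N bases never count as matches", {
  q <- "ACGTACGTAC"
  qn <- "ACGTNCGTAC"
  expect_equal(sequence_identity(qn, q)$identity, 9 / 10)
  # N against N is still not a match
  expect_equal(sequence_identity(qn, qn)$identity, 9 / 10)
})

test_that("best match honours threshold and completeness/contamination tie-breaks", {
  set.seed(7)
  seq16s <- random_dna(800)
  asv <- substr(seq16s, 100, 349)

  # identical 16S in two genomes: higher completeness wins
  cat1 <- make_catalogue(
    c(g_low = seq16s, g_high = seq16s),
    tibble::tibble(
      accession = c("g_low", "g_high"),
      checkm_completeness = c(92, 98),
      checkm_contamination = c(1, 1)
    )
  )
  expect_equal(best_match(asv, cat1)$accession, "g_high")

  # completeness tied: lower contamination wins
  cat2 <- make_catalogue(
    c(g_dirty = seq16s, g_clean = seq16s),
    tibble::tibble(
      accession = c("g_dirty", "g_clean"),
      checkm_completeness = c(98, 98),
      checkm_contamination = c(3.5, 1.0)
    )
  )
  expect_equal(best_match(asv, cat2)$accession, "g_clean")

  # identity below threshold: no match (10 mismatches over 250 = 0.96)
  frag <- strsplit(asv, "")[[1]]
  idx <- seq(5, 230, by = 25)
  frag[idx] <- vapply(frag[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  far <- paste(frag, collapse = "")
  cat3 <- make_catalogue(c(g1 = seq16s))
  expect_null(best_match(far, cat3, threshold = 0.97))
  expect_equal(best_match(far, cat3, threshold = 0.95)$identity, 240 / 250)
})

test_that("multi-copy genomes are represented by their best 16S copy", {
  set.seed(8)
  good <- random_dna(800)
  bad <- random_dna(800)
  asv <- substr(good, 200, 449)
  cat <- make_catalogue(c(g1 = bad, g1 = good, g2 = random_dna(800)))
  hit <- best_match(asv, cat)
  expect_equal(hit$accession, "g1")
  expect_equal(hit$identity, 1)
})

test_that("matching is independent of catalogue ordering", {
  set.seed(9)
  refs <- setNames(replicate(5, random_dna(600)), paste0("g", 1:5))
  asvs <- Biostrings::DNAStringSet(setNames(
    vapply(refs[c(2, 4)], function(r) substr(r, 50, 299), character(1)),
    c("asv1", "asv2")
  ))
  meta <- tibble::tibble(
    accession = names(refs),
    checkm_completeness = c(90, 95, 80, 99, 85),
    checkm_contamination = c(2, 1, 3, 0.5, 1)
  )
  m1 <- match_asvs(asvs, make_catalogue(refs, meta))
  perm <- c(4, 1, 5, 3, 2)
  m2 <- match_asvs(asvs, make_catalogue(refs[perm], meta[perm, ]))
  expect_equal(m1, m2)
  expect_equal(m1$accession, c("g2", "g4"))
})

test_that("planted 16S fragments are recalled perfectly at <=3 mismatches", {
  gcfg <- genome_sim_config(n_genomes_per_class = 4, n_cds = 4, seed = 31)
  cat <- simulate_genomes(gcfg)
  truth <- tibble::tibble(
    asv_id = sprintf("asv_%02d", 1:16),
    truth = rep(c("planted_oligotroph", "planted_copiotroph"), 8)
  )
  seqs <- simulate_asv_sequences(cat, truth, max_mismatches = 3, seed = 5)
  matches <- match_asvs(seqs$seqs, cat)
  expect_equal(nrow(matches), 16)
  expect_equal(
    matches$accession[match(seqs$sources$asv_id, matches$asv_id)],
    seqs$sources$accession
  )
  # constructed identity: k mismatches over 250 nt
  joined <- dplyr::inner_join(matches, seqs$sources, by = c("asv_id", "accession"))
  expect_equal(joined$identity, (250 - joined$n_mismatches) / 250)
  expect_equal(joined$strand.x, joined$strand.y)
})

test_that("genome sets resolve to disjoint groups with shared genomes removed", {
  res <- resolve_genome_sets(c("g1", "g2"), c("g2", "g3"))
  expect_equal(res, list(oligotroph = "g1", copiotroph = "g3", removed = "g2"))

  res2 <- resolve_genome_sets(c("a", "b"), c("c"))
  expect_equal(res2$removed, character(0))
  expect_equal(res2$oligotroph, c("a", "b"))

  # many-to-one ASV->genome fixture: 10 ASVs onto 4 genomes, one shared
  olig <- tibble::tibble(
    asv_id = paste0("o", 1:5),
    accession = c("gA", "gA", "gB", "gB", "gS")
  )
  copio <- tibble::tibble(
    asv_id = paste0("c", 1:5),
    accession = c("gC", "gC", "gC", "gS", "gS")
  )
  res3 <- resolve_genome_sets(olig, copio)
  expect_equal(res3$oligotroph, c("gA", "gB"))
  expect_equal(res3$copiotroph, "gC")
  expect_equal(res3$removed, "gS")
  # partition bookkeeping: disjoint outputs covering all matched accessions
  expect_length(intersect(res3$oligotroph, res3$copiotroph), 0)
  expect_equal(
    sort(c(res3$oligotroph, res3$copiotroph, res3$removed)),
    sort(unique(c(olig$accession, copio$accession)))
  )
})
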