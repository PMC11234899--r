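# Independent oracles and fixture builders shared across test files.

# Exhaustive permutation oracle for the two-sided Mann-Whitney p-value:
# enumerates every assignment of the pooled observations into groups of
# the observed sizes and counts splits at least as extreme (in |U - mu|)
# as the observed one.
mw_enumeration_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  splits <- utils::combn(n, n1)
  us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Minimal experiment with explicit per-sample totals (one dominant ASV
# plus a remainder row so column sums hit the requested totals exactly).
make_depth_experiment <- function(totals, groups = NULL, dataset_id = "fix") {
  n <- length(totals)
  groups <- groups %||% rep(c("carbon_limited", "carbon_rich"), length.out = n)
  counts <- rbind(
    asv_a = pmin(totals, 1L),
    asv_b = pmax(totals - 1L, 0L)
  )
  colnames(counts) <- sprintf("s%03d", seq_len(n))
  samples <- tibble::tibble(
    sample_id = colnames(counts), dataset_id = dataset_id, group = groups
  )
  asv_experiment(counts, samples)
}

# Taxonomy row builder with sensible defaults.
tax_row <- function(asv_id, phylum = "Acidobacteriota", order = "ord",
                    family = "fam", domain = "Bacteria", confidence = 0.9) {
  tibble::tibble(
    asv_id = asv_id, domain = domain, phylum = phylum, class = "cls",
    order = order, family = family, genus = "gen", confidence = confidence
  )
}

# Complete-separation relative-abundance matrix: `n_olig` ASVs strictly
# higher in every carbon-limited sample, `n_copio` strictly higher in
# every carbon-rich sample, `n_ns` identical across groups up to noise
# that keeps them far from significance.
separation_relabund <- function(n_olig, n_copio, n_ns, n_lim, n_rich, seed = 1) {
  set.seed(seed)
  n_asv <- n_olig + n_copio + n_ns
  n_s <- n_lim + n_rich
  lim_cols <- seq_len(n_lim)
  rich_cols <- n_lim + seq_len(n_rich)
  m <- matrix(runif(n_asv * n_s), nrow = n_asv)
  if (n_olig > 0) m[seq_len(n_olig), lim_cols] <- m[seq_len(n_olig), lim_cols] + 2
  if (n_copio > 0) {
    rows <- n_olig + seq_len(n_copio)
    m[rows, rich_cols] <- m[rows, rich_cols] + 2
  }
  rownames(m) <- sprintf("asv_%05d", seq_len(n_asv))
  colnames(m) <- sprintf("s%04d", seq_len(n_s))
  list(
    relabund = m,
    groups = rep(c("carbon_limited", "carbon_rich"), c(n_lim, n_rich))
  )
}

# Tiny genome catalogue around explicit 16S sequences (for matching
# tests); completeness/contamination taken from the supplied tibble.
make_catalogue <- function(ssu_named, meta = NULL) {
  accs <- unique(names(ssu_named))
  meta <- meta %||% tibble::tibble(
    accession = accs,
    checkm_completeness = 95,
    checkm_contamination = 1
  )
  list(ssu = Biostrings::DNAStringSet(ssu_named), metadata = meta)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Uniform codon-count vector over the 59 family codons (count per codon).
uniform_codon_counts <- function(per_codon = 1000L) {
  fams <- oligotraits:::.codon_families
  setNames(
    rep(per_codon, length(unlist(fams))),
    unlist(fams, use.names = FALSE)
  )
}

# Outcome tibble shaped like compare_profiles() output, from a direction
# label vector (used to exercise the consistency screen's accounting).
outcome_from_directions <- function(cogs, directions) {
  tibble::tibble(
    feature = cogs,
    u_statistic = 0,
    p_raw = ifelse(directions == "ns", 0.5, 1e-8),
    p_adj = ifelse(directions == "ns", 1, 1e-5),
    effect = ifelse(directions == "oligotroph_enriched", -1,
      ifelse(directions == "copiotroph_enriched", 1, 0)
    ),
    direction = directions
  )
}
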