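#' Configuration for a synthetic reference-genome catalogue
#'
#' Parameterises the two life-history classes ("oligotroph",
#' "copiotroph") of a planted genome catalogue: genome size, MAG
#' probability, GC, rRNA operon count, codon-usage bias of highly
#' expressed genes, and COG content. Per-class arguments are named
#' length-2 vectors (or lists) with elements `oligotroph` and
#' `copiotroph`.
#'
#' Defaults encode the trait contrasts the analysis is designed to
#' detect: oligotroph genomes are smaller, more often MAGs, carry fewer
#' rRNA operons, show weaker HEG codon bias, and are enriched for a
#' small set of stress/storage/uptake COGs, while copiotroph genomes
#' are enriched for a biosynthesis COG.
#'
#' @param n_genomes_per_class Genomes per class.
#' @param size_mean_bp,size_sd_bp Normal genome-size model per class
#'   (shared sd), in bp.
#' @param mag_prob Probability that a genome is a MAG (vs isolate).
#' @param gc_mean Mean GC fraction per class (reported in metadata as a
#'   percentage).
#' @param ssu_mean Mean rRNA operon (SSU) count per class; counts are
#'   drawn as `1 + Poisson(ssu_mean - 1)`.
#' @param n_cds CDS per genome.
#' @param heg_fraction Fraction of CDS flagged highly expressed.
#' @param bias_strength Codon-usage skew of HEGs per class, in
#'   \[0, 1\]: 0 = uniform synonymous usage, 1 = a single preferred
#'   codon per family.
#' @param cds_len_codons Codons per CDS.
#' @param ssu_len Length of each genome's 16S reference sequence (nt).
#' @param cog_catalogue_size Total COG ids in the synthetic catalogue
#'   (hypothesis-map members are always included).
#' @param enriched_cogs Named list per class: named numeric vectors of
#'   COG id -> rate multiplier planted in that class.
#' @param seed Integer seed.
#' @return A `genome_sim_config` list.
#' @export
genome_sim_config <- function(n_genomes_per_class = 20,
                              size_mean_bp = c(oligotroph = 3.5e6, copiotroph = 5.5e6),
                              size_sd_bp = 6e5,
                              mag_prob = c(oligotroph = 0.70, copiotroph = 0.35),
                              gc_mean = c(oligotroph = 0.60, copiotroph = 0.645),
                              ssu_mean = c(oligotroph = 1.5, copiotroph = 3.5),
                              n_cds = 60,
                              heg_fraction = 0.1,
                              bias_strength = c(oligotroph = 0.15, copiotroph = 0.65),
                              cds_len_codons = 300,
                              ssu_len = 800,
                              cog_catalogue_size = 120,
                              enriched_cogs = list(
                                oligotroph = c(
                                  COG2113 = 3, COG1595 = 3, COG0380 = 3,
                                  COG1529 = 3, COG0374 = 3, COG3243 = 3
                                ),
                                copiotroph = c(COG0422 = 3, COG1868 = 3)
                              ),
                              seed = 1) {
  classes <- c("oligotroph", "copiotroph")
  per_class <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, 2L), classes)
    if (!all(classes %in% names(x))) {
      stop("`", what, "` must name both classes", call. = FALSE)
    }
    x[classes]
  }
  cfg <- list(
    n_genomes_per_class = per_class(n_genomes_per_class, "n_genomes_per_class"),
    size_mean_bp = per_class(size_mean_bp, "size_mean_bp"),
    size_sd_bp = size_sd_bp,
    mag_prob = per_class(mag_prob, "mag_prob"),
    gc_mean = per_class(gc_mean, "gc_mean"),
    ssu_mean = per_class(ssu_mean, "ssu_mean"),
    n_cds = n_cds,
    heg_fraction = heg_fraction,
    bias_strength = per_class(bias_strength, "bias_strength"),
    cds_len_codons = cds_len_codons,
    ssu_len = ssu_len,
    cog_catalogue_size = cog_catalogue_size,
    enriched_cogs = enriched_cogs,
    seed = seed
  )
  if (any(cfg$n_genomes_per_class < 1)) stop("both classes need genomes", call. = FALSE)
  if (any(cfg$size_mean_bp <= 0) || cfg$size_sd_bp <= 0) {
    stop("genome sizes must be positive", call. = FALSE)
  }
  for (f in c("mag_prob", "gc_mean")) {
    if (any(cfg[[f]] < 0 | cfg[[f]] > 1)) {
      stop("`", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$heg_fraction <= 0 || cfg$heg_fraction >= 1) {
    stop("`heg_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (any(cfg$bias_strength < 0 | cfg$bias_strength > 1)) {
    stop("`bias_strength` must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "genome_sim_config")
}

# internal: codon sampling distribution over the 59 degenerate-family
# codons; bias b interpolates uniform -> single preferred codon per family
codon_distribution <- function(bias) {
  codons <- unlist(.codon_families, use.names = FALSE)
  fam_of <- rep(names(.codon_families), .family_degeneracy)
  p <- numeric(length(codons))
  for (fam in names(.codon_families)) {
    idx <- which(fam_of == fam)
    k <- length(idx)
    within <- rep((1 - bias) / k, k)
    within[1L] <- within[1L] + bias
    # amino acids weighted by family size so the background is uniform
    p[idx] <- (k / length(codons)) * within
  }
  setNames(p, codons)
}

# internal: one set of CDS strings drawn codon-by-codon
draw_cds <- function(n_genes, len_codons, dist) {
  codons <- sample(names(dist), n_genes * len_codons, replace = TRUE, prob = dist)
  mat <- matrix(codons, nrow = len_codons)
  apply(mat, 2L, paste, collapse = "")
}

#' Simulate a reference-genome catalogue with planted class contrasts
#'
#' Generates, per genome: reference-database-style metadata (origin,
#' size, GC, SSU count, completeness, contamination), a synthetic 16S
#' sequence, CDS with class-dependent codon-usage bias in the highly
#' expressed subset, and COG counts with class-dependent enrichment.
#' Deterministic under `seed`.
#'
#' @param gcfg A [genome_sim_config()].
#' @return List with `metadata` (tibble), `ssu` (`DNAStringSet`, one
#'   16S per genome, named by accession), `cds` (`DNAStringSet` named
#'   by CDS id), `cds_info` (tibble: `accession`, `cds_id`, `heg`),
#'   `cog_counts` (tibble: `accession`, `cog`, `count`), `cog2cat`
#'   (tibble: `cog`, `category`), `truth` (tibble: `accession`,
#'   `class`).
#' @export
simulate_genomes <- function(gcfg) {
  stopifnot(inherits(gcfg, "genome_sim_config"))
  set.seed(gcfg$seed)
  classes <- c("oligotroph", "copiotroph")
  n <- gcfg$n_genomes_per_class

  acc <- sprintf(
    "SYN_%s_%03d",
    rep(c("OLI", "COP"), n),
    unlist(lapply(n, seq_len))
  )
  cls <- rep(classes, n)
  total <- length(acc)

  is_mag <- runif(total) < gcfg$mag_prob[cls]
  metadata <- tibble::tibble(
    accession = acc,
    genome_category = ifelse(is_mag, "MAG", "isolate"),
    genome_size = round(pmax(5e5, rnorm(total, gcfg$size_mean_bp[cls], gcfg$size_sd_bp))),
    gc_percentage = round(100 * pmin(pmax(rnorm(total, gcfg$gc_mean[cls], 0.02), 0.2), 0.8), 2),
    ssu_count = 1L + rpois(total, pmax(gcfg$ssu_mean[cls] - 1, 0)),
    checkm_completeness = round(ifelse(is_mag, runif(total, 70, 99), runif(total, 95, 100)), 2),
    checkm_contamination = round(ifelse(is_mag, runif(total, 0, 8), runif(total, 0, 2)), 2)
  )

  ssu <- Biostrings::DNAStringSet(vapply(seq_len(total), function(i) {
    paste(sample(c("A", "C", "G", "T"), gcfg$ssu_len, replace = TRUE), collapse = "")
  }, character(1)))
  names(ssu) <- acc

  n_heg <- max(1L, round(gcfg$heg_fraction * gcfg$n_cds))
  bg_dist <- codon_distribution(0)
  cds_list <- vector("list", total)
  info_list <- vector("list", total)
  for (i in seq_len(total)) {
    heg_dist <- codon_distribution(gcfg$bias_strength[cls[i]])
    genes <- c(
      draw_cds(gcfg$n_cds - n_heg, gcfg$cds_len_codons, bg_dist),
      draw_cds(n_heg, gcfg$cds_len_codons, heg_dist)
    )
    ids <- sprintf("%s|cds%03d", acc[i], seq_along(genes))
    cds_list[[i]] <- setNames(genes, ids)
    info_list[[i]] <- tibble::tibble(
      accession = acc[i],
      cds_id = ids,
      heg = c(rep(FALSE, gcfg$n_cds - n_heg), rep(TRUE, n_heg))
    )
  }
  cds <- Biostrings::DNAStringSet(unlist(cds_list))
  cds_info <- dplyr::bind_rows(info_list)

  cogs <- cog_catalogue(gcfg)
  lambda <- setNames(rgamma(length(cogs$ids), shape = 2, rate = 1) + 0.5, cogs$ids)
  count_list <- lapply(seq_len(total), function(i) {
    mult <- rep(1, length(cogs$ids))
    names(mult) <- cogs$ids
    planted <- gcfg$enriched_cogs[[cls[i]]]
    mult[names(planted)[names(planted) %in% cogs$ids]] <-
      planted[names(planted) %in% cogs$ids]
    # scale with genome size so bigger genomes carry more genes overall
    rate <- lambda * mult * metadata$genome_size[i] / 5e6
    tibble::tibble(
      accession = acc[i],
      cog = cogs$ids,
      count = rpois(length(cogs$ids), rate)
    )
  })
  cog_counts <- dplyr::bind_rows(count_list)

  list(
    metadata = metadata,
    ssu = ssu,
    cds = cds,
    cds_info = cds_info,
    cog_counts = cog_counts,
    cog2cat = cogs$cog2cat,
    truth = tibble::tibble(accession = acc, class = cls)
  )
}

# internal: synthetic COG catalogue including all hypothesis-map members,
# with a category map where ~15% of COGs carry two categories
cog_catalogue <- function(gcfg) {
  map <- default_hypothesis_map()
  known <- unique(map$member_id[map$member_type == "cog"])
  known_cat <- c(
    COG2113 = "E", COG1595 = "K", COG0380 = "G", COG1653 = "G",
    COG1529 = "C", COG0374 = "C", COG0422 = "H", COG3243 = "I",
    COG1868 = "N"
  )
  extra_needed <- max(0L, gcfg$cog_catalogue_size - length(known))
  filler <- sprintf("COG9%03d", seq_len(extra_needed))
  ids <- c(known, filler)
  cats <- cog_category_letters()
  primary <- c(
    unname(known_cat[known]),
    sample(cats, extra_needed, replace = TRUE)
  )
  primary[is.na(primary)] <- sample(cats, sum(is.na(primary)), replace = TRUE)
  cog2cat <- tibble::tibble(cog = ids, category = primary)
  second <- runif(length(ids)) < 0.15
  if (any(second)) {
    cog2cat <- dplyr::bind_rows(
      cog2cat,
      tibble::tibble(
        cog = ids[second],
        category = vapply(
          primary[second],
          function(cc) sample(setdiff(cats, cc), 1L),
          character(1)
        )
      )
    )
  }
  list(ids = ids, cog2cat = dplyr::arrange(cog2cat, .data$cog, .data$category))
}

#' The 25 single-letter COG functional categories
#' @return Character vector of category letters.
#' @export
cog_category_letters <- function() {
  c(
    "J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z",
    "W", "U", "O", "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S"
  )
}

#' Emit ASV sequences as fragments of catalogue 16S genes
#'
#' Planted ASVs are drawn as `fragment_length`-nt subsequences of a
#' source genome's 16S with a controlled number of substitutions;
#' unplanted ASVs receive unrelated random sequences. Roughly half the
#' planted fragments are emitted on the reverse strand so strand
#' handling is exercised.
#'
#' @param catalogue Output of [simulate_genomes()].
#' @param truth ASV truth tibble from [simulate_counts()].
#' @param fragment_length Fragment length in nt.
#' @param max_mismatches Per-ASV substitution count drawn uniformly
#'   from `0:max_mismatches`.
#' @param seed Integer seed.
#' @return List with `seqs` (`DNAStringSet` named by ASV id) and
#'   `sources` (tibble: `asv_id`, `accession`, `n_mismatches`,
#'   `strand`; NA accession for unplanted ASVs).
#' @export
simulate_asv_sequences <- function(catalogue, truth, fragment_length = 250,
                                   max_mismatches = 2, seed = 1) {
  set.seed(seed)
  classes <- catalogue$truth
  pick_source <- function(cls) {
    pool <- classes$accession[classes$class == cls]
    sample(pool, 1L)
  }
  bases <- c("A", "C", "G", "T")
  out_seq <- character(nrow(truth))
  src <- rep(NA_character_, nrow(truth))
  mm <- rep(NA_integer_, nrow(truth))
  strand <- rep(NA_character_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    t_i <- truth$truth[i]
    if (t_i %in% c("planted_oligotroph", "planted_copiotroph")) {
      cls <- if (t_i == "planted_oligotroph") "oligotroph" else "copiotroph"
      accession <- pick_source(cls)
      full <- as.character(catalogue$ssu[[accession]])
      start <- sample(seq_len(nchar(full) - fragment_length + 1L), 1L)
      frag <- strsplit(substr(full, start, start + fragment_length - 1L), "")[[1L]]
      k <- sample(0:max_mismatches, 1L)
      if (k > 0) {
        pos <- sample(seq_along(frag), k)
        frag[pos] <- vapply(frag[pos], function(b) sample(setdiff(bases, b), 1L), character(1))
      }
      s <- sample(c("+", "-"), 1L)
      seq <- paste(frag, collapse = "")
      if (s == "-") {
        seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      }
      out_seq[i] <- seq
      src[i] <- accession
      mm[i] <- k
      strand[i] <- s
    } else {
      out_seq[i] <- paste(sample(bases, fragment_length, replace = TRUE), collapse = "")
    }
  }
  seqs <- Biostrings::DNAStringSet(setNames(out_seq, truth$asv_id))
  list(
    seqs = seqs,
    sources = tibble::tibble(
      asv_id = truth$asv_id, accession = src,
      n_mismatches = mm, strand = strand
    )
  )
}
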