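#' Configuration for a two-group compositional count simulation
#'
#' Defines one synthetic carbon-contrast amplicon dataset: a shared
#' community profile, Dirichlet-multinomial counts per sample,
#' negative-binomial library sizes, planted differential ASVs, and
#' nuisance ASVs (organelle / unassigned taxonomy) that exercise the
#' filtering rules.
#'
#' @param n_samples_per_group Samples in each of the carbon-limited and
#'   carbon-rich groups.
#' @param n_asvs Total ASVs, including planted and nuisance ASVs.
#' @param depth_mean,depth_dispersion Mean and size parameter of the
#'   negative-binomial library-size model.
#' @param base_concentration Total Dirichlet concentration of the
#'   community; larger values mean less sample-to-sample overdispersion.
#' @param n_planted Number of truly differential ASVs; planted ASVs are
#'   split evenly between the two enrichment directions.
#' @param effect_logfc Log fold change applied multiplicatively to a
#'   planted ASV's Dirichlet weight in its enriched group.
#' @param frac_organelle,frac_unassigned Fractions of ASVs carrying
#'   organelle/eukaryote taxonomy labels or lacking a phylum assignment.
#' @param seed Integer seed; identical configurations with identical
#'   seeds reproduce byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples_per_group = 20,
                       n_asvs = 500,
                       depth_mean = 30000,
                       depth_dispersion = 5,
                       base_concentration = 500,
                       n_planted = 0,
                       effect_logfc = 2,
                       frac_organelle = 0.05,
                       frac_unassigned = 0.05,
                       seed = 1) {
  cfg <- list(
    n_samples_per_group = n_samples_per_group, n_asvs = n_asvs,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    base_concentration = base_concentration, n_planted = n_planted,
    effect_logfc = effect_logfc, frac_organelle = frac_organelle,
    frac_unassigned = frac_unassigned, seed = seed
  )
  ints <- c("n_samples_per_group", "n_asvs", "n_planted", "seed")
  for (f in ints) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v != round(v)) {
      stop("`", f, "` must be a single integer", call. = FALSE)
    }
  }
  if (cfg$n_samples_per_group < 1 || cfg$n_asvs < 1 || cfg$n_planted < 0) {
    stop("sample/ASV counts must be positive; n_planted non-negative", call. = FALSE)
  }
  if (cfg$n_planted > cfg$n_asvs) stop("n_planted exceeds n_asvs", call. = FALSE)
  if (cfg$depth_mean <= 0 || cfg$depth_dispersion <= 0 ||
      cfg$base_concentration <= 0) {
    stop("depths and concentrations must be strictly positive", call. = FALSE)
  }
  for (f in c("frac_organelle", "frac_unassigned")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("`", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-group carbon-contrast count dataset
#'
#' Draws a shared lognormal mean community profile, applies the planted
#' multiplicative effects to the Dirichlet weights of one group, then
#' draws per-sample compositions (Dirichlet) and counts (multinomial at
#' a negative-binomial library size). Nuisance ASVs receive organelle /
#' eukaryote taxonomy labels or a missing phylum so the taxonomy
#' filters have work to do.
#'
#' @param cfg A [sim_config()].
#' @param dataset_id Label recorded in the sample metadata.
#' @return List with `experiment` (an [asv_experiment()] carrying
#'   counts, metadata and taxonomy) and `truth` (tibble `asv_id`,
#'   `truth` in planted_oligotroph / planted_copiotroph / null /
#'   nuisance).
#' @export
simulate_counts <- function(cfg, dataset_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_asv <- cfg$n_asvs
  n_per <- cfg$n_samples_per_group
  asv_ids <- sprintf("asv_%04d", seq_len(n_asv))

  # nuisance assignment first (disjoint blocks), then planted among the rest
  n_org <- round(cfg$frac_organelle * n_asv)
  n_unassigned <- round(cfg$frac_unassigned * n_asv)
  truth <- rep("null", n_asv)
  idx_org <- utils::head(seq_len(n_asv), n_org)
  idx_un <- utils::head(setdiff(seq_len(n_asv), idx_org), n_unassigned)
  truth[c(idx_org, idx_un)] <- "nuisance"
  usable <- which(truth == "null")
  if (cfg$n_planted > length(usable)) {
    stop("not enough non-nuisance ASVs to plant effects in", call. = FALSE)
  }
  planted <- sample(usable, cfg$n_planted)
  n_up <- ceiling(cfg$n_planted / 2)
  planted_olig <- planted[seq_len(n_up)]
  planted_copio <- setdiff(planted, planted_olig)
  truth[planted_olig] <- "planted_oligotroph"
  truth[planted_copio] <- "planted_copiotroph"

  base_weight <- stats::rlnorm(n_asv, meanlog = 0, sdlog = 1)
  w_limited <- base_weight
  w_rich <- base_weight
  w_limited[planted_olig] <- w_limited[planted_olig] * exp(cfg$effect_logfc)
  w_rich[planted_copio] <- w_rich[planted_copio] * exp(cfg$effect_logfc)
  alpha_limited <- cfg$base_concentration * w_limited / sum(w_limited)
  alpha_rich <- cfg$base_concentration * w_rich / sum(w_rich)

  n_samples <- 2L * n_per
  groups <- rep(c("carbon_limited", "carbon_rich"), each = n_per)
  depths <- rnbinom(n_samples, size = cfg$depth_dispersion, mu = cfg$depth_mean)
  counts <- matrix(0, nrow = n_asv, ncol = n_samples)
  for (j in seq_len(n_samples)) {
    a <- if (groups[j] == "carbon_limited") alpha_limited else alpha_rich
    g <- rgamma(n_asv, shape = a)
    if (sum(g) == 0) g <- rep(1, n_asv)
    counts[, j] <- stats::rmultinom(1L, size = depths[j], prob = g / sum(g))
  }
  rownames(counts) <- asv_ids
  sample_ids <- sprintf("%s_s%03d", dataset_id, seq_len(n_samples))
  colnames(counts) <- sample_ids

  samples <- tibble::tibble(
    sample_id = sample_ids,
    dataset_id = dataset_id,
    group = groups,
    profile_id = sprintf(
      "%s_p%02d", dataset_id, ((seq_len(n_samples) - 1L) %% max(1L, n_per %/% 2L)) + 1L
    )
  )
  taxonomy <- simulate_taxonomy(asv_ids, idx_org, idx_un)
  exp <- asv_experiment(counts, samples, taxonomy)
  list(
    experiment = exp,
    truth = tibble::tibble(asv_id = asv_ids, truth = truth)
  )
}

# internal: plausible six-rank taxonomy with organelle/unassigned nuisance rows
simulate_taxonomy <- function(asv_ids, idx_org, idx_un) {
  n <- length(asv_ids)
  phyla <- c(
    "Acidobacteriota", "Actinobacteriota", "Proteobacteria",
    "Chloroflexi", "Verrucomicrobiota", "Dormibacterota"
  )
  families <- sprintf("family_%02d", seq_len(24))
  phylum <- sample(phyla, n, replace = TRUE)
  family <- sample(families, n, replace = TRUE)
  tax <- tibble::tibble(
    asv_id = asv_ids,
    domain = "Bacteria",
    phylum = phylum,
    class = paste0(phylum, "_c"),
    order = paste0(phylum, "_o"),
    family = family,
    genus = paste0(family, "_g"),
    confidence = round(runif(n, 0.6, 1), 3)
  )
  if (length(idx_org)) {
    # organelle / eukaryote labels at their canonical ranks
    kinds <- sample(c("Chloroplast", "Mitochondria", "Eukaryota"),
      length(idx_org),
      replace = TRUE
    )
    tax$order[idx_org] <- ifelse(kinds == "Chloroplast", "Chloroplast", tax$order[idx_org])
    tax$family[idx_org] <- ifelse(kinds == "Mitochondria", "Mitochondria", tax$family[idx_org])
    tax$domain[idx_org] <- ifelse(kinds == "Eukaryota", "Eukaryota", tax$domain[idx_org])
  }
  if (length(idx_un)) tax$phylum[idx_un] <- NA_character_
  tax
}
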