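#' Configuration for an end-to-end run
#'
#' Bundles one to three dataset specifications (each a filter preset
#' plus a count-simulation configuration) with a genome-catalogue
#' configuration, significance level and run seed. The cross-dataset
#' consistency screen requires exactly three datasets.
#'
#' @param datasets Named list; each element is a list with `preset`
#'   (see [preset_policy()]) and `sim` (a [sim_config()]). Names must
#'   be unique.
#' @param genome_cfg A [genome_sim_config()].
#' @param alpha Family-wise significance level used at every stage.
#' @param seed Run seed; per-stage seeds are derived from it, so the
#'   `seed` fields of the member configurations are overridden.
#' @return A `run_config` list.
#' @export
run_config <- function(datasets, genome_cfg = genome_sim_config(),
                       alpha = 0.05, seed = 1) {
  if (!length(datasets) || length(datasets) > 3L) {
    stop("1-3 datasets per run", call. = FALSE)
  }
  if (is.null(names(datasets)) || anyDuplicated(names(datasets))) {
    stop("datasets must have unique names", call. = FALSE)
  }
  for (d in datasets) {
    stopifnot(inherits(d$sim, "sim_config"))
    preset_policy(d$preset) # validates
  }
  structure(
    list(datasets = datasets, genome_cfg = genome_cfg, alpha = alpha, seed = seed),
    class = "run_config"
  )
}

#' The packaged three-dataset demonstration configuration
#'
#' Three synthetic carbon contrasts mirroring the three study designs
#' the pipeline emulates (a soil-profile survey, a paired
#' bulk/rhizosphere survey, and a glucose-amendment microcosm), at
#' desk-scale sample sizes chosen so every downstream stage is
#' estimable.
#'
#' @param seed Run seed.
#' @return A [run_config()].
#' @export
demo_run_config <- function(seed = 1) {
  run_config(
    datasets = list(
      soil_profile = list(
        preset = "soil_profile",
        sim = sim_config(
          n_samples_per_group = 30, n_asvs = 300, n_planted = 40,
          depth_mean = 30000, effect_logfc = 2
        )
      ),
      rhizosphere = list(
        preset = "rhizosphere",
        sim = sim_config(
          n_samples_per_group = 25, n_asvs = 300, n_planted = 40,
          depth_mean = 20000, effect_logfc = 2
        )
      ),
      microcosm = list(
        preset = "microcosm",
        sim = sim_config(
          n_samples_per_group = 15, n_asvs = 250, n_planted = 40,
          depth_mean = 15000, effect_logfc = 2.5
        )
      )
    ),
    genome_cfg = genome_sim_config(n_genomes_per_class = 20),
    seed = seed
  )
}

#' Run the full inference pipeline on synthetic datasets
#'
#' Stage order: simulate -> filter samples -> filter ASVs -> classify
#' -> match classified ASVs to the genome catalogue -> resolve disjoint
#' genome sets -> trait contrasts -> COG contrasts -> (consistency
#' screen when three datasets are configured). Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param screen Run the cross-dataset COG consistency screen; defaults
#'   to `TRUE` when exactly three datasets are configured. Requesting
#'   it with fewer is an error.
#' @return Object of class `pipeline_run`: list with `catalogue`,
#'   per-dataset results (`datasets`), the genome `traits` table,
#'   `screen` (or `NULL`) and a bookkeeping `manifest` tibble.
#' @export
run_pipeline <- function(config, screen = length(config$datasets) == 3L) {
  stopifnot(inherits(config, "run_config"))
  if (screen && length(config$datasets) != 3L) {
    stop("the consistency screen requires exactly 3 datasets", call. = FALSE)
  }
  gcfg <- config$genome_cfg
  gcfg$seed <- child_seed(config$seed, "genomes")
  catalogue <- simulate_genomes(gcfg)
  traits <- genome_traits(catalogue)
  normalized <- normalize_cogs(catalogue$cog_counts, catalogue$metadata)
  cog_mat <- feature_matrix(normalized, "cog", "per_mbp")
  cat_props <- category_proportions(catalogue$cog_counts, catalogue$cog2cat)
  cat_mat <- feature_matrix(cat_props, "category", "proportion")
  hyp_map <- default_hypothesis_map()
  hyp <- hypothesis_scores(normalized, hyp_map, catalogue$cog2cat)
  hyp_mat <- feature_matrix(hyp, "hypothesis_id", "score")

  datasets <- list()
  manifest_rows <- list()
  for (nm in names(config$datasets)) {
    spec <- config$datasets[[nm]]
    sim_cfg <- spec$sim
    sim_cfg$seed <- child_seed(config$seed, paste0("counts_", nm))
    sim <- simulate_counts(sim_cfg, dataset_id = nm)
    seqs <- simulate_asv_sequences(
      catalogue, sim$truth,
      seed = child_seed(config$seed, paste0("seqs_", nm))
    )
    policy <- preset_policy(spec$preset)
    filtered_s <- filter_samples(sim$experiment, policy$min_sample_reads)
    filtered <- filter_asvs(filtered_s, policy)
    classification <- classify_dataset(filtered, alpha = config$alpha)

    sig <- dplyr::filter(classification, .data$group_label != "ns")
    olig_ids <- sig$asv_id[sig$group_label == "oligotroph_associated"]
    copio_ids <- sig$asv_id[sig$group_label == "copiotroph_associated"]
    olig_matches <- match_asvs(seqs$seqs[olig_ids], catalogue)
    copio_matches <- match_asvs(seqs$seqs[copio_ids], catalogue)
    sets <- resolve_genome_sets(olig_matches, copio_matches)

    ds_acc <- c(sets$oligotroph, sets$copiotroph)
    ds_labels <- rep(c("oligotroph", "copiotroph"),
      c(length(sets$oligotroph), length(sets$copiotroph))
    )
    enough <- length(sets$oligotroph) >= 2 && length(sets$copiotroph) >= 2
    trait_cmp <- cog_out <- cat_out <- hyp_out <- NULL
    if (enough) {
      idx <- match(ds_acc, traits$accession)
      trait_cmp <- compare_traits(traits[idx, ], ds_labels, alpha = config$alpha)
      cog_out <- compare_profiles(cog_mat[ds_acc, , drop = FALSE], ds_labels, config$alpha)
      cat_out <- compare_profiles(cat_mat[ds_acc, , drop = FALSE], ds_labels, config$alpha)
      hyp_out <- compare_profiles(hyp_mat[ds_acc, , drop = FALSE], ds_labels, config$alpha)
    }

    datasets[[nm]] <- list(
      truth = sim$truth,
      asv_sources = seqs$sources,
      filter_report = attr(filtered, "filter_report"),
      dropped_samples = attr(filtered_s, "dropped_samples"),
      experiment = filtered,
      classification = classification,
      family_overlap = family_overlap(classification, sim$experiment$taxonomy),
      matches = list(oligotroph = olig_matches, copiotroph = copio_matches),
      genome_sets = sets,
      trait_comparison = trait_cmp,
      cog_outcomes = cog_out,
      category_outcomes = cat_out,
      hypothesis_outcomes = hyp_out
    )
    manifest_rows[[nm]] <- tibble::tibble(
      dataset = nm,
      n_samples_in = ncol(sim$experiment$counts),
      n_samples_retained = ncol(filtered$counts),
      n_asvs_in = nrow(sim$experiment$counts),
      n_asvs_retained = nrow(filtered$counts),
      n_oligotroph_asvs = length(olig_ids),
      n_copiotroph_asvs = length(copio_ids),
      n_ns_asvs = sum(classification$group_label == "ns"),
      n_oligotroph_genomes = length(sets$oligotroph),
      n_copiotroph_genomes = length(sets$copiotroph),
      n_shared_genomes_removed = length(sets$removed)
    )
  }

  screen_res <- NULL
  if (screen) {
    outs <- purrr::map(datasets, "cog_outcomes")
    if (any(purrr::map_lgl(outs, is.null))) {
      stop("consistency screen needs estimable genome sets in all 3 datasets",
        call. = FALSE
      )
    }
    screen_res <- consistency_screen(outs)
  }

  structure(
    list(
      config = config,
      catalogue = catalogue,
      traits = traits,
      category_proportions = cat_props,
      hypothesis_scores = hyp,
      datasets = datasets,
      screen = screen_res,
      manifest = dplyr::bind_rows(manifest_rows)
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", length(x$datasets), " dataset(s), catalogue of ",
    nrow(x$catalogue$metadata), " genomes\n",
    sep = ""
  )
  print(x$manifest)
  if (!is.null(x$screen)) print(x$screen)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `pipeline_run` object.
#' @param ... Unused.
#' @export
glance.pipeline_run <- function(x, ...) x$manifest
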