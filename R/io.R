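#' Write all inputs of a simulated dataset to plain-text files
#'
#' Emits the standard file set a real analysis would start from:
#' counts TSV (ASVs x samples), sample metadata TSV, taxonomy TSV,
#' ASV FASTA, and the genome-catalogue files (metadata TSV, 16S FASTA,
#' CDS FASTA with `heg=` flags in headers, COG counts TSV,
#' COG-to-category TSV) plus the truth TSVs.
#'
#' @param sim Output of [simulate_counts()].
#' @param seqs Output of [simulate_asv_sequences()] (optional).
#' @param catalogue Output of [simulate_genomes()] (optional).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_simulated_inputs <- function(sim, dir, seqs = NULL, catalogue = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w <- function(x, name) {
    path <- file.path(dir, name)
    readr::write_tsv(x, path, progress = FALSE)
    files <<- c(files, path)
  }
  counts <- tibble::as_tibble(sim$experiment$counts, rownames = "asv_id")
  w(counts, "counts.tsv")
  w(sim$experiment$samples, "samples.tsv")
  w(sim$experiment$taxonomy, "taxonomy.tsv")
  w(sim$truth, "asv_truth.tsv")
  if (!is.null(seqs)) {
    path <- file.path(dir, "asvs.fasta")
    Biostrings::writeXStringSet(seqs$seqs, path)
    files <- c(files, path)
    w(seqs$sources, "asv_sources.tsv")
  }
  if (!is.null(catalogue)) {
    w(catalogue$metadata, "genome_metadata.tsv")
    w(catalogue$cog_counts, "cog_counts.tsv")
    w(catalogue$cog2cat, "cog_categories.tsv")
    w(catalogue$truth, "genome_truth.tsv")
    path <- file.path(dir, "genomes_16S.fasta")
    Biostrings::writeXStringSet(catalogue$ssu, path)
    files <- c(files, path)
    cds <- catalogue$cds
    names(cds) <- paste0(
      catalogue$cds_info$cds_id, " heg=", as.integer(catalogue$cds_info$heg)
    )
    path <- file.path(dir, "genomes_cds.fasta")
    Biostrings::writeXStringSet(cds, path)
    files <- c(files, path)
  }
  invisible(files)
}

#' Read an ASV experiment from counts/metadata/taxonomy TSVs
#'
#' Counterpart of [write_simulated_inputs()] for the amplicon tables.
#'
#' @param counts_tsv Counts TSV: first column `asv_id`, one column per
#'   sample.
#' @param samples_tsv Sample metadata TSV (`sample_id`, `dataset_id`,
#'   `group`, optional `profile_id`).
#' @param taxonomy_tsv Optional taxonomy TSV.
#' @return An [asv_experiment()].
#' @export
read_asv_experiment <- function(counts_tsv, samples_tsv, taxonomy_tsv = NULL) {
  counts <- readr::read_tsv(counts_tsv, show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(samples_tsv, show_col_types = FALSE, progress = FALSE)
  taxonomy <- if (!is.null(taxonomy_tsv)) {
    readr::read_tsv(taxonomy_tsv, show_col_types = FALSE, progress = FALSE)
  }
  asv_experiment(counts, samples, taxonomy)
}

#' Write the result tables of a pipeline run
#'
#' One TSV per result type per dataset (classification, filter report,
#' matches, genome sets, trait tests, COG-family outcomes), plus the
#' run manifest, the trait table and, when present, the consistency
#' screen.
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_pipeline_outputs <- function(run, dir) {
  stopifnot(inherits(run, "pipeline_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w <- function(x, name) {
    path <- file.path(dir, name)
    readr::write_tsv(x, path, progress = FALSE)
    files <<- c(files, path)
  }
  w(run$manifest, "manifest.tsv")
  w(run$traits, "genome_traits.tsv")
  for (nm in names(run$datasets)) {
    d <- run$datasets[[nm]]
    w(d$classification, paste0(nm, "_classification.tsv"))
    w(d$filter_report, paste0(nm, "_filter_report.tsv"))
    w(
      dplyr::bind_rows(
        dplyr::mutate(d$matches$oligotroph, group = "oligotroph"),
        dplyr::mutate(d$matches$copiotroph, group = "copiotroph")
      ),
      paste0(nm, "_matches.tsv")
    )
    sets <- tibble::tibble(
      accession = c(d$genome_sets$oligotroph, d$genome_sets$copiotroph, d$genome_sets$removed),
      group = rep(
        c("oligotroph", "copiotroph", "removed"),
        c(
          length(d$genome_sets$oligotroph), length(d$genome_sets$copiotroph),
          length(d$genome_sets$removed)
        )
      )
    )
    w(sets, paste0(nm, "_genome_sets.tsv"))
    if (!is.null(d$trait_comparison)) {
      w(d$trait_comparison$tests, paste0(nm, "_trait_tests.tsv"))
      w(d$trait_comparison$mag_proportions, paste0(nm, "_mag_proportions.tsv"))
    }
    if (!is.null(d$category_outcomes)) {
      w(d$category_outcomes, paste0(nm, "_category_outcomes.tsv"))
    }
    if (!is.null(d$hypothesis_outcomes)) {
      w(d$hypothesis_outcomes, paste0(nm, "_hypothesis_outcomes.tsv"))
    }
    if (!is.null(d$cog_outcomes)) {
      w(d$cog_outcomes, paste0(nm, "_cog_outcomes.tsv"))
    }
  }
  if (!is.null(run$screen)) {
    w(run$screen$results, "screen_results.tsv")
    w(run$screen$summary, "screen_summary.tsv")
  }
  invisible(files)
}
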