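#' Filtering policy for one dataset
#'
#' Collects the per-dataset thresholds applied before differential
#' abundance testing. Removal rules follow the conventions of the
#' source studies: samples are *retained* iff their total reads are
#' strictly greater than `min_sample_reads`; ASVs are *removed* iff
#' their total reads are strictly below `min_asv_reads`, or they occur
#' in strictly fewer than `min_prevalence` units.
#'
#' @param min_sample_reads Sample retained iff total reads > this.
#' @param min_asv_reads ASV removed iff total reads across retained
#'   samples < this.
#' @param min_prevalence ASV removed iff present (count > 0) in fewer
#'   than this many prevalence units.
#' @param prevalence_unit `"sample"` or `"profile"`; profiles group
#'   samples via the `profile_id` metadata column.
#' @param taxonomy_exclusions Taxonomy labels that disqualify an ASV at
#'   any rank (organelle and non-bacterial signal).
#' @param require_phylum Drop ASVs unassigned at the phylum level.
#' @param min_classifier_confidence Taxonomy assignments with classifier
#'   confidence below this are treated as unassigned.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_sample_reads = 0,
                          min_asv_reads = 50,
                          min_prevalence = 0,
                          prevalence_unit = c("sample", "profile"),
                          taxonomy_exclusions = c("Chloroplast", "Mitochondria", "Eukaryota"),
                          require_phylum = TRUE,
                          min_classifier_confidence = 0.5) {
  prevalence_unit <- match.arg(prevalence_unit)
  stopifnot(
    min_sample_reads >= 0, min_asv_reads >= 0, min_prevalence >= 0,
    min_classifier_confidence >= 0, min_classifier_confidence <= 1
  )
  structure(
    list(
      min_sample_reads = min_sample_reads,
      min_asv_reads = min_asv_reads,
      min_prevalence = min_prevalence,
      prevalence_unit = prevalence_unit,
      taxonomy_exclusions = taxonomy_exclusions,
      require_phylum = require_phylum,
      min_classifier_confidence = min_classifier_confidence
    ),
    class = "filter_policy"
  )
}

#' Shipped per-dataset filter presets
#'
#' Three presets mirror the three study designs the pipeline emulates:
#' a depth-resolved soil-profile survey (prevalence counted over
#' profiles), a paired bulk/rhizosphere survey, and a small glucose
#' -amendment microcosm experiment.
#'
#' @param name One of `"soil_profile"`, `"rhizosphere"`, `"microcosm"`.
#' @return A [filter_policy()].
#' @export
preset_policy <- function(name = c("soil_profile", "rhizosphere", "microcosm")) {
  name <- match.arg(name)
  switch(name,
    soil_profile = filter_policy(
      min_sample_reads = 10000, min_asv_reads = 50,
      min_prevalence = 5, prevalence_unit = "profile"
    ),
    rhizosphere = filter_policy(
      min_sample_reads = 1000, min_asv_reads = 50,
      min_prevalence = 5, prevalence_unit = "sample"
    ),
    microcosm = filter_policy(
      min_sample_reads = 0, min_asv_reads = 50,
      min_prevalence = 3, prevalence_unit = "sample"
    )
  )
}

#' Drop low-depth samples
#'
#' Samples are retained iff their total read count is strictly greater
#' than `min_sample_reads`; survivor order is preserved.
#'
#' @param x An [asv_experiment()].
#' @param min_sample_reads Retention threshold (strict `>`).
#' @return A filtered `asv_experiment` with an attribute
#'   `"dropped_samples"` listing removed sample ids.
#' @export
filter_samples <- function(x, min_sample_reads) {
  stopifnot(inherits(x, "asv_experiment"), min_sample_reads >= 0)
  totals <- colSums(x$counts)
  keep <- totals > min_sample_reads
  if (!any(keep)) {
    stop(
      "no sample has more than ", min_sample_reads,
      " reads; all samples would be dropped", call. = FALSE
    )
  }
  out <- subset_experiment(x, samples = colnames(x$counts)[keep])
  attr(out, "dropped_samples") <- colnames(x$counts)[!keep]
  out
}

# internal: mask taxonomy assignments below the confidence floor
effective_taxonomy <- function(taxonomy, policy) {
  ranks <- intersect(
    c("domain", "phylum", "class", "order", "family", "genus"),
    names(taxonomy)
  )
  if ("confidence" %in% names(taxonomy)) {
    low <- !is.na(taxonomy$confidence) &
      taxonomy$confidence < policy$min_classifier_confidence
    taxonomy[low, ranks] <- NA_character_
  }
  taxonomy
}

#' Apply the ASV-level filters in fixed order
#'
#' Removal order: (1) taxonomy exclusions (organelle / non-bacterial
#' labels at any rank), (2) ASVs unassigned at the phylum level,
#' (3) ASVs with total reads below `min_asv_reads`, (4) ASVs present in
#' fewer than `min_prevalence` prevalence units. Classifier assignments
#' below the confidence floor count as unassigned.
#'
#' @param x An [asv_experiment()] whose `taxonomy` covers every ASV
#'   (or a `taxonomy` argument).
#' @param policy A [filter_policy()].
#' @param taxonomy Optional taxonomy table overriding `x$taxonomy`.
#' @return Filtered `asv_experiment`; attribute `"filter_report"` is a
#'   tibble of per-step removal counts.
#' @export
filter_asvs <- function(x, policy, taxonomy = NULL) {
  stopifnot(inherits(x, "asv_experiment"), inherits(policy, "filter_policy"))
  taxonomy <- taxonomy %||% x$taxonomy
  if (is.null(taxonomy)) stop("no taxonomy available", call. = FALSE)
  taxonomy <- tibble::as_tibble(taxonomy)
  missing_tax <- setdiff(rownames(x$counts), taxonomy$asv_id)
  if (length(missing_tax)) {
    stop(
      "taxonomy row missing for ", length(missing_tax), " ASV(s), e.g. ",
      missing_tax[1L], call. = FALSE
    )
  }
  tax <- effective_taxonomy(taxonomy, policy)
  tax <- tax[match(rownames(x$counts), tax$asv_id), ]
  ranks <- intersect(
    c("domain", "phylum", "class", "order", "family", "genus"),
    names(tax)
  )
  keep <- rep(TRUE, nrow(x$counts))
  report <- list()

  rank_mat <- as.matrix(tax[, ranks, drop = FALSE])
  excluded <- rowSums(
    matrix(rank_mat %in% policy$taxonomy_exclusions, nrow = nrow(rank_mat))
  ) > 0
  report$taxonomy_exclusion <- sum(excluded & keep)
  keep <- keep & !excluded

  if (policy$require_phylum) {
    no_phylum <- if ("phylum" %in% names(tax)) {
      is.na(tax$phylum) | tax$phylum == ""
    } else {
      rep(TRUE, nrow(tax))
    }
    report$unassigned_phylum <- sum(no_phylum & keep)
    keep <- keep & !no_phylum
  } else {
    report$unassigned_phylum <- 0L
  }

  low_reads <- rowSums(x$counts) < policy$min_asv_reads
  report$low_total_reads <- sum(low_reads & keep)
  keep <- keep & !low_reads

  prevalence <- asv_prevalence(x, policy$prevalence_unit)
  low_prev <- prevalence < policy$min_prevalence
  report$low_prevalence <- sum(low_prev & keep)
  keep <- keep & !low_prev

  out <- subset_experiment(x, asvs = rownames(x$counts)[keep])
  attr(out, "filter_report") <- tibble::tibble(
    step = c(
      "taxonomy_exclusion", "unassigned_phylum",
      "low_total_reads", "low_prevalence", "retained"
    ),
    n_asvs = unname(c(unlist(report), sum(keep)))
  )
  out
}

# internal: number of units (samples or profiles) in which each ASV occurs
asv_prevalence <- function(x, unit) {
  present <- x$counts > 0
  if (unit == "sample") {
    return(rowSums(present))
  }
  if (!"profile_id" %in% names(x$samples)) {
    stop("prevalence_unit = \"profile\" needs a `profile_id` metadata column",
      call. = FALSE
    )
  }
  profiles <- x$samples$profile_id[match(colnames(x$counts), x$samples$sample_id)]
  agg <- vapply(
    split(seq_len(ncol(present)), profiles),
    function(idx) rowSums(present[, idx, drop = FALSE]) > 0,
    logical(nrow(present))
  )
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1L)
  rowSums(agg)
}

#' Relative abundances after filtering
#'
#' Each ASV count is divided by its sample's post-filtering total, so
#' every column of the result sums to one.
#'
#' @param x A filtered [asv_experiment()]; every sample total must be
#'   positive.
#' @return ASV x sample matrix of fractions.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "asv_experiment"))
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop(
      "zero-total sample(s) present (", paste(
        utils::head(colnames(x$counts)[totals == 0], 3L),
        collapse = ", "
      ),
      "); filter samples first", call. = FALSE
    )
  }
  sweep(x$counts, 2L, totals, `/`)
}
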