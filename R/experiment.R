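#' Bundle an ASV count matrix with its sample metadata and taxonomy
#'
#' `asv_experiment()` is the unit every amplicon stage transforms: an
#' ASV x sample matrix of non-negative integer read counts, a sample
#' metadata table assigning every sample to a carbon-contrast group, and
#' (optionally) a per-ASV taxonomy table with classifier confidence.
#'
#' @param counts ASV x sample matrix of non-negative integers with row
#'   and column names, or a data frame whose first column is `asv_id`
#'   and remaining columns are samples.
#' @param samples Data frame with columns `sample_id`, `dataset_id`,
#'   `group` (one of `"carbon_limited"`, `"carbon_rich"`) and optionally
#'   `profile_id` (the unit over which prevalence may be counted).
#' @param taxonomy Optional data frame with columns `asv_id`, the ranks
#'   `domain` ... `genus`, and `confidence` in \[0, 1\].
#'
#' @return An object of class `asv_experiment`.
#' @export
asv_experiment <- function(counts, samples, taxonomy = NULL) {
  if (is.data.frame(counts)) {
    asv_ids <- as.character(counts[[1L]])
    counts <- as.matrix(counts[, -1L, drop = FALSE])
    rownames(counts) <- asv_ids
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry ASV row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("ASV ids must be unique", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "dataset_id", "group")
  if (!all(req %in% names(samples))) {
    stop("`samples` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!setequal(samples$sample_id, colnames(counts)) ||
      nrow(samples) != ncol(counts)) {
    stop("`samples` must describe exactly the count columns", call. = FALSE)
  }
  bad <- setdiff(unique(samples$group), c("carbon_limited", "carbon_rich"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (!is.null(taxonomy)) {
    taxonomy <- tibble::as_tibble(taxonomy)
    if (!"asv_id" %in% names(taxonomy)) {
      stop("`taxonomy` needs an `asv_id` column", call. = FALSE)
    }
  }
  structure(
    list(counts = counts, samples = samples, taxonomy = taxonomy),
    class = "asv_experiment"
  )
}

#' @export
print.asv_experiment <- function(x, ...) {
  cat(
    "<asv_experiment> ", nrow(x$counts), " ASVs x ", ncol(x$counts),
    " samples (", sum(x$samples$group == "carbon_limited"), " carbon_limited, ",
    sum(x$samples$group == "carbon_rich"), " carbon_rich)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.asv_experiment <- function(x) dim(x$counts)

#' Per-sample read totals
#'
#' @param x An [asv_experiment()].
#' @return Tibble with `sample_id`, `dataset_id`, `group`, `total_reads`.
#' @export
sample_totals <- function(x) {
  stopifnot(inherits(x, "asv_experiment"))
  dplyr::mutate(x$samples, total_reads = unname(colSums(x$counts)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-format view of an ASV experiment
#'
#' @param x An [asv_experiment()].
#' @param ... Unused.
#' @return Tibble with one row per (ASV, sample) pair.
#' @export
tidy.asv_experiment <- function(x, ...) {
  long <- tibble::as_tibble(x$counts, rownames = "asv_id") |>
    tidyr::pivot_longer(-"asv_id", names_to = "sample_id", values_to = "count")
  dplyr::left_join(long, x$samples, by = "sample_id")
}

# internal: subset keeping metadata in step
subset_experiment <- function(x, asvs = NULL, samples = NULL) {
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  if (!is.null(asvs)) counts <- counts[asvs, , drop = FALSE]
  meta <- x$samples[x$samples$sample_id %in% colnames(counts), ]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[tax$asv_id %in% rownames(counts), ]
  asv_experiment(counts, meta, tax)
}
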