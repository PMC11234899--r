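#' Cross-dataset consistency screen over individual COGs
#'
#' A COG is `oligotroph_consistent` (resp. `copiotroph_consistent`)
#' when it is Bonferroni-significant with that same enrichment
#' direction in every dataset; everything else is
#' `inconsistent_or_ns`. The three summary counts partition the shared
#' COG universe.
#'
#' @param outcomes Named list of per-dataset outcome tibbles from
#'   [compare_profiles()] run on the full COG feature family; the
#'   tibbles must share one COG universe.
#' @return Object of class `consistency_screen`: list with `results`
#'   (tibble: `cog`, per-dataset direction columns, `consistent_label`)
#'   and `summary` (tibble of the three partition counts).
#' @export
consistency_screen <- function(outcomes) {
  if (length(outcomes) < 2L) {
    stop("the consistency screen needs outcomes from several datasets", call. = FALSE)
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- paste0("dataset", seq_along(outcomes))
  }
  universes <- lapply(outcomes, function(x) sort(unique(x$feature)))
  if (!all(vapply(universes[-1L], identical, logical(1), universes[[1L]]))) {
    stop("datasets do not share one COG universe", call. = FALSE)
  }
  per_ds <- purrr::imap(outcomes, function(x, nm) {
    tibble::tibble(
      cog = x$feature,
      "{nm}_direction" := x$direction,
      "{nm}_p_adj" := x$p_adj
    )
  })
  results <- purrr::reduce(per_ds, dplyr::inner_join, by = "cog")
  dirs <- as.matrix(
    results[, grep("_direction$", names(results)), drop = FALSE]
  )
  all_olig <- rowSums(dirs == "oligotroph_enriched") == ncol(dirs)
  all_copio <- rowSums(dirs == "copiotroph_enriched") == ncol(dirs)
  results$consistent_label <- dplyr::case_when(
    all_olig ~ "oligotroph_consistent",
    all_copio ~ "copiotroph_consistent",
    .default = "inconsistent_or_ns"
  )
  summary <- tibble::tibble(
    label = c("oligotroph_consistent", "copiotroph_consistent", "inconsistent_or_ns"),
    n_cogs = c(sum(all_olig), sum(all_copio), sum(!all_olig & !all_copio))
  )
  structure(
    list(results = results, summary = summary, n_universe = nrow(results)),
    class = "consistency_screen"
  )
}

#' @export
print.consistency_screen <- function(x, ...) {
  cat("<consistency_screen> universe of", x$n_universe, "COGs\n")
  print(x$summary)
  invisible(x)
}

#' @rdname consistency_screen
#' @param x A `consistency_screen` object.
#' @param ... Unused.
#' @export
tidy.consistency_screen <- function(x, ...) x$results

#' @rdname consistency_screen
#' @export
glance.consistency_screen <- function(x, ...) {
  tibble::tibble(
    n_universe = x$n_universe,
    n_oligotroph_consistent = x$summary$n_cogs[1L],
    n_copiotroph_consistent = x$summary$n_cogs[2L],
    n_remaining = x$summary$n_cogs[3L]
  )
}
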