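#' Contrast genomic traits between life-history classes
#'
#' Mann-Whitney tests on genome size, GC, SSU (rRNA operon) count and
#' the codon-usage growth proxy, Bonferroni-corrected over the trait
#' family, plus the MAG proportion per class. The effect is
#' `mean(copiotroph) - mean(oligotroph)` on each trait.
#'
#' @param traits Tibble from [genome_traits()].
#' @param labels Character vector aligned with `traits` rows:
#'   `"oligotroph"` / `"copiotroph"`; alternatively a tibble with
#'   `accession` and `class` columns.
#' @param alpha Family-wise significance level.
#' @return Object of class `trait_comparison`: list with `tests`
#'   (tibble per trait: `trait`, `u_statistic`, `p_raw`, `p_adj`,
#'   `effect`, `direction`), `mag_proportions` (tibble: `class`,
#'   `n_genomes`, `prop_mag`) and `n` per class.
#' @export
compare_traits <- function(traits, labels, alpha = 0.05) {
  if (is.data.frame(labels)) {
    labels <- labels$class[match(traits$accession, labels$accession)]
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(traits))
  trait_cols <- c("genome_size", "gc", "ssu_count", "delta_enc")
  mat <- as.matrix(traits[, trait_cols])
  rownames(mat) <- traits$accession
  tests <- compare_profiles(mat, labels, alpha = alpha)
  tests <- dplyr::rename(tests, trait = "feature")

  mag <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(class = labels, category = traits$genome_category),
      .data$class
    ),
    n_genomes = dplyr::n(),
    prop_mag = mean(.data$category == "MAG"),
    .groups = "drop"
  )
  structure(
    list(
      tests = tests,
      mag_proportions = mag,
      n_oligotroph = sum(labels == "oligotroph"),
      n_copiotroph = sum(labels == "copiotroph"),
      alpha = alpha
    ),
    class = "trait_comparison"
  )
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat(
    "<trait_comparison> ", x$n_oligotroph, " oligotroph vs ",
    x$n_copiotroph, " copiotroph genomes\n",
    sep = ""
  )
  print(x$tests)
  invisible(x)
}

#' @rdname compare_traits
#' @param x A `trait_comparison` object.
#' @param ... Unused.
#' @export
tidy.trait_comparison <- function(x, ...) x$tests

#' @rdname compare_traits
#' @export
glance.trait_comparison <- function(x, ...) {
  tibble::tibble(
    n_oligotroph = x$n_oligotroph,
    n_copiotroph = x$n_copiotroph,
    n_significant = sum(x$tests$direction != "ns"),
    prop_mag_oligotroph = x$mag_proportions$prop_mag[
      match("oligotroph", x$mag_proportions$class)
    ],
    prop_mag_copiotroph = x$mag_proportions$prop_mag[
      match("copiotroph", x$mag_proportions$class)
    ]
  )
}
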