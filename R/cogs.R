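#' Normalize COG counts by genome size
#'
#' Scales each genome's COG counts to copies per million base pairs:
#' `count * 1e6 / genome_size`.
#'
#' @param cog_counts Long tibble (`accession`, `cog`, `count`) or a
#'   named count vector for a single genome.
#' @param genome_size Genome size(s) in bp: a named vector (by
#'   accession) or a metadata tibble with `accession` and
#'   `genome_size`; for a single-genome count vector, one number.
#' @return Same shape as the input with a `per_mbp` column (tibble
#'   input) or a named numeric vector (vector input).
#' @export
normalize_cogs <- function(cog_counts, genome_size) {
  if (!is.data.frame(cog_counts)) {
    if (length(genome_size) != 1L || genome_size <= 0) {
      stop("`genome_size` must be a single positive number", call. = FALSE)
    }
    return(cog_counts * 1e6 / genome_size)
  }
  if (is.data.frame(genome_size)) {
    genome_size <- setNames(genome_size$genome_size, genome_size$accession)
  }
  sizes <- genome_size[cog_counts$accession]
  if (anyNA(sizes)) stop("genome size missing for some accessions", call. = FALSE)
  if (any(sizes <= 0)) stop("genome sizes must be positive", call. = FALSE)
  dplyr::mutate(cog_counts, per_mbp = .data$count * 1e6 / unname(sizes))
}

#' COG functional-category proportions per genome
#'
#' For each genome, the proportion of a category is the number of
#' COG-assigned genes in that category divided by the total COG-assigned
#' gene count. A COG assigned to multiple categories is counted in each,
#' so proportions may sum to more than one.
#'
#' @param cog_counts Long tibble (`accession`, `cog`, `count`).
#' @param cog2cat Tibble (`cog`, `category`), one row per assignment.
#' @return Tibble (`accession`, `category`, `proportion`) covering all
#'   25 categories for every genome (absent categories get 0).
#' @export
category_proportions <- function(cog_counts, cog2cat) {
  totals <- dplyr::summarise(
    dplyr::group_by(cog_counts, .data$accession),
    total = sum(.data$count), .groups = "drop"
  )
  if (any(totals$total == 0)) {
    stop("empty COG profile for accession(s): ", paste(
      utils::head(totals$accession[totals$total == 0], 3L),
      collapse = ", "
    ), call. = FALSE)
  }
  unmapped <- setdiff(unique(cog_counts$cog[cog_counts$count > 0]), cog2cat$cog)
  if (length(unmapped)) {
    stop("COG(s) without a category assignment, e.g. ", unmapped[1L], call. = FALSE)
  }
  per_cat <- dplyr::summarise(
    dplyr::group_by(
      dplyr::inner_join(cog_counts, cog2cat, by = "cog",
        relationship = "many-to-many"
      ),
      .data$accession, .data$category
    ),
    n_genes = sum(.data$count), .groups = "drop"
  )
  grid <- tidyr::expand_grid(
    accession = totals$accession,
    category = cog_category_letters()
  )
  out <- dplyr::left_join(grid, per_cat, by = c("accession", "category"))
  out <- dplyr::left_join(out, totals, by = "accession")
  dplyr::transmute(
    out, .data$accession, .data$category,
    proportion = dplyr::coalesce(.data$n_genes, 0) / .data$total
  )
}

#' The shipped hypothesis battery
#'
#' Reads the editable hypothesis map distributed with the package:
#' functional-category rows (COG letters) and individual-gene rows with
#' placeholder COG id lists, each with the direction in which
#' oligotroph genomes are expected to differ.
#'
#' @param path Optional path to a custom map TSV with columns
#'   `hypothesis_id`, `label`, `member_type` (`cog`/`category`),
#'   `member_id`, `expected_direction`.
#' @return Tibble, one row per (hypothesis, member).
#' @export
default_hypothesis_map <- function(path = NULL) {
  path <- path %||% system.file(
    "extdata", "hypothesis_map.tsv",
    package = "oligotraits", mustWork = TRUE
  )
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("hypothesis_id", "label", "member_type", "member_id", "expected_direction")
  if (!all(req %in% names(map))) {
    stop("hypothesis map needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(map$member_type), c("cog", "category"))
  if (length(bad)) stop("unknown member_type: ", paste(bad, collapse = ", "), call. = FALSE)
  map
}

#' Per-genome hypothesis scores
#'
#' Each hypothesis score is the sum of the genome-size-normalized
#' abundances of the hypothesis' member COGs; category members expand
#' to every COG assigned to that category.
#'
#' @param normalized Long tibble (`accession`, `cog`, `per_mbp`) from
#'   [normalize_cogs()].
#' @param map Hypothesis map (see [default_hypothesis_map()]).
#' @param cog2cat Tibble (`cog`, `category`) used to expand category
#'   members.
#' @return Tibble (`accession`, `hypothesis_id`, `score`).
#' @export
hypothesis_scores <- function(normalized, map, cog2cat) {
  members <- dplyr::bind_rows(
    dplyr::select(
      dplyr::filter(map, .data$member_type == "cog"),
      "hypothesis_id",
      cog = "member_id"
    ),
    dplyr::select(
      dplyr::inner_join(
        dplyr::filter(map, .data$member_type == "category"),
        cog2cat,
        by = c(member_id = "category"),
        relationship = "many-to-many"
      ),
      "hypothesis_id", "cog"
    )
  )
  members <- dplyr::distinct(members)
  joined <- dplyr::inner_join(
    members, normalized,
    by = "cog", relationship = "many-to-many"
  )
  scored <- dplyr::summarise(
    dplyr::group_by(joined, .data$accession, .data$hypothesis_id),
    score = sum(.data$per_mbp), .groups = "drop"
  )
  grid <- tidyr::expand_grid(
    accession = unique(normalized$accession),
    hypothesis_id = unique(map$hypothesis_id)
  )
  out <- dplyr::left_join(grid, scored, by = c("accession", "hypothesis_id"))
  dplyr::mutate(out, score = dplyr::coalesce(.data$score, 0))
}

#' Contrast per-genome features between the two life-history groups
#'
#' Mann-Whitney test per feature with Bonferroni correction over the
#' features tested in this call (one family per run: the 25 categories,
#' the hypothesis battery, or the full COG screen are three separate
#' families). The effect is `mean(copiotroph) - mean(oligotroph)`, so
#' negative effects mark oligotroph-enriched features.
#'
#' @param features Genome x feature numeric matrix (rownames =
#'   accessions) or a tibble with an `accession` column.
#' @param labels Character vector aligned with rows: `"oligotroph"` /
#'   `"copiotroph"`.
#' @param alpha Family-wise significance level.
#' @param presence_absence Test presence (feature > 0) instead of
#'   abundance.
#' @return Tibble per feature: `feature`, `u_statistic`, `p_raw`,
#'   `p_adj`, `effect`, `direction` (`oligotroph_enriched`,
#'   `copiotroph_enriched`, or `ns`).
#' @export
compare_profiles <- function(features, labels, alpha = 0.05,
                             presence_absence = FALSE) {
  if (is.data.frame(features)) {
    accs <- features$accession
    features <- as.matrix(features[, setdiff(names(features), "accession"), drop = FALSE])
    rownames(features) <- accs
  }
  if (presence_absence) {
    features <- (features > 0) * 1
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  olig <- labels == "oligotroph"
  copio <- labels == "copiotroph"
  if (sum(olig) < 2 || sum(copio) < 2) {
    stop("need at least 2 genomes per class", call. = FALSE)
  }
  m <- ncol(features)
  res <- apply(features, 2L, function(v) {
    mw <- mann_whitney_u(v[olig], v[copio])
    c(mw$u, mw$p, mean(v[copio]) - mean(v[olig]))
  })
  out <- tibble::tibble(
    feature = colnames(features),
    u_statistic = unname(res[1L, ]),
    p_raw = unname(res[2L, ]),
    p_adj = pmin(1, unname(res[2L, ]) * m),
    effect = unname(res[3L, ])
  )
  dplyr::mutate(out, direction = dplyr::case_when(
    .data$p_adj >= alpha ~ "ns",
    .data$effect < 0 ~ "oligotroph_enriched",
    .default = "copiotroph_enriched"
  ))
}

# internal: long (accession, key, value) -> genome x feature matrix
feature_matrix <- function(long, key, value) {
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "accession", dplyr::all_of(c(key, value))),
    names_from = dplyr::all_of(key), values_from = dplyr::all_of(value),
    values_fill = 0
  )
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$accession
  m
}
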