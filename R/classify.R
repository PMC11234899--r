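#' Classify ASVs as oligotroph- or copiotroph-associated
#'
#' Runs a two-sided Mann-Whitney test per ASV on relative abundances
#' between the carbon-limited and carbon-rich sample groups, applies a
#' Bonferroni correction with family size equal to the number of ASVs
#' tested in the dataset, and labels each significant ASV by the group
#' in which its mean relative abundance is higher: higher in
#' carbon-limited soil = `oligotroph_associated`, higher in carbon-rich
#' soil = `copiotroph_associated`, otherwise `ns`.
#'
#' @param relabund ASV x sample matrix of relative abundances (see
#'   [relative_abundance()]).
#' @param groups Character vector (`"carbon_limited"` /
#'   `"carbon_rich"`) aligned with the columns of `relabund`.
#' @param alpha Family-wise significance level in (0, 1).
#' @return Tibble with one row per ASV: `asv_id`, `group_label`,
#'   `u_statistic` (U for the carbon-limited group), `p_raw`, `p_adj`,
#'   `mean_carbon_limited`, `mean_carbon_rich`, `direction`
#'   (sign of carbon-rich minus carbon-limited mean).
#' @export
classify_asvs <- function(relabund, groups, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  relabund <- as.matrix(relabund)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(relabund))
  lim <- groups == "carbon_limited"
  rich <- groups == "carbon_rich"
  if (sum(lim) < 2 || sum(rich) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  m <- nrow(relabund)
  res <- apply(relabund, 1L, function(v) {
    mw <- mann_whitney_u(v[lim], v[rich])
    c(mw$u, mw$p, mean(v[lim]), mean(v[rich]))
  })
  out <- tibble::tibble(
    asv_id = rownames(relabund),
    u_statistic = unname(res[1L, ]),
    p_raw = unname(res[2L, ]),
    p_adj = pmin(1, unname(res[2L, ]) * m),
    mean_carbon_limited = unname(res[3L, ]),
    mean_carbon_rich = unname(res[4L, ])
  )
  out$direction <- sign(out$mean_carbon_rich - out$mean_carbon_limited)
  out$group_label <- dplyr::case_when(
    out$p_adj >= alpha ~ "ns",
    out$mean_carbon_limited > out$mean_carbon_rich ~ "oligotroph_associated",
    .default = "copiotroph_associated"
  )
  dplyr::select(
    out, "asv_id", "group_label", "u_statistic", "p_raw", "p_adj",
    "mean_carbon_limited", "mean_carbon_rich", "direction"
  )
}

#' Classify a filtered experiment in one call
#'
#' Convenience wrapper: computes [relative_abundance()] and passes the
#' sample groups through to [classify_asvs()].
#'
#' @param x A filtered [asv_experiment()].
#' @inheritParams classify_asvs
#' @return See [classify_asvs()].
#' @export
classify_dataset <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "asv_experiment"))
  classify_asvs(relative_abundance(x), x$samples$group, alpha = alpha)
}

#' Families containing both oligotroph- and copiotroph-associated ASVs
#'
#' Among classified (non-`ns`) ASVs with a family-level assignment,
#' counts the distinct families and the subset claimed by both
#' life-history groups.
#'
#' @param classification Output of [classify_asvs()].
#' @param taxonomy Taxonomy table with `asv_id` and `family` columns.
#' @return One-row tibble: `n_families`, `n_shared`, `prop_shared`.
#' @export
family_overlap <- function(classification, taxonomy) {
  sig <- dplyr::filter(classification, .data$group_label != "ns")
  tab <- dplyr::inner_join(
    sig, dplyr::select(tibble::as_tibble(taxonomy), "asv_id", "family"),
    by = "asv_id"
  )
  tab <- dplyr::filter(tab, !is.na(.data$family) & .data$family != "")
  per_family <- dplyr::summarise(
    dplyr::group_by(tab, .data$family),
    n_labels = dplyr::n_distinct(.data$group_label),
    .groups = "drop"
  )
  n_fam <- nrow(per_family)
  n_shared <- sum(per_family$n_labels == 2L)
  tibble::tibble(
    n_families = n_fam,
    n_shared = n_shared,
    prop_shared = if (n_fam > 0) n_shared / n_fam else NA_real_
  )
}
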