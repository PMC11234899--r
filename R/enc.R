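#' @name codon_families
#' @title Synonymous codon families of the standard genetic code
#' @description Internal tables for the 59 codons belonging to
#' degenerate families (Met, Trp and the three stop codons are
#' excluded). Six-fold amino acids (Leu, Ser, Arg) are treated as
#' single families, Wright's original convention.
#' @keywords internal
NULL

# named list: amino acid -> codons (DNA alphabet)
.codon_families <- list(
  Phe = c("TTT", "TTC"),
  Tyr = c("TAT", "TAC"),
  His = c("CAT", "CAC"),
  Gln = c("CAA", "CAG"),
  Asn = c("AAT", "AAC"),
  Lys = c("AAA", "AAG"),
  Asp = c("GAT", "GAC"),
  Glu = c("GAA", "GAG"),
  Cys = c("TGT", "TGC"),
  Ile = c("ATT", "ATC", "ATA"),
  Val = c("GTT", "GTC", "GTA", "GTG"),
  Pro = c("CCT", "CCC", "CCA", "CCG"),
  Thr = c("ACT", "ACC", "ACA", "ACG"),
  Ala = c("GCT", "GCC", "GCA", "GCG"),
  Gly = c("GGT", "GGC", "GGA", "GGG"),
  Leu = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  Ser = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  Arg = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")
)

.family_degeneracy <- vapply(.codon_families, length, integer(1))

#' Count codons in a set of coding sequences
#'
#' Codons are read in frame from position 1 of each sequence; sequences
#' are expected to be complete CDS (length a multiple of 3).
#'
#' @param seqs A `Biostrings::DNAStringSet` or character vector of CDS.
#' @return Named integer vector over the 64 codons (pooled).
#' @export
codon_counts <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (!length(seqs)) stop("no sequences supplied", call. = FALSE)
  freq <- Biostrings::trinucleotideFrequency(seqs, step = 3)
  colSums(freq)
}

#' Effective number of codons (Nc)
#'
#' Wright's Nc from pooled codon counts. Per amino-acid family the
#' codon homozygosity is `F = (n * sum(p_i^2) - 1) / (n - 1)` with `n`
#' the family total and `p_i` the within-family codon fractions.
#' Degeneracy-class means average families with `n >= 2` (non-positive
#' `F` values are excluded as undefined); a class with no usable family
#' falls back to its neutral value `1/k`. Then
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped to \[20, 61\].
#'
#' @param counts Named codon count vector (64 or 59 codons; names in
#'   DNA alphabet). Extra codons (Met, Trp, stops) are ignored.
#' @return Nc, a single number in \[20, 61\].
#' @export
enc <- function(counts) {
  if (is.null(names(counts))) stop("`counts` must be a named codon vector", call. = FALSE)
  if (any(counts < 0)) stop("codon counts must be non-negative", call. = FALSE)
  fam_F <- vapply(.codon_families, function(codons) {
    n_i <- counts[codons]
    n_i[is.na(n_i)] <- 0
    n <- sum(n_i)
    if (n < 2) return(NA_real_)
    p <- n_i / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  if (all(is.na(fam_F))) stop("all codon families empty", call. = FALSE)
  class_mean <- vapply(c(`2` = 2L, `3` = 3L, `4` = 4L, `6` = 6L), function(k) {
    f <- fam_F[.family_degeneracy == k]
    f <- f[!is.na(f) & f > 0]
    if (!length(f)) 1 / k else mean(f)
  }, numeric(1))
  nc <- 2 + 9 / class_mean[["2"]] + 1 / class_mean[["3"]] +
    5 / class_mean[["4"]] + 3 / class_mean[["6"]]
  min(max(nc, 20), 61)
}

#' Codon-usage-bias growth proxy from highly expressed genes
#'
#' Pools codons separately for the highly expressed gene (HEG) set and
#' the background (all remaining CDS), computes Nc for each, and
#' returns the relative ENC reduction
#' `delta_enc = (enc_background - enc_heg) / enc_background`. Stronger
#' codon-usage bias in HEGs (larger `delta_enc`) proxies a shorter
#' minimum doubling time.
#'
#' @param cds A `DNAStringSet` (or character vector) of all CDS.
#' @param heg Logical vector (or index/name vector) flagging the HEG
#'   subset; must be non-empty and leave a non-empty background.
#' @return List with `enc_background`, `enc_heg`, `delta_enc`.
#' @export
delta_enc <- function(cds, heg) {
  if (!methods::is(cds, "DNAStringSet")) cds <- Biostrings::DNAStringSet(cds)
  if (is.logical(heg)) {
    stopifnot(length(heg) == length(cds))
    heg_idx <- which(heg)
  } else {
    heg_idx <- if (is.character(heg)) match(heg, names(cds)) else as.integer(heg)
  }
  if (!length(heg_idx) || anyNA(heg_idx)) {
    stop("HEG set empty or not resolvable against the CDS set", call. = FALSE)
  }
  bg_idx <- setdiff(seq_along(cds), heg_idx)
  if (!length(bg_idx)) stop("background CDS set is empty", call. = FALSE)
  enc_bg <- enc(codon_counts(cds[bg_idx]))
  enc_heg <- enc(codon_counts(cds[heg_idx]))
  list(
    enc_background = enc_bg,
    enc_heg = enc_heg,
    delta_enc = (enc_bg - enc_heg) / enc_bg
  )
}

#' Per-genome trait vectors from a genome catalogue
#'
#' Combines the catalogue metadata (genome size, GC, rRNA count,
#' MAG/isolate origin) with the codon-usage growth proxy computed from
#' each genome's CDS and HEG annotation.
#'
#' @param catalogue A genome catalogue as returned by
#'   [simulate_genomes()] (list with `metadata`, `cds`, `cds_info`).
#' @param heg_ids Optional character vector of CDS ids to use as the
#'   HEG set, overriding the `heg` flags in `cds_info`.
#' @return Tibble: one row per genome with `accession`,
#'   `genome_category`, `genome_size`, `gc`, `ssu_count`,
#'   `enc_background`, `enc_heg`, `delta_enc`.
#' @export
genome_traits <- function(catalogue, heg_ids = NULL) {
  meta <- catalogue$metadata
  info <- catalogue$cds_info
  if (!is.null(heg_ids)) {
    info$heg <- info$cds_id %in% heg_ids
  }
  per_genome <- purrr::map_dfr(meta$accession, function(acc) {
    rows <- info$accession == acc
    cds <- catalogue$cds[info$cds_id[rows]]
    d <- delta_enc(cds, info$heg[rows])
    tibble::tibble(
      accession = acc,
      enc_background = d$enc_background,
      enc_heg = d$enc_heg,
      delta_enc = d$delta_enc
    )
  })
  out <- dplyr::left_join(
    dplyr::select(
      meta, "accession", "genome_category", "genome_size",
      gc = "gc_percentage", ssu_count = "ssu_count"
    ),
    per_genome,
    by = "accession"
  )
  # metadata carries GC as a percentage (reference-database convention)
  dplyr::mutate(out, gc = .data$gc / 100)
}
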