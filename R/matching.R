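#' Strand-aware global sequence identity
#'
#' Aligns the query against the reference and against its reverse
#' complement, global in the shorter sequence with terminal gaps on the
#' longer sequence free (the identity definition used by reference-based
#' amplicon matching: matching columns over alignment length, internal
#' gaps counted). `N` never counts as a match. The better strand is
#' reported.
#'
#' @param query,reference DNA sequences (character or
#'   `Biostrings::DNAString`) over `A C G T N`.
#' @return List with `identity` (fraction in \[0, 1\]) and `strand`
#'   (`"+"` or `"-"`).
#' @export
sequence_identity <- function(query, reference) {
  q <- toupper(as.character(query))
  r <- toupper(as.character(reference))
  if (!nzchar(q) || !nzchar(r)) stop("sequences must be non-empty", call. = FALSE)
  if (grepl("[^ACGTN]", q) || grepl("[^ACGTN]", r)) {
    stop("sequences must use the alphabet A, C, G, T, N", call. = FALSE)
  }
  fwd <- aligned_identities(q, r)
  rev <- aligned_identities(revcomp(q), r)
  if (rev > fwd) list(identity = rev, strand = "-") else list(identity = fwd, strand = "+")
}

# internal: reverse complement of a character DNA sequence
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.identity_submat <- NULL

# internal: substitution matrix cached across calls
identity_submat <- function() {
  if (is.null(.identity_submat)) {
    utils::assignInMyNamespace(
      ".identity_submat",
      Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE
      )
    )
  }
  .identity_submat
}

# internal: identities of one or more queries vs one reference, one
# orientation; queries must not be longer than the reference (the
# amplicon-vs-gene case), so terminal gaps on the reference are free
aligned_identities <- function(queries, reference) {
  queries <- Biostrings::DNAStringSet(queries)
  too_long <- Biostrings::width(queries) > nchar(reference)
  if (any(too_long)) {
    # fall back to pairwise swaps for the rare longer-than-reference query
    return(vapply(as.character(queries), function(q) {
      if (nchar(q) > nchar(reference)) {
        aligned_identities(as.character(reference), q)
      } else {
        aligned_identities(q, reference)
      }
    }, numeric(1), USE.NAMES = FALSE))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = queries, subject = Biostrings::DNAString(reference),
    type = "global-local", substitutionMatrix = identity_submat(),
    gapOpening = 2, gapExtension = 1
  )
  has_n <- grepl("N", reference, fixed = TRUE) |
    grepl("N", as.character(queries), fixed = TRUE)
  ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  if (any(has_n)) {
    # N must never count as a match, so recount those alignments per column
    ap <- as.character(Biostrings::alignedPattern(aln[has_n]))
    as_ <- as.character(Biostrings::alignedSubject(aln[has_n]))
    ident[has_n] <- vapply(seq_along(ap), function(i) {
      a <- strsplit(ap[i], "")[[1L]]
      b <- strsplit(as_[i], "")[[1L]]
      sum(a == b & a != "-" & a != "N") / length(a)
    }, numeric(1))
  }
  ident
}

# internal: ASV x genome-sequence identity/strand over both strands;
# returns a tibble (asv_id, accession, identity, strand) with the best
# identity per (ASV, accession) pair, copies collapsed
identity_table <- function(asv_seqs, catalogue) {
  accs <- names(catalogue$ssu)
  qnames <- names(asv_seqs)
  q_fwd <- as.character(asv_seqs)
  q_rev <- vapply(q_fwd, revcomp, character(1), USE.NAMES = FALSE)
  rows <- purrr::map(seq_along(catalogue$ssu), function(i) {
    ref <- as.character(catalogue$ssu[[i]])
    id_f <- aligned_identities(q_fwd, ref)
    id_r <- aligned_identities(q_rev, ref)
    tibble::tibble(
      asv_id = qnames,
      accession = accs[i],
      identity = pmax(id_f, id_r),
      strand = ifelse(id_r > id_f, "-", "+")
    )
  })
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::group_by(tab, .data$asv_id, .data$accession)
  # best identity over a genome's 16S copies represents the genome
  tab <- dplyr::slice_max(tab, .data$identity, n = 1L, with_ties = FALSE)
  dplyr::ungroup(tab)
}

#' Match a set of ASV sequences against a genome catalogue
#'
#' Scans every genome 16S sequence on both strands (a genome with
#' multiple 16S copies is represented by its best copy). Per ASV, among
#' genomes reaching the identity threshold the highest identity wins;
#' exact identity ties are broken by higher completeness, then lower
#' contamination, then accession order.
#'
#' @param asv_seqs `DNAStringSet` (or named character vector) of ASV
#'   sequences.
#' @param catalogue Genome catalogue: list with `ssu` (`DNAStringSet`
#'   named by accession; repeated names are treated as 16S copies) and
#'   `metadata` (tibble with `accession`, `checkm_completeness`,
#'   `checkm_contamination`).
#' @param threshold Minimum identity (default 0.97).
#' @return Tibble with one row per matched ASV: `asv_id`, `accession`,
#'   `identity`, `strand`. ASVs with no hit at the threshold are absent.
#' @export
match_asvs <- function(asv_seqs, catalogue, threshold = 0.97) {
  if (!length(catalogue$ssu)) stop("catalogue is empty", call. = FALSE)
  if (!methods::is(asv_seqs, "DNAStringSet")) {
    asv_seqs <- Biostrings::DNAStringSet(asv_seqs)
  }
  if (is.null(names(asv_seqs))) stop("ASV sequences must be named", call. = FALSE)
  if (!length(asv_seqs)) {
    return(tibble::tibble(
      asv_id = character(), accession = character(),
      identity = double(), strand = character()
    ))
  }
  tab <- identity_table(asv_seqs, catalogue)
  tab <- dplyr::filter(tab, .data$identity >= threshold)
  if (!nrow(tab)) {
    return(tibble::tibble(
      asv_id = character(), accession = character(),
      identity = double(), strand = character()
    ))
  }
  tab <- dplyr::left_join(
    tab,
    dplyr::select(
      catalogue$metadata, "accession",
      "checkm_completeness", "checkm_contamination"
    ),
    by = "accession"
  )
  tab <- dplyr::arrange(
    tab, .data$asv_id, dplyr::desc(.data$identity),
    dplyr::desc(.data$checkm_completeness),
    .data$checkm_contamination, .data$accession
  )
  tab <- dplyr::slice_head(dplyr::group_by(tab, .data$asv_id), n = 1L)
  out <- dplyr::select(
    dplyr::ungroup(tab), "asv_id", "accession", "identity", "strand"
  )
  out[match(intersect(names(asv_seqs), out$asv_id), out$asv_id), ]
}

#' Match one ASV against a genome catalogue
#'
#' Single-query convenience wrapper around [match_asvs()].
#'
#' @param asv_seq Query sequence (character or `DNAString`).
#' @inheritParams match_asvs
#' @return One-row tibble (`accession`, `identity`, `strand`) or `NULL`
#'   if no genome reaches the threshold.
#' @export
best_match <- function(asv_seq, catalogue, threshold = 0.97) {
  res <- match_asvs(
    Biostrings::DNAStringSet(setNames(as.character(asv_seq), "query")),
    catalogue, threshold
  )
  if (!nrow(res)) return(NULL)
  dplyr::select(res, "accession", "identity", "strand")
}

#' Resolve matched genomes into disjoint life-history sets
#'
#' Maps each group's matched accessions to a unique set and removes
#' genomes claimed by both groups from both.
#'
#' @param oligo_matches,copio_matches Match tibbles (or character
#'   vectors of accessions) for the oligotroph- and
#'   copiotroph-associated ASVs.
#' @return List with `oligotroph`, `copiotroph` (disjoint sorted
#'   accession vectors) and `removed` (accessions claimed by both).
#' @export
resolve_genome_sets <- function(oligo_matches, copio_matches) {
  get_acc <- function(x) {
    if (is.data.frame(x)) unique(x$accession) else unique(as.character(x))
  }
  oligo <- get_acc(oligo_matches)
  copio <- get_acc(copio_matches)
  shared <- intersect(oligo, copio)
  list(
    oligotroph = sort(setdiff(oligo, shared)),
    copiotroph = sort(setdiff(copio, shared)),
    removed = sort(shared)
  )
}
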