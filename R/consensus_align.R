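# Pairwise global alignment, percent identity, and majority-rule consensus.
# The alignment engine is Biostrings::pairwiseAlignment (Needleman-Wunsch
# with affine gaps; "overlap" type when terminal gaps are free); identity
# bookkeeping and consensus construction are done here.

#' Alignment scoring scheme
#'
#' Affine-gap nucleotide scoring. With `end_gaps_free = TRUE` (the default)
#' terminal gaps are unpenalised, so length differences and terminal
#' overhangs do not drag identity down; this matches identity figures quoted
#' "over the entire length" of elements of slightly different lengths.
#'
#' @param match Match score (> mismatch).
#' @param mismatch Mismatch score.
#' @param gap_open Gap opening score (<= 0).
#' @param gap_extend Gap extension score per gap position (<= 0).
#' @param end_gaps_free Whether terminal gaps are free.
#' @return A list of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2, end_gaps_free = TRUE) {
  if (match <= mismatch) abort("scoring_scheme: match must exceed mismatch")
  if (gap_open > 0 || gap_extend > 0) {
    abort("scoring_scheme: gap penalties must be <= 0")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, end_gaps_free = end_gaps_free),
            class = "scoring_scheme")
}

.subst_matrix <- function(s) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(s$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- s$match
  m["N", "N"] <- s$mismatch  # N never matches anything, including itself
  m
}

#' Global pairwise alignment
#'
#' Optimal global alignment of two nucleotide sequences under an affine gap
#' model ([scoring_scheme()]). Identity bookkeeping spans the columns between
#' the first and the last aligned residue pair: internal gap columns count in
#' the denominator, terminal overhangs do not.
#'
#' @param a,b Nucleotide strings (non-empty).
#' @param scheme A [scoring_scheme()].
#' @return A one-row tibble: `aligned_a`, `aligned_b` (equal-length gapped
#'   strings), `score`, `matches`, `aligned_columns`.
#' @examples
#' global_align("ACGT", "ACGA")
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) abort("global_align: empty input sequence")
  .check_nuc(c(a, b))
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b,
    type = if (scheme$end_gaps_free) "overlap" else "global",
    substitutionMatrix = .subst_matrix(scheme),
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- .chars(pa)
  cb <- .chars(pb)
  both <- which(ca != "-" & cb != "-")
  if (length(both) == 0L) {
    matches <- 0L
    cols <- 0L
  } else {
    span <- both[1L]:both[length(both)]
    matches <- sum(ca[span] == cb[span] & ca[span] != "-" & ca[span] != "N")
    cols <- length(span)
  }
  tibble(
    aligned_a = pa, aligned_b = pb,
    score = Biostrings::score(aln),
    matches = as.integer(matches),
    aligned_columns = as.integer(cols)
  )
}

#' Percent identity of an alignment
#'
#' `100 * matches / aligned_columns`, where `aligned_columns` spans the first
#' to the last aligned pair (internal gap columns count in the denominator,
#' terminal overhangs do not).
#'
#' @param aln Tibble from [global_align()] (one or more rows).
#' @return Numeric vector of percentages.
#' @export
percent_identity <- function(aln) {
  if (any(aln$aligned_columns == 0L)) {
    abort("percent_identity: alignment has no aligned columns")
  }
  100 * aln$matches / aln$aligned_columns
}

#' Majority-rule consensus from a multiple alignment
#'
#' Per column, the most frequent base among `{A,C,G,T}` wins (`N` and gaps do
#' not vote for a base); columns where the gap character is the strict
#' plurality are dropped from the consensus. Base ties are broken in the
#' fixed order A < C < G < T, so the result is reproducible and invariant
#' under row permutation.
#'
#' @param msa Tibble with columns `id` and `seq`: >= 2 equal-length gapped
#'   rows over `{A,C,G,T,N,-}`.
#' @return An object of class `"consensus_result"`: fields `consensus`
#'   (ungapped string), `support` (fraction of rows agreeing with the
#'   consensus base, per emitted position), `n_rows`. [tidy()] returns a
#'   per-position tibble.
#' @export
build_consensus <- function(msa) {
  .check_seq_tbl(msa, "msa")
  if (nrow(msa) < 2L) abort("build_consensus: need at least two rows")
  lens <- str_length(msa$seq)
  if (length(unique(lens)) != 1L) abort("build_consensus: ragged rows")
  bad <- regexpr("[^ACGTN-]", msa$seq)
  if (any(bad > 0L)) abort("build_consensus: rows must be over {A,C,G,T,N,-}")
  m <- do.call(rbind, strsplit(msa$seq, "", fixed = TRUE))
  n_rows <- nrow(m)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  gaps <- colSums(m == "-")
  top_i <- apply(counts, 1L, which.max)  # ties: first index = A<C<G<T order
  top_n <- counts[cbind(seq_len(nrow(counts)), top_i)]
  keep <- gaps <= top_n & top_n > 0
  structure(
    list(
      consensus = .collapse(bases[top_i[keep]]),
      support = unname(top_n[keep] / n_rows),
      n_rows = n_rows
    ),
    class = "consensus_result"
  )
}

#' @exportS3Method generics::tidy
tidy.consensus_result <- function(x, ...) {
  tibble(position = seq_along(x$support),
         base = .chars(x$consensus),
         support = x$support)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d bp from %d rows; mean support %.3f\n",
              str_length(x$consensus), x$n_rows, mean(x$support)))
  invisible(x)
}

#' Identity of copies to a family consensus
#'
#' One [global_align()] + [percent_identity()] per copy.
#'
#' @param copies Tibble with columns `id` and `seq`.
#' @param consensus Consensus nucleotide string (non-empty).
#' @param scheme A [scoring_scheme()].
#' @return Tibble with columns `copy_id` and `identity`.
#' @export
identity_to_consensus <- function(copies, consensus,
                                  scheme = scoring_scheme()) {
  if (!nzchar(consensus)) abort("identity_to_consensus: empty consensus")
  if (nrow(copies) == 0L) {
    return(tibble(copy_id = character(), identity = numeric()))
  }
  .check_seq_tbl(copies, "copies")
  ident <- purrr::map_dbl(copies$seq, function(s) {
    percent_identity(global_align(s, consensus, scheme))
  })
  tibble(copy_id = copies$id, identity = ident)
}

#' Stack copies into a seed-anchored multiple alignment
#'
#' A light multiple-alignment construction for consensus building: every copy
#' is globally aligned to a seed (the longest copy by default) and projected
#' onto the seed's coordinates; copy bases inserted relative to the seed are
#' dropped and seed positions the copy does not cover become gaps. The result
#' is a rectangular row set suitable for [build_consensus()]. Full
#' progressive multiple alignment is deliberately out of scope.
#'
#' @param copies Tibble with columns `id` and `seq` (>= 2 copies).
#' @param scheme A [scoring_scheme()].
#' @param seed_id Optional id of the seed copy; default: the longest copy.
#' @return Tibble with columns `id` and `seq` of equal-length gapped rows
#'   (seed coordinates).
#' @export
align_to_seed <- function(copies, scheme = scoring_scheme(), seed_id = NULL) {
  .check_seq_tbl(copies, "copies")
  if (nrow(copies) < 2L) abort("align_to_seed: need at least two copies")
  seed_row <- if (is.null(seed_id)) {
    which.max(str_length(copies$seq))
  } else {
    match(seed_id, copies$id)
  }
  if (is.na(seed_row)) abort("align_to_seed: seed_id not found")
  seed <- copies$seq[seed_row]
  slen <- str_length(seed)
  rows <- purrr::map_chr(seq_len(nrow(copies)), function(i) {
    if (i == seed_row) return(seed)
    aln <- global_align(copies$seq[i], seed, scheme)
    ca <- .chars(aln$aligned_a)
    cb <- .chars(aln$aligned_b)
    out <- rep("-", slen)
    pos <- cumsum(cb != "-")
    keep <- cb != "-"
    out[pos[keep]] <- ca[keep]
    .collapse(out)
  })
  tibble(id = copies$id, seq = rows)
}
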