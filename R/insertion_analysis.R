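# TSD calling and family-level insertion statistics.
#
# An insertion locus is the pair of host flanks around one element copy:
# `left_flank` (its 3' end abuts the element 5' boundary) and `right_flank`
# (its 5' end abuts the element 3' boundary). A target site duplication (TSD)
# shows up as an exact string shared between the end of the left flank and
# the start of the right flank. Because annotated element boundaries of
# truncated copies are imprecise, a small boundary slack is allowed: the
# shared string may terminate up to `slack` bp before the left flank's 3'
# end and begin up to `slack` bp into the right flank (the skipped bases are
# element-side sequence). For each slack pair the problem is the classic
# string overlap: the longest suffix of the adjusted left flank that equals
# a prefix of the adjusted right flank.

.call_tsd1 <- function(locus_id, left, right, min_len, max_len, slack) {
  nl <- str_length(left)
  nr <- str_length(right)
  if (nl < max_len + slack || nr < max_len + slack) {
    abort(sprintf(
      "locus %s: flanks must be at least max_len + slack = %d bp (got %d and %d)",
      locus_id, max_len + slack, nl, nr))
  }
  best_len <- 0L
  best_ls <- 0L
  best_rs <- 0L
  for (ls in 0:slack) {
    for (rs in 0:slack) {
      lim <- min(max_len, nl - ls, nr - rs)
      if (lim < 1L) next
      suff <- str_sub(left, nl - ls - lim + 1L, nl - ls)
      pref <- str_sub(right, rs + 1L, rs + lim)
      L <- 0L
      for (k in lim:1) {
        if (str_sub(suff, lim - k + 1L, lim) == str_sub(pref, 1L, k)) {
          L <- k
          break
        }
      }
      if (L > best_len ||
          (L == best_len && L > 0L &&
             (ls + rs < best_ls + best_rs ||
                (ls + rs == best_ls + best_rs && ls < best_ls)))) {
        best_len <- L
        best_ls <- ls
        best_rs <- rs
      }
    }
  }
  status <- if (best_len >= min_len) "tsd" else "none"
  if (status == "tsd") {
    ls <- best_ls
    rs <- best_rs
    tsd_seq <- str_sub(left, nl - ls - best_len + 1L, nl - ls)
    tgt_end <- nl - ls - best_len
  } else {
    tsd_seq <- ""
    best_len <- 0L
    ls <- 0L
    rs <- 0L
    tgt_end <- nl
  }
  target <- if (tgt_end >= 4L) str_sub(left, tgt_end - 3L, tgt_end) else NA_character_
  tibble(
    locus_id = locus_id, status = status, tsd_seq = tsd_seq,
    tsd_len = best_len, left_slack = ls, right_slack = rs,
    target_tetranucleotide = target,
    t_rich = if (is.na(target)) NA else check_target_site(target)
  )
}

#' Call target site duplications at insertion loci
#'
#' For each locus, finds the longest exact string that terminates within
#' `slack` bp of the left flank's 3' end and begins within `slack` bp of the
#' right flank's 5' start. If its length reaches `min_len` the locus gets
#' `status = "tsd"`; otherwise `"none"`. Ties on length are broken by the
#' smallest total slack, then the smallest left slack. The target
#' tetranucleotide (the 4-mer immediately 5' of the 5'-TSD copy, or of the
#' insertion point when there is no TSD) and its T-richness are always
#' reported.
#'
#' Typical TSDs of these families run about 7-19 bp, but much longer ones
#' occur (hundreds of bp); raise `max_len` (e.g. to 500) to call those.
#'
#' @param loci Tibble with columns `locus_id`, `left_flank`, `right_flank`.
#' @param min_len Minimum length for a positive TSD call, bp.
#' @param max_len Maximum TSD length searched, bp.
#' @param slack Maximum boundary adjustment on each flank, bp.
#' @return Tibble with one row per locus: `locus_id`, `status`, `tsd_seq`,
#'   `tsd_len`, `left_slack`, `right_slack`, `target_tetranucleotide`,
#'   `t_rich`.
#' @export
call_tsd <- function(loci, min_len = 5L, max_len = 25L, slack = 3L) {
  req <- c("locus_id", "left_flank", "right_flank")
  if (!is.data.frame(loci) || !all(req %in% names(loci))) {
    abort("`loci` must have columns locus_id, left_flank, right_flank")
  }
  if (any(!nzchar(loci$left_flank)) || any(!nzchar(loci$right_flank))) {
    abort("`loci` contains an empty flank")
  }
  .check_nuc(loci$left_flank, "left_flank")
  .check_nuc(loci$right_flank, "right_flank")
  bind_rows(purrr::pmap(
    list(loci$locus_id, loci$left_flank, loci$right_flank),
    .call_tsd1,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    slack = as.integer(slack)
  ))
}

#' Is a target tetranucleotide T-rich?
#'
#' `TRUE` when at least 3 of the 4 bases are `T`. This captures the observed
#' insertion-target set (`TTTT` and the T-rich variants `TTTG`, `TTTC`,
#' `TCTT`, `TGTT`) together with the remaining single-substitution
#' permutations.
#'
#' @param tetranucleotide Character vector of 4-mers.
#' @return Logical vector.
#' @examples
#' check_target_site(c("TTTT", "TTTG", "TTAG"))
#' @export
check_target_site <- function(tetranucleotide) {
  if (any(str_length(tetranucleotide) != 4L)) {
    abort("check_target_site: each input must be exactly 4 bases")
  }
  vapply(strsplit(tetranucleotide, "", fixed = TRUE),
         function(x) sum(x == "T") >= 3L, logical(1))
}

#' Reconstruct the pre-insertion (empty) site
#'
#' Joins the two flanks of each locus, removing exactly one TSD copy when the
#' call reported one (the copy at the left flank's adjusted 3' end), so the
#' result has length `nchar(left) + nchar(right) - tsd_len`. For `status =
#' "none"` the flanks are simply concatenated, which for target-specific,
#' TSD-less insertions restores runs such as `TTTTT` across the junction.
#'
#' @param loci Tibble as for [call_tsd()].
#' @param calls The matching tibble returned by [call_tsd()] on `loci`.
#' @return Tibble with columns `locus_id` and `empty_site`.
#' @export
reconstruct_empty_site <- function(loci, calls) {
  if (!identical(loci$locus_id, calls$locus_id)) {
    abort("`calls` must come from call_tsd() on the same `loci`, in order")
  }
  out <- purrr::pmap_chr(
    list(loci$left_flank, loci$right_flank, calls$status, calls$tsd_seq,
         calls$tsd_len, calls$left_slack),
    function(left, right, status, tsd_seq, tsd_len, ls) {
      if (status == "none") return(paste0(left, right))
      nl <- str_length(left)
      tstart <- nl - ls - tsd_len + 1L
      if (str_sub(left, tstart, nl - ls) != tsd_seq) {
        abort("inconsistent call/locus pair: TSD not found at stated position")
      }
      paste0(str_sub(left, 1L, tstart - 1L),
             str_sub(left, tstart + tsd_len, nl),
             right)
    }
  )
  tibble(locus_id = loci$locus_id, empty_site = out)
}

#' Summarise TSD statistics for a repeat family
#'
#' Applies [call_tsd()] with shared parameters to every locus of a family and
#' tallies the results: TSD fraction, TSD length histogram, target
#' tetranucleotide counts, and the fraction of T-rich targets.
#'
#' @param loci Tibble as for [call_tsd()] (>= 1 locus).
#' @param family_id Label for the family.
#' @inheritParams call_tsd
#' @return A one-row tibble of class `"family_insertion_summary"`:
#'   `family_id`, `n_loci`, `n_tsd`, `tsd_fraction`, `t_rich_fraction`, and
#'   list-columns `tsd_length_histogram` (tibble `tsd_len`, `n`) and
#'   `target_counts` (tibble `target_tetranucleotide`, `n`).
#' @export
summarize_family <- function(loci, family_id = "family", min_len = 5L,
                             max_len = 25L, slack = 3L) {
  if (nrow(loci) < 1L) abort("summarize_family: need at least one locus")
  calls <- call_tsd(loci, min_len = min_len, max_len = max_len, slack = slack)
  tsd <- filter(calls, .data$status == "tsd")
  hist <- count(arrange(tsd, .data$tsd_len), .data$tsd_len, name = "n")
  tgt <- count(filter(calls, !is.na(.data$target_tetranucleotide)),
               .data$target_tetranucleotide, name = "n")
  known <- filter(calls, !is.na(.data$t_rich))
  out <- tibble(
    family_id = family_id,
    n_loci = nrow(calls),
    n_tsd = nrow(tsd),
    tsd_fraction = nrow(tsd) / nrow(calls),
    t_rich_fraction = if (nrow(known)) mean(known$t_rich) else NA_real_,
    tsd_length_histogram = list(hist),
    target_counts = list(tgt)
  )
  class(out) <- c("family_insertion_summary", class(out))
  out
}

#' Truncation profile of a repeat family
#'
#' Per-position copy depth over the family consensus, from copy-to-consensus
#' alignment intervals, plus the fractions of copies intact at either
#' terminus. A copy counts as 5'-intact when its alignment starts within the
#' first `d` bp of the consensus, and 3'-intact when it ends within the last
#' `d` bp. One-ended (rolling-circle-like) replication leaves a family
#' 3'-intact but frequently 5'-truncated, which shows up as a coverage ramp
#' rising toward the 3' end.
#'
#' @param copy_alignments Tibble with columns `copy_id`, `start`, `end`:
#'   1-based inclusive consensus interval covered by each copy.
#' @param consensus_len Consensus length, bp.
#' @param d Terminal window width, bp.
#' @param family_id Label for the family.
#' @return An object of class `"truncation_profile"` with fields
#'   `family_id`, `consensus_len`, `coverage` (integer vector of length
#'   `consensus_len`), `five_prime_intact_fraction`,
#'   `three_prime_intact_fraction`, `n_copies`. Use [tidy()] for the
#'   per-position coverage tibble, [glance()] for the one-row summary, and
#'   [autoplot()] to plot the coverage ramp.
#' @export
truncation_profile <- function(copy_alignments, consensus_len, d = 20L,
                               family_id = "family") {
  req <- c("copy_id", "start", "end")
  if (!is.data.frame(copy_alignments) || !all(req %in% names(copy_alignments))) {
    abort("`copy_alignments` must have columns copy_id, start, end")
  }
  consensus_len <- as.integer(consensus_len)
  a <- copy_alignments
  if (nrow(a) > 0 &&
      (any(a$start < 1L) || any(a$end > consensus_len) || any(a$start > a$end))) {
    abort("truncation_profile: interval out of range of the consensus")
  }
  cov <- integer(consensus_len)
  for (i in seq_len(nrow(a))) {
    cov[a$start[i]:a$end[i]] <- cov[a$start[i]:a$end[i]] + 1L
  }
  structure(
    list(
      family_id = family_id,
      consensus_len = consensus_len,
      coverage = cov,
      five_prime_intact_fraction =
        if (nrow(a)) mean(a$start <= d) else NA_real_,
      three_prime_intact_fraction =
        if (nrow(a)) mean(a$end >= consensus_len - d + 1L) else NA_real_,
      n_copies = nrow(a)
    ),
    class = "truncation_profile"
  )
}

#' @exportS3Method generics::tidy
tidy.truncation_profile <- function(x, ...) {
  tibble(position = seq_len(x$consensus_len), depth = x$coverage)
}

#' @exportS3Method generics::glance
glance.truncation_profile <- function(x, ...) {
  tibble(
    family_id = x$family_id,
    consensus_len = x$consensus_len,
    n_copies = x$n_copies,
    five_prime_intact_fraction = x$five_prime_intact_fraction,
    three_prime_intact_fraction = x$three_prime_intact_fraction
  )
}

#' @export
print.truncation_profile <- function(x, ...) {
  cat(sprintf(
    "<truncation_profile> %s: %d copies over %d bp; 5'-intact %.2f, 3'-intact %.2f\n",
    x$family_id, x$n_copies, x$consensus_len,
    x$five_prime_intact_fraction, x$three_prime_intact_fraction))
  invisible(x)
}
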