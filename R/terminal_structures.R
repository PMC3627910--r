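# Terminal-structure detectors: TIRs, hairpins, ATIR pairs, Helitron calls.
# Pairing is combinatorial DNA complementarity (A:T, C:G); G.T wobbles count
# as mismatches and N never pairs.

.is_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

# Single-sequence TIR search. Candidate arms are anchored near both termini
# (left arm starting within max_offset of the 5' end, right arm ending within
# max_offset of the 3' end). For each offset pair the arm is grown inward
# under a match/mismatch score (+1/-2), so random inward extension has
# negative drift and the reported arm is the maximal-scoring one; candidates
# must satisfy the mismatch-fraction bound and start and end on matching
# pairs. Among offset pairs: longest arm, then fewest mismatches, then
# smallest left offset, then smallest right offset.
.find_tirs1 <- function(id, seq, min_len, max_offset, max_mismatch_frac) {
  n <- str_length(seq)
  ch <- .chars(seq)
  best <- NULL
  for (a in 0:max_offset) {
    for (b in 0:max_offset) {
      lmax <- (n - a - b) %/% 2L
      if (lmax < min_len) next
      k <- seq_len(lmax)
      left <- ch[a + k]
      right <- ch[n - b + 1L - k]
      mm <- !.is_pair(left, right)
      # positive prefix-score maximisation with terminal-match requirement
      score <- cumsum(ifelse(mm, -2L, 1L))
      cum_mm <- cumsum(mm)
      ok <- k >= min_len & !mm & cum_mm <= floor(k * max_mismatch_frac) &
        !mm[1L]
      if (!any(ok)) next
      cand <- which(ok)
      L <- cand[which.max(score[cand])]
      rec <- list(arm_len = L, mismatches = cum_mm[L], left_offset = a,
                  right_offset = b)
      if (is.null(best) ||
          rec$arm_len > best$arm_len ||
          (rec$arm_len == best$arm_len && rec$mismatches < best$mismatches) ||
          (rec$arm_len == best$arm_len && rec$mismatches == best$mismatches &&
             rec$left_offset < best$left_offset)) {
        best <- rec
      }
    }
  }
  if (is.null(best)) {
    return(tibble(
      id = character(), arm_len = integer(), mismatches = integer(),
      left_offset = integer(), right_offset = integer(),
      left_start = integer(), left_end = integer(),
      right_start = integer(), right_end = integer()
    ))
  }
  tibble(
    id = id, arm_len = best$arm_len, mismatches = as.integer(best$mismatches),
    left_offset = best$left_offset, right_offset = best$right_offset,
    left_start = best$left_offset + 1L,
    left_end = best$left_offset + best$arm_len,
    right_start = n - best$right_offset - best$arm_len + 1L,
    right_end = n - best$right_offset
  )
}

#' Find terminal inverted repeats
#'
#' Reports, per element, the maximal inverted repeat whose left arm starts
#' within `max_offset` bp of the 5' end and whose right arm ends within
#' `max_offset` bp of the 3' end. Arm length is maximised under a
#' match/mismatch extension score so that arms end at the true repeat
#' boundary rather than drifting into random flanking pairs; candidates must
#' keep their mismatch count at or below `floor(arm_len * max_mismatch_frac)`
#' and both terminal pairs of the arm must be complementary. Ties between
#' offset placements are broken by fewest mismatches, then smallest left
#' offset. Elements with no qualifying arm of at least `min_len` bp
#' contribute no row.
#'
#' @param elems Tibble with columns `id` and `seq` (elements, 5' to 3').
#' @param min_len Minimum arm length in bp (must be >= 4).
#' @param max_offset Maximum distance of each arm from its terminus, bp.
#' @param max_mismatch_frac Maximum fraction of mismatched arm positions.
#' @return Tibble with one row per element with a detected TIR: `id`,
#'   `arm_len`, `mismatches`, `left_offset`, `right_offset` and 1-based arm
#'   coordinates `left_start`, `left_end`, `right_start`, `right_end`.
#' @export
find_tirs <- function(elems, min_len = 10L, max_offset = 5L,
                      max_mismatch_frac = 0.2) {
  .check_seq_tbl(elems, "elems")
  if (min_len < 4L) abort("find_tirs: min_len must be >= 4")
  .check_nuc(elems$seq)
  bind_rows(purrr::map2(elems$id, elems$seq, .find_tirs1,
                        min_len = as.integer(min_len),
                        max_offset = as.integer(max_offset),
                        max_mismatch_frac = max_mismatch_frac))
}

# Single-sequence hairpin search inside a window [wstart, wend] (1-based,
# inclusive). For every loop placement (loop_start, loop_len) the stem is the
# unique longest arm pair with at most max_mismatches internal mismatches
# whose innermost and outermost pairs are complementary; a hairpin whose stem
# could grow into the loop (inner pair complementary and remaining loop still
# >= loop_min) is suppressed in favour of the longer-stemmed variant.
.find_hairpins1 <- function(id, seq, wstart, wend, stem_min, loop_min,
                            loop_max, max_mismatches) {
  ch <- .chars(seq)
  out <- list()
  if (wend - wstart + 1L >= 2L * stem_min + loop_min) {
    for (loop_len in loop_min:loop_max) {
      ls_hi <- wend - loop_len + 1L - stem_min
      ls_lo <- wstart + stem_min
      if (ls_hi < ls_lo) next
      for (loop_start in ls_lo:ls_hi) {
        loop_end <- loop_start + loop_len - 1L
        smax <- min(loop_start - wstart, wend - loop_end)
        if (smax < stem_min) next
        k <- seq_len(smax)
        mm <- !.is_pair(ch[loop_start - k], ch[loop_end + k])
        cum_mm <- cumsum(mm)
        ok <- !mm & cum_mm <= max_mismatches & !mm[1L]
        if (!any(ok)) next
        s <- max(which(ok))
        if (s < stem_min) next
        # inner extendability: the loop-adjacent pair is handled at the
        # smaller-loop placement; suppress the duplicate here
        if (loop_len - 2L >= loop_min &&
            .is_pair(ch[loop_start], ch[loop_end])) next
        out[[length(out) + 1L]] <- c(loop_start - s, s, loop_len, cum_mm[s])
      }
    }
  }
  if (!length(out)) {
    return(tibble(
      id = character(), stem_left_start = integer(), stem_left_end = integer(),
      stem_right_start = integer(), stem_right_end = integer(),
      stem_len = integer(), loop_len = integer(), mismatches = integer()
    ))
  }
  m <- unique(do.call(rbind, out))
  # repetitive arms admit shifted sub-pairings of one physical stem; drop any
  # hairpin whose full span lies inside the span of a longer-stemmed one
  if (nrow(m) > 1L) {
    span_s <- m[, 1]
    span_e <- m[, 1] + 2L * m[, 2] + m[, 3] - 1L
    keep <- vapply(seq_len(nrow(m)), function(i) {
      !any(span_s <= span_s[i] & span_e >= span_e[i] & m[, 2] > m[i, 2])
    }, logical(1))
    m <- m[keep, , drop = FALSE]
  }
  tb <- tibble(
    id = id,
    stem_left_start = m[, 1],
    stem_left_end = m[, 1] + m[, 2] - 1L,
    stem_right_start = m[, 1] + m[, 2] + m[, 3],
    stem_right_end = m[, 1] + 2L * m[, 2] + m[, 3] - 1L,
    stem_len = m[, 2], loop_len = m[, 3], mismatches = m[, 4]
  )
  arrange(tb, .data$stem_left_start, .data$loop_len)
}

#' Find hairpins (stem-loops)
#'
#' Purely combinatorial stem-loop finder: two nearby reverse-complementary
#' arms separated by a short loop, with bounded mismatches and no
#' thermodynamic model. All maximal hairpins inside the window are returned:
#' per loop placement the longest admissible stem, not extendable by one
#' complementary pair at either stem end, with complementary innermost and
#' outermost pairs. Repetitive arms can pair in several shifted registers;
#' shifted sub-pairings whose span lies inside that of a longer-stemmed
#' hairpin are suppressed, so one physical stem-loop is reported once.
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param window Optional length-2 integer vector `c(start, end)` (1-based,
#'   inclusive) restricting the search; applied to every sequence. Default:
#'   the whole sequence.
#' @param stem_min Minimum stem length, bp.
#' @param loop_min,loop_max Loop length bounds, bp.
#' @param max_mismatches Maximum mismatched pairs per stem.
#' @return Tibble with one row per hairpin: `id`, `stem_left_start`,
#'   `stem_left_end`, `stem_right_start`, `stem_right_end`, `stem_len`,
#'   `loop_len`, `mismatches`, sorted by stem start.
#' @export
find_hairpins <- function(seqs, window = NULL, stem_min = 6L, loop_min = 3L,
                          loop_max = 15L, max_mismatches = 1L) {
  .check_seq_tbl(seqs, "seqs")
  if (loop_min > loop_max) abort("find_hairpins: loop_min > loop_max")
  .check_nuc(seqs$seq)
  bind_rows(purrr::map2(seqs$id, seqs$seq, function(id, s) {
    n <- str_length(s)
    w <- if (is.null(window)) c(1L, n) else as.integer(window)
    if (w[1] < 1L || w[2] > n || w[1] > w[2]) {
      abort(sprintf("find_hairpins: window out of bounds for sequence %s", id))
    }
    .find_hairpins1(id, s, w[1], w[2], as.integer(stem_min),
                    as.integer(loop_min), as.integer(loop_max),
                    as.integer(max_mismatches))
  }))
}

#' Default parameters for ATIR and Helitron detection
#'
#' Bundles the tunable thresholds of [find_atir_pair()] and
#' [classify_helitron()]. ATIR arms are short (8-15 bp) inverted repeats
#' placed asymmetrically: the 5' arm within 0-2 bp of the 5' terminus, the 3'
#' arm ending subterminally (15-40 bp from the 3' end; slightly wider than
#' the typical 20-30 bp placement, for tolerance) and immediately upstream
#' (gap at most `atir_hairpin_gap_max`) of a 3' hairpin.
#'
#' @param atir_arm_min,atir_arm_max ATIR arm length range, bp.
#' @param atir_max_mismatches Maximum mismatched pairs in an ATIR arm.
#' @param five_prime_offset_max Maximum 5' arm offset from the 5' end, bp.
#' @param subterminal_min,subterminal_max Allowed distance of the 3' arm end
#'   from the 3' terminus, bp.
#' @param atir_hairpin_gap_max Maximum gap between the 3' arm end and the 3'
#'   hairpin stem start, bp.
#' @param hairpin_window Width of the terminal windows searched for hairpins,
#'   bp.
#' @param stem_min,loop_min,loop_max,max_mismatches Hairpin parameters passed
#'   to [find_hairpins()].
#' @return A named list of class `"helitron_params"`.
#' @export
helitron_params <- function(atir_arm_min = 8L, atir_arm_max = 15L,
                            atir_max_mismatches = 1L,
                            five_prime_offset_max = 2L,
                            subterminal_min = 15L, subterminal_max = 40L,
                            atir_hairpin_gap_max = 3L,
                            hairpin_window = 50L,
                            stem_min = 6L, loop_min = 3L, loop_max = 15L,
                            max_mismatches = 1L) {
  p <- lapply(list(
    atir_arm_min = atir_arm_min, atir_arm_max = atir_arm_max,
    atir_max_mismatches = atir_max_mismatches,
    five_prime_offset_max = five_prime_offset_max,
    subterminal_min = subterminal_min, subterminal_max = subterminal_max,
    atir_hairpin_gap_max = atir_hairpin_gap_max,
    hairpin_window = hairpin_window,
    stem_min = stem_min, loop_min = loop_min, loop_max = loop_max,
    max_mismatches = max_mismatches
  ), as.integer)
  if (p$atir_arm_min > p$atir_arm_max) abort("atir_arm_min > atir_arm_max")
  if (p$subterminal_min > p$subterminal_max) abort("subterminal_min > subterminal_max")
  structure(p, class = "helitron_params")
}

# hairpins within the last `window` bp of the element
.three_prime_hairpins <- function(id, seq, p) {
  n <- str_length(seq)
  .find_hairpins1(id, seq, max(1L, n - p$hairpin_window + 1L), n,
                  p$stem_min, p$loop_min, p$loop_max, p$max_mismatches)
}

.five_prime_hairpins <- function(id, seq, p) {
  n <- str_length(seq)
  .find_hairpins1(id, seq, 1L, min(n, p$hairpin_window),
                  p$stem_min, p$loop_min, p$loop_max, p$max_mismatches)
}

.find_atir_pair1 <- function(id, seq, p, hp3 = NULL) {
  n <- str_length(seq)
  ch <- .chars(seq)
  if (is.null(hp3)) hp3 <- .three_prime_hairpins(id, seq, p)
  empty <- tibble(
    id = character(), arm_len = integer(), mismatches = integer(),
    left_start = integer(), left_end = integer(),
    right_start = integer(), right_end = integer(),
    left_offset = integer(), right_offset = integer(),
    five_prime_ok = logical(), three_prime_ok = logical(),
    upstream_of_hairpin = logical()
  )
  if (n < 60L || nrow(hp3) == 0L) return(empty)
  best <- NULL
  for (L in seq(p$atir_arm_max, p$atir_arm_min)) {
    for (a in 0:p$five_prime_offset_max) {
      if (a + L > n) next
      left <- ch[a + seq_len(L)]
      for (r in p$subterminal_min:p$subterminal_max) {
        right_end <- n - r
        right_start <- right_end - L + 1L
        if (right_start <= a + L) next
        right <- ch[right_end + 1L - seq_len(L)]
        mmv <- !.is_pair(left, right)
        mm <- sum(mmv)
        if (mm > p$atir_max_mismatches || mmv[1L] || mmv[L]) next
        gap <- hp3$stem_left_start - right_end - 1L
        if (!any(gap >= 0L & gap <= p$atir_hairpin_gap_max)) next
        rec <- list(arm_len = L, mismatches = mm, left_offset = a,
                    right_offset = r, left_start = a + 1L, left_end = a + L,
                    right_start = right_start, right_end = right_end)
        if (is.null(best) ||
            rec$arm_len > best$arm_len ||
            (rec$arm_len == best$arm_len && rec$mismatches < best$mismatches) ||
            (rec$arm_len == best$arm_len && rec$mismatches == best$mismatches &&
               rec$left_offset < best$left_offset)) {
          best <- rec
        }
      }
    }
  }
  if (is.null(best)) return(empty)
  tibble(
    id = id, arm_len = best$arm_len, mismatches = as.integer(best$mismatches),
    left_start = best$left_start, left_end = best$left_end,
    right_start = best$right_start, right_end = best$right_end,
    left_offset = best$left_offset, right_offset = best$right_offset,
    five_prime_ok = TRUE, three_prime_ok = TRUE, upstream_of_hairpin = TRUE
  )
}

#' Find an asymmetric terminal inverted repeat (ATIR) pair
#'
#' The diagnostic Helitron2 feature: a short inverted repeat whose left arm
#' sits at the extreme 5' end (offset at most 2 bp by default), whose right
#' arm ends in the 3' subterminal region, immediately upstream of a 3'
#' hairpin. Per element the best qualifying pair is reported (longest arm,
#' then fewest mismatches, then smallest offsets); elements without one
#' contribute no row.
#'
#' @param elems Tibble with columns `id` and `seq` (elements >= 60 bp).
#' @param params A [helitron_params()] list.
#' @return Tibble with columns `id`, `arm_len`, `mismatches`, 1-based arm
#'   coordinates, `left_offset` (bp from the 5' end), `right_offset` (bp from
#'   the 3' end to the right arm end), and the qualification flags
#'   `five_prime_ok`, `three_prime_ok`, `upstream_of_hairpin` (all `TRUE` for
#'   reported pairs, by construction).
#' @export
find_atir_pair <- function(elems, params = helitron_params()) {
  .check_seq_tbl(elems, "elems")
  .check_nuc(elems$seq)
  bind_rows(purrr::map2(elems$id, elems$seq, .find_atir_pair1, p = params))
}

.classify_helitron1 <- function(id, seq, p) {
  n <- str_length(seq)
  ch1 <- substr(seq, 1L, 1L)
  first2 <- substr(seq, 1L, 2L)
  last4 <- substr(seq, n - 3L, n)
  hp5 <- .five_prime_hairpins(id, seq, p)
  hp3 <- .three_prime_hairpins(id, seq, p)
  atir <- .find_atir_pair1(id, seq, p, hp3 = hp3)

  five_prime_end_match <- first2 == "TC"
  three_prime_end_match <- grepl("^CT[AG][AG]$", last4)
  three_prime_hairpin <- nrow(hp3) > 0L
  atir_pair <- nrow(atir) == 1L
  # Helitron2 requires the 5' hairpin to involve part of the 5'-ATIR: at
  # least 1 bp overlap between a 5'-window hairpin and the left ATIR arm
  if (atir_pair && nrow(hp5) > 0L) {
    ov <- pmin(hp5$stem_right_end, atir$left_end) -
      pmax(hp5$stem_left_start, atir$left_start) + 1L
    five_prime_hairpin <- any(ov >= 1L)
  } else {
    five_prime_hairpin <- nrow(hp5) > 0L
  }

  verdict <- if (atir_pair && five_prime_hairpin && three_prime_hairpin &&
                 ch1 == "T" && nrow(hp5) > 0L) {
    "helitron2"
  } else if (five_prime_end_match && three_prime_end_match &&
             three_prime_hairpin && !atir_pair) {
    "helitron1"
  } else {
    "unclassified"
  }
  tibble(
    id = id, verdict = verdict,
    five_prime_end_match = five_prime_end_match,
    three_prime_end_match = three_prime_end_match,
    five_prime_hairpin = five_prime_hairpin,
    three_prime_hairpin = three_prime_hairpin,
    atir_pair = atir_pair,
    atir_arm_len = if (atir_pair) atir$arm_len else NA_integer_,
    atir_left_offset = if (atir_pair) atir$left_offset else NA_integer_,
    atir_right_offset = if (atir_pair) atir$right_offset else NA_integer_
  )
}

#' Classify Helitron candidates into Helitron1 / Helitron2
#'
#' A DNA-structure-only classifier (the orientation of any RepHel coding
#' sequence plays no role). An element is called `helitron2` when it carries
#' a qualifying ATIR pair, a 5' hairpin overlapping at least 1 bp of the
#' 5'-ATIR, a 3' hairpin, and starts with `T`. It is called `helitron1` when
#' it starts with `TC`, ends with `CTRR` (IUPAC `R` = A or G), has a
#' 3'-subterminal hairpin and no qualifying ATIR pair. Everything else is
#' `unclassified`. The per-criterion evidence booleans are always populated,
#' so the verdict is re-derivable from them.
#'
#' @param elems Tibble with columns `id` and `seq` (elements >= 100 bp).
#' @param params A [helitron_params()] list.
#' @return Tibble with one row per element: `id`, `verdict` (`"helitron1"`,
#'   `"helitron2"` or `"unclassified"`), evidence flags
#'   `five_prime_end_match`, `three_prime_end_match`, `five_prime_hairpin`,
#'   `three_prime_hairpin`, `atir_pair`, and the ATIR geometry columns
#'   (`NA` when absent).
#' @export
classify_helitron <- function(elems, params = helitron_params()) {
  .check_seq_tbl(elems, "elems")
  .check_nuc(elems$seq)
  if (any(str_length(elems$seq) < 100L)) {
    abort("classify_helitron: all elements must be >= 100 bp")
  }
  bind_rows(purrr::map2(elems$id, elems$seq, .classify_helitron1, p = params))
}
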