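#' Specification of the Fanzor/TnpB conserved-residue motif
#'
#' The Fanzor/TnpB signature is a constellation of strictly conserved
#' residues in the C-terminal protein half, written PROSITE-style as
#' `D-X(125,275)-[TS]-[TS]-X-X-[C4 zinc finger]-X(5,50)-RD`: an aspartate
#' anchor, a long bounded spacer, two consecutive residues each of which is T
#' or S, an exact two-residue spacer, a four-cysteine zinc finger
#' (OrfB_Zn_ribbon-like), a second bounded spacer, and a terminal arginine-
#' aspartate pair. All spacer notation `X(a,b)` counts residues strictly
#' between the two flanking anchors, so an anchor at position `i` followed by
#' one at `j` satisfies `a <= j - i - 1 <= b`.
#'
#' The internal spacing of the C4 zinc finger is not part of the published
#' motif string; the defaults admit canonical CxxC...CxxC fingers and are
#' fully configurable.
#'
#' @param d_ts_min,d_ts_max Residues strictly between the D anchor and the
#'   first `[TS]` position (defaults 125 and 275).
#' @param post_ts_gap Exact number of residues strictly between the second
#'   `[TS]` and the first zinc-finger cysteine (default 2, the literal `X-X`).
#' @param zf_gap12_min,zf_gap12_max,zf_gap23_min,zf_gap23_max,zf_gap34_min,zf_gap34_max
#'   Residues strictly between consecutive cysteines C1..C4
#'   (defaults 1-6, 4-30, 1-6).
#' @param zf_rd_min,zf_rd_max Residues strictly between C4 and the R of the
#'   terminal RD (defaults 5 and 50).
#' @param aux_anchors Optional data frame with columns `residue`, `min_gap`,
#'   `max_gap`: extra single-residue anchors required, in order, after the
#'   terminal D, each gap counted strictly between consecutive anchors.
#'   Default empty (disabled).
#' @return A list of class `"motif_spec"`.
#' @seealso [scan_protein()]
#' @export
motif_spec <- function(d_ts_min = 125L, d_ts_max = 275L,
                       post_ts_gap = 2L,
                       zf_gap12_min = 1L, zf_gap12_max = 6L,
                       zf_gap23_min = 4L, zf_gap23_max = 30L,
                       zf_gap34_min = 1L, zf_gap34_max = 6L,
                       zf_rd_min = 5L, zf_rd_max = 50L,
                       aux_anchors = NULL) {
  spec <- list(
    d_ts_min = as.integer(d_ts_min), d_ts_max = as.integer(d_ts_max),
    post_ts_gap = as.integer(post_ts_gap),
    zf_gap12_min = as.integer(zf_gap12_min), zf_gap12_max = as.integer(zf_gap12_max),
    zf_gap23_min = as.integer(zf_gap23_min), zf_gap23_max = as.integer(zf_gap23_max),
    zf_gap34_min = as.integer(zf_gap34_min), zf_gap34_max = as.integer(zf_gap34_max),
    zf_rd_min = as.integer(zf_rd_min), zf_rd_max = as.integer(zf_rd_max),
    aux_anchors = aux_anchors
  )
  pairs <- list(
    c("d_ts_min", "d_ts_max"), c("zf_gap12_min", "zf_gap12_max"),
    c("zf_gap23_min", "zf_gap23_max"), c("zf_gap34_min", "zf_gap34_max"),
    c("zf_rd_min", "zf_rd_max")
  )
  for (p in pairs) {
    if (spec[[p[1]]] > spec[[p[2]]]) {
      abort(sprintf("motif_spec: %s > %s", p[1], p[2]))
    }
    if (spec[[p[1]]] < 0L) abort(sprintf("motif_spec: %s < 0", p[1]))
  }
  if (spec$post_ts_gap < 0L) abort("motif_spec: post_ts_gap < 0")
  structure(spec, class = "motif_spec")
}

# minimal residue span a hit can occupy under `spec`
.motif_min_span <- function(spec) {
  # D + gap + T S + gap + C C C C + gap + R D, using the minimum of each gap
  1L + spec$d_ts_min + 2L + spec$post_ts_gap +
    1L + spec$zf_gap12_min + 1L + spec$zf_gap23_min + 1L + spec$zf_gap34_min +
    1L + spec$zf_rd_min + 2L
}

# positions (sorted) of anchor residues of one class
.anchor_pos <- function(ch, letters) which(ch %in% letters)

# candidates within [lo, hi] from a sorted position vector
.within <- function(pos, lo, hi) pos[pos >= lo & pos <= hi]

.scan_protein1 <- function(id, seq, spec) {
  ch <- .chars(seq)
  n <- length(ch)
  empty <- tibble(
    protein_id = character(), pos_d = integer(), pos_ts1 = integer(),
    pos_ts2 = integer(), pos_c1 = integer(), pos_c2 = integer(),
    pos_c3 = integer(), pos_c4 = integer(), pos_r = integer(),
    pos_d2 = integer(), span = integer()
  )
  if (n < .motif_min_span(spec)) return(empty)
  d_pos <- which(ch == "D")
  c_pos <- which(ch == "C")
  ts1 <- which(ch %in% c("T", "S"))
  ts1 <- ts1[ts1 < n & ch[ts1 + 1L] %in% c("T", "S")]
  if (!length(d_pos) || !length(ts1) || length(c_pos) < 4L) return(empty)

  hits <- list()
  for (d in d_pos) {
    for (t1 in .within(ts1, d + spec$d_ts_min + 1L, d + spec$d_ts_max + 1L)) {
      t2 <- t1 + 1L
      c1 <- t2 + spec$post_ts_gap + 1L
      if (c1 > n || ch[c1] != "C") next
      for (c2 in .within(c_pos, c1 + spec$zf_gap12_min + 1L, c1 + spec$zf_gap12_max + 1L)) {
        for (c3 in .within(c_pos, c2 + spec$zf_gap23_min + 1L, c2 + spec$zf_gap23_max + 1L)) {
          for (c4 in .within(c_pos, c3 + spec$zf_gap34_min + 1L, c3 + spec$zf_gap34_max + 1L)) {
            r_lo <- c4 + spec$zf_rd_min + 1L
            r_hi <- min(c4 + spec$zf_rd_max + 1L, n - 1L)
            if (r_lo > r_hi) next
            for (r in r_lo:r_hi) {
              if (ch[r] != "R" || ch[r + 1L] != "D") next
              d2 <- r + 1L
              if (!.aux_ok(ch, d2, spec$aux_anchors)) next
              hits[[length(hits) + 1L]] <- c(d, t1, t2, c1, c2, c3, c4, r, d2)
            }
          }
        }
      }
    }
  }
  if (!length(hits)) return(empty)
  m <- do.call(rbind, hits)
  out <- tibble(
    protein_id = id,
    pos_d = m[, 1], pos_ts1 = m[, 2], pos_ts2 = m[, 3],
    pos_c1 = m[, 4], pos_c2 = m[, 5], pos_c3 = m[, 6], pos_c4 = m[, 7],
    pos_r = m[, 8], pos_d2 = m[, 9],
    span = m[, 9] - m[, 1] + 1L
  )
  arrange(out, .data$pos_d, .data$span,
          .data$pos_ts1, .data$pos_c2, .data$pos_c3, .data$pos_c4, .data$pos_r)
}

.aux_ok <- function(ch, last_pos, aux) {
  if (is.null(aux) || nrow(aux) == 0L) return(TRUE)
  prev <- last_pos
  n <- length(ch)
  for (i in seq_len(nrow(aux))) {
    lo <- prev + aux$min_gap[i] + 1L
    hi <- min(prev + aux$max_gap[i] + 1L, n)
    if (lo > hi) return(FALSE)
    cand <- lo:hi
    cand <- cand[ch[cand] == aux$residue[i]]
    if (!length(cand)) return(FALSE)
    prev <- cand[1L]
  }
  TRUE
}

#' Scan proteins for the Fanzor/TnpB motif
#'
#' Reports every distinct anchor assignment satisfying the motif
#' specification on each input protein. Overlapping placements are possible
#' under wide spacing bounds and all are reported, sorted by
#' (`pos_d`, `span`), so results are reproducible; use [best_hit()] for a
#' single-placement summary. Positions are 1-based residue indices.
#'
#' @param prots Tibble with columns `id` and `seq` (uppercase amino-acid
#'   strings over the 20 standard letters plus `X`).
#' @param spec A [motif_spec()].
#' @return A tibble with one row per hit: `protein_id`, anchor positions
#'   `pos_d`, `pos_ts1`, `pos_ts2`, `pos_c1`..`pos_c4`, `pos_r`, `pos_d2`,
#'   and `span` (`pos_d2 - pos_d + 1`).
#' @examples
#' p <- paste0("D", strrep("A", 125), "TS", "AA", "C", "AA", "C",
#'             strrep("A", 10), "C", "AA", "C", strrep("A", 5), "RD")
#' scan_protein(tibble::tibble(id = "toy", seq = p))
#' @export
scan_protein <- function(prots, spec = motif_spec()) {
  .check_seq_tbl(prots, "prots")
  if (!inherits(spec, "motif_spec")) abort("`spec` must be a motif_spec()")
  .check_prot(prots$seq)
  bind_rows(purrr::map2(prots$id, prots$seq, .scan_protein1, spec = spec))
}

#' Select the best motif hit
#'
#' The hit with the smallest span; ties broken by smallest `pos_d`.
#'
#' @param hits A tibble of hits from [scan_protein()] (a single protein).
#' @return A one-row tibble, or a zero-row tibble if `hits` is empty.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  head(arrange(hits, .data$span, .data$pos_d), 1L)
}

#' Scan a proteome and summarise per-protein motif presence
#'
#' Batch wrapper over [scan_protein()]: one row per input protein, in input
#' order, flagging motif presence and reporting the [best_hit()] anchors.
#'
#' @inheritParams scan_protein
#' @return A tibble with `protein_id`, `has_motif`, `n_hits` and the best-hit
#'   anchor columns (`NA` when there is no hit).
#' @export
scan_proteome <- function(prots, spec = motif_spec()) {
  .check_seq_tbl(prots, "prots")
  rows <- purrr::map2(prots$id, prots$seq, function(id, seq) {
    hits <- .scan_protein1(id, seq, spec)
    b <- best_hit(hits)
    if (nrow(b) == 0L) {
      tibble(
        protein_id = id, has_motif = FALSE, n_hits = 0L,
        pos_d = NA_integer_, pos_ts1 = NA_integer_, pos_ts2 = NA_integer_,
        pos_c1 = NA_integer_, pos_c2 = NA_integer_, pos_c3 = NA_integer_,
        pos_c4 = NA_integer_, pos_r = NA_integer_, pos_d2 = NA_integer_,
        span = NA_integer_
      )
    } else {
      mutate(select(b, -"protein_id"),
             protein_id = id, has_motif = TRUE, n_hits = nrow(hits),
             .before = 1L)
    }
  })
  bind_rows(rows)
}
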