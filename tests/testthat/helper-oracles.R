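# Independent brute-force oracles and tiny sequence generators used across
# the suite. Everything here is deliberately naive (nested position loops,
# full re-counting) and shares no code with the package internals.

r_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

r_prot <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

mutate_dna <- function(x, p) {
  ch <- strsplit(x, "")[[1]]
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

rc <- function(x) {
  paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")
                   [strsplit(x, "")[[1]]])), collapse = "")
}

pair_ok <- function(a, b) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "C" && b == "G") || (a == "G" && b == "C")
}

# ---- motif scanner oracle: enumerate anchor tuples by nested loops --------

oracle_scan_protein <- function(seq, spec = motif_spec()) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hits <- NULL
  for (d in which(ch == "D")) {
    t1_range <- (d + spec$d_ts_min + 1):(d + spec$d_ts_max + 1)
    t1_range <- t1_range[t1_range >= 1 & t1_range + 1 <= n]
    for (t1 in t1_range) {
      if (!(ch[t1] %in% c("T", "S")) || !(ch[t1 + 1] %in% c("T", "S"))) next
      t2 <- t1 + 1
      c1 <- t2 + spec$post_ts_gap + 1
      if (c1 > n || ch[c1] != "C") next
      for (c2 in (c1 + spec$zf_gap12_min + 1):(c1 + spec$zf_gap12_max + 1)) {
        if (c2 > n || ch[c2] != "C") next
        for (c3 in (c2 + spec$zf_gap23_min + 1):(c2 + spec$zf_gap23_max + 1)) {
          if (c3 > n || ch[c3] != "C") next
          for (c4 in (c3 + spec$zf_gap34_min + 1):(c3 + spec$zf_gap34_max + 1)) {
            if (c4 > n || ch[c4] != "C") next
            for (r in (c4 + spec$zf_rd_min + 1):(c4 + spec$zf_rd_max + 1)) {
              if (r + 1 > n || ch[r] != "R" || ch[r + 1] != "D") next
              hits <- rbind(hits, c(d, t1, t2, c1, c2, c3, c4, r, r + 1))
            }
          }
        }
      }
    }
  }
  if (is.null(hits)) {
    return(data.frame(pos_d = integer(), pos_ts1 = integer(),
                      pos_ts2 = integer(), pos_c1 = integer(),
                      pos_c2 = integer(), pos_c3 = integer(),
                      pos_c4 = integer(), pos_r = integer(),
                      pos_d2 = integer(), span = integer()))
  }
  out <- as.data.frame(hits)
  names(out) <- c("pos_d", "pos_ts1", "pos_ts2", "pos_c1", "pos_c2",
                  "pos_c3", "pos_c4", "pos_r", "pos_d2")
  out$span <- out$pos_d2 - out$pos_d + 1
  out[order(out$pos_d, out$span, out$pos_ts1, out$pos_c2, out$pos_c3,
            out$pos_c4, out$pos_r), , drop = FALSE]
}

# ---- TIR oracle: all (left offset, right offset, arm length) triples ------

oracle_find_tirs <- function(seq, min_len = 10, max_offset = 5,
                             max_mismatch_frac = 0.2) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- NULL
  for (a in 0:max_offset) {
    for (b in 0:max_offset) {
      lmax <- (n - a - b) %/% 2
      cand <- NULL
      for (L in seq_len(lmax)) {
        mm <- 0
        for (k in 1:L) {
          if (!pair_ok(ch[a + k], ch[n - b + 1 - k])) mm <- mm + 1
        }
        first_ok <- pair_ok(ch[a + 1], ch[n - b])
        last_ok <- pair_ok(ch[a + L], ch[n - b + 1 - L])
        if (L >= min_len && mm <= floor(L * max_mismatch_frac) &&
            first_ok && last_ok) {
          score <- (L - mm) - 2 * mm
          cand <- rbind(cand, c(L, mm, score))
        }
      }
      if (is.null(cand)) next
      i <- which(cand[, 3] == max(cand[, 3]))[1]  # max score, smallest L
      rec <- c(arm_len = cand[i, 1], mm = cand[i, 2], a = a, b = b)
      if (is.null(best) ||
          rec["arm_len"] > best["arm_len"] ||
          (rec["arm_len"] == best["arm_len"] && rec["mm"] < best["mm"]) ||
          (rec["arm_len"] == best["arm_len"] && rec["mm"] == best["mm"] &&
             rec["a"] < best["a"])) {
        best <- rec
      }
    }
  }
  best
}

# ---- hairpin oracle: all (stem start, stem len, loop len) triples ---------

oracle_find_hairpins <- function(seq, wstart, wend, stem_min = 6,
                                 loop_min = 3, loop_max = 15,
                                 max_mismatches = 1) {
  ch <- strsplit(seq, "")[[1]]
  cand <- NULL
  for (i in wstart:wend) {
    for (s in stem_min:((wend - wstart + 1) %/% 2)) {
      for (l in loop_min:loop_max) {
        j <- i + 2 * s + l - 1           # span end
        if (j > wend) next
        mm <- 0
        for (k in 1:s) {
          if (!pair_ok(ch[i + s - k], ch[i + s + l - 1 + k])) mm <- mm + 1
        }
        inner_ok <- pair_ok(ch[i + s - 1], ch[i + s + l])
        outer_ok <- pair_ok(ch[i], ch[j])
        if (mm > max_mismatches || !inner_ok || !outer_ok) next
        cand <- rbind(cand, c(i, s, l, mm))
      }
    }
  }
  if (is.null(cand)) return(NULL)
  # longest admissible stem per loop placement
  loop_key <- paste(cand[, 1] + cand[, 2], cand[, 3])
  keep <- unlist(lapply(split(seq_len(nrow(cand)), loop_key), function(ix) {
    ix[which.max(cand[ix, 2])]
  }))
  cand <- cand[sort(keep), , drop = FALSE]
  # inner extendability: handled at the smaller-loop placement
  drop <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; s <- cand[r, 2]; l <- cand[r, 3]
    if (l - 2 >= loop_min && pair_ok(ch[i + s], ch[i + s + l - 1])) {
      drop[r] <- TRUE
    }
  }
  cand <- cand[!drop, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  # dominance: drop spans contained in a longer-stemmed hairpin's span
  ss <- cand[, 1]
  se <- cand[, 1] + 2 * cand[, 2] + cand[, 3] - 1
  keep <- vapply(seq_len(nrow(cand)), function(r) {
    !any(ss <= ss[r] & se >= se[r] & cand[, 2] > cand[r, 2])
  }, logical(1))
  m <- cand[keep, , drop = FALSE]
  data.frame(
    stem_left_start = m[, 1], stem_len = m[, 2], loop_len = m[, 3],
    mismatches = m[, 4]
  )[order(m[, 1], m[, 3]), , drop = FALSE]
}

# ---- TSD oracle: all (left slack, right slack, length) combinations -------

oracle_call_tsd <- function(left, right, min_len = 5, max_len = 25,
                            slack = 3) {
  nl <- nchar(left)
  nr <- nchar(right)
  best <- c(len = 0, ls = 0, rs = 0)
  for (ls in 0:slack) {
    for (rs in 0:slack) {
      for (L in seq_len(min(max_len, nl - ls, nr - rs))) {
        if (substr(left, nl - ls - L + 1, nl - ls) ==
            substr(right, rs + 1, rs + L)) {
          better <- L > best["len"] ||
            (L == best["len"] && L > 0 &&
               (ls + rs < best["ls"] + best["rs"] ||
                  (ls + rs == best["ls"] + best["rs"] && ls < best["ls"])))
          if (better) best <- c(len = L, ls = ls, rs = rs)
        }
      }
    }
  }
  if (best["len"] >= min_len) {
    list(status = "tsd", tsd_len = unname(best["len"]),
         tsd_seq = substr(left, nl - best["ls"] - best["len"] + 1,
                          nl - best["ls"]),
         ls = unname(best["ls"]), rs = unname(best["rs"]))
  } else {
    list(status = "none", tsd_len = 0, tsd_seq = "", ls = 0, rs = 0)
  }
}

# ---- alignment oracle: Gotoh affine DP, ends free in one sequence each ----

oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2,
                               end_gaps_free = TRUE) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (consuming b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (consuming a)
  H[1, 1] <- 0
  for (i in 2:(n + 1)) {
    H[i, 1] <- if (end_gaps_free) 0 else gap_open + (i - 1) * gap_extend
  }
  for (j in 2:(m + 1)) {
    H[1, j] <- if (end_gaps_free) 0 else gap_open + (j - 1) * gap_extend
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  if (end_gaps_free) {
    max(H[n + 1, ], H[, m + 1])
  } else {
    H[n + 1, m + 1]
  }
}
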