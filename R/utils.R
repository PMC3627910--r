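# Internal string helpers shared by the detectors and the simulator.
# Sequences are plain uppercase character scalars over {A,C,G,T,N}; hot loops
# work on split character vectors to avoid repeated substr() calls.

.NUC_ALPHABET <- c("A", "C", "G", "T", "N")
.PROT_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.collapse <- function(x) paste(x, collapse = "")

# complement of a split character vector; N stays N
.comp_chars <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

.revcomp1 <- function(x) {
  .collapse(rev(.comp_chars(.chars(x))))
}

.check_nuc <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGTN]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf(
      "%s %d contains a disallowed character '%s' at offset %d",
      what, i, substr(x[i], bad[i], bad[i]), bad[i]
    ))
  }
  invisible(x)
}

.check_prot <- function(x, what = "protein") {
  pat <- sprintf("[^%s]", .collapse(.PROT_ALPHABET))
  bad <- regexpr(pat, x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf(
      "%s %d contains a disallowed character '%s' at offset %d",
      what, i, substr(x[i], bad[i], bad[i]), bad[i]
    ))
  }
  invisible(x)
}

.check_seq_tbl <- function(x, arg = "seqs") {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg))
  }
  if (nrow(x) > 0 && any(!nzchar(x$seq))) {
    abort(sprintf("`%s` contains an empty sequence", arg))
  }
  invisible(x)
}

# random i.i.d. nucleotide string at a given GC fraction
.rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  .collapse(sample(names(p), n, replace = TRUE, prob = p))
}

# per-base substitution: each position flips to a different base with prob p
.mutate_seq <- function(x, p) {
  if (p <= 0 || !nzchar(x)) return(x)
  ch <- .chars(x)
  hit <- which(runif(length(ch)) < p & ch != "N")
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  .collapse(ch)
}

.t_rich_tetramers <- function() {
  # all 4-mers with at least three T's
  base <- c("A", "C", "G", "T")
  out <- "TTTT"
  for (pos in 1:4) {
    for (b in c("A", "C", "G")) {
      x <- rep("T", 4)
      x[pos] <- b
      out <- c(out, .collapse(x))
    }
  }
  unique(out)
}
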