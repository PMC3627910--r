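#' Read sequences from a FASTA file
#'
#' Reads nucleotide or protein FASTA into a tibble with one row per record,
#' in file order. Residues are folded to uppercase (soft-masking is ignored).
#' For nucleotide input the alphabet is `{A,C,G,T,N}`; characters outside it
#' are rejected unless `tolerate_n = TRUE`, in which case they are mapped to
#' `N`. For protein input the 20 amino-acid letters plus `X` are accepted and
#' stop characters (`*`) are stripped.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param tolerate_n Nucleotide only: map characters outside the alphabet to
#'   `N` instead of raising an error.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein"),
                       tolerate_n = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(tibble(id = character(), seq = character()))
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) abort(sprintf("malformed FASTA in %s: first line is not a header", path))
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  if (any(is.na(ids)) || any(!nzchar(ids))) {
    abort(sprintf("malformed FASTA header (record %d) in %s",
                  which(is.na(ids) | !nzchar(ids))[1L], path))
  }
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), .collapse, character(1))
  out <- rep("", length(ids))
  out[as.integer(names(seqs))] <- unname(seqs)
  out <- str_to_upper(gsub("\\s", "", out))
  if (alphabet == "nucleotide") {
    if (tolerate_n) out <- gsub("[^ACGTN]", "N", out) else .check_nuc(out, "record")
  } else {
    out <- gsub("*", "", out, fixed = TRUE)
    .check_prot(out, "record")
  }
  tibble(id = ids, seq = unname(out))
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces `x`
#' up to line wrapping.
#'
#' @param seqs Tibble (or data frame) with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  .check_seq_tbl(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$seq[i]
    starts <- seq(1L, max(str_length(s), 1L), by = width)
    writeLines(str_sub(s, starts, pmin(starts + width - 1L, str_length(s))), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Reverse complement of nucleotide strings over `{A,C,G,T,N}`; `N` maps to
#' `N`. An involution: `revcomp(revcomp(x))` is `x`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAAACC"))
#' @export
revcomp <- function(x) {
  .check_nuc(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.FEATURE_VOCAB <- c("tir", "hairpin", "atir", "tsd", "element", "motif_hit")

#' Write annotation records as GFF3
#'
#' Writes a tibble of annotation records to GFF3. Input coordinates are
#' 1-based inclusive (the package-wide convention), which is also the GFF3
#' convention, so `end - start + 1` equals the feature length. Records are
#' written in a deterministic order (`seq_id`, `start`, `feature`).
#'
#' @param records Tibble with columns `seq_id`, `start`, `end`, `feature` and
#'   optionally `strand` (`"+"`/`"-"`, default `"+"`), `score` (numeric or
#'   `NA`) and further columns, which become GFF3 attributes.
#' @param path Output path.
#' @param seqlens Optional named integer vector of sequence lengths; when
#'   given, intervals are checked against it and out-of-bounds records raise
#'   an error.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, path, seqlens = NULL) {
  req <- c("seq_id", "start", "end", "feature")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    abort("`records` must have columns seq_id, start, end, feature")
  }
  if (nrow(records) > 0) {
    if (!all(records$feature %in% .FEATURE_VOCAB)) {
      abort(sprintf("unknown feature term(s): %s",
                    paste(setdiff(records$feature, .FEATURE_VOCAB), collapse = ", ")))
    }
    if (any(records$start < 1L) || any(records$end < records$start)) {
      abort("invalid interval: require 1 <= start <= end")
    }
    if (!is.null(seqlens)) {
      lim <- seqlens[records$seq_id]
      if (any(is.na(lim)) || any(records$end > lim)) {
        abort("interval out of bounds of the named sequence")
      }
    }
  }
  records <- arrange(as_tibble(records), .data$seq_id, .data$start, .data$feature)
  strand <- if ("strand" %in% names(records)) records$strand else rep("+", nrow(records))
  score <- if ("score" %in% names(records)) records$score else rep(NA_real_, nrow(records))
  gr <- GenomicRanges::GRanges(
    seqnames = records$seq_id,
    ranges = IRanges::IRanges(start = records$start, end = records$end),
    strand = ifelse(is.na(strand), "+", strand)
  )
  S4Vectors::mcols(gr)$type <- records$feature
  S4Vectors::mcols(gr)$score <- score
  extra <- setdiff(names(records), c(req, "strand", "score"))
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- records[[nm]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @importFrom rlang .data
NULL
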