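# Synthetic genomes with planted elements and full ground truth.
#
# The generator emulates the insertion phenomenology of the Fanzor-carrying
# families: elements with exact terminal structures (TIRs, or Helitron1 /
# Helitron2 termini), copies that are 5'-truncated with geometric truncation
# lengths (the one-ended replication signature: intact 3' ends, ramped 5'
# coverage), variable-length TSDs duplicated from the target site, T-rich
# insertion-target preference, and post-insertion divergence as independent
# per-base substitutions on each element copy and each TSD copy. The
# background is i.i.d. with configurable GC and carries no repeats, so
# detector behaviour is isolated from background structure.

#' Specification of one simulated element family
#'
#' One row per family; combine families with [dplyr::bind_rows()]. The
#' defaults describe a young family in the regime the detectors target:
#' TSDs of variable length (7-19 bp) at most loci, frequent 5'-truncation,
#' and a few percent of sequence divergence.
#'
#' @param family_id Family label.
#' @param element_len Full element length, bp.
#' @param structure Terminal structure planted in the element: `"tir"`
#'   (reverse-complementary terminal arms), `"helitron1"` (5'-TC, CTRR-3',
#'   one 3'-subterminal hairpin), `"helitron2"` (ATIR pair plus hairpins at
#'   both ends, 5'-T start), or `"none"`.
#' @param tir_arm_len Arm length for `structure = "tir"`, bp.
#' @param copy_number Number of copies planted.
#' @param substitution_rate Per-base substitution probability applied to each
#'   element copy and each TSD copy independently after insertion.
#' @param truncation_prob Probability that a copy is 5'-truncated.
#' @param truncation_mean_frac Mean fraction of the element length removed
#'   from a truncated copy's 5' end (geometric model).
#' @param tsd_model `"none"`, `"fixed"` or `"uniform"` TSD length model.
#' @param tsd_prob Probability that a copy produces a TSD at all.
#' @param tsd_min,tsd_max TSD length (bp): the fixed length is `tsd_min`; the
#'   uniform model draws from `[tsd_min, tsd_max]`.
#' @param target_preference_prob Probability that a copy inserts immediately
#'   3' of a T-rich tetranucleotide.
#' @param gc GC fraction of the element body.
#' @return A one-row tibble.
#' @export
family_spec <- function(family_id, element_len = 2000L,
                        structure = c("tir", "helitron1", "helitron2", "none"),
                        tir_arm_len = 33L,
                        copy_number = 10L,
                        substitution_rate = 0,
                        truncation_prob = 0,
                        truncation_mean_frac = 0.3,
                        tsd_model = c("none", "fixed", "uniform"),
                        tsd_prob = 1,
                        tsd_min = 7L, tsd_max = 19L,
                        target_preference_prob = 0,
                        gc = 0.5) {
  structure <- match.arg(structure)
  tsd_model <- match.arg(tsd_model)
  probs <- c(substitution_rate, truncation_prob, tsd_prob,
             target_preference_prob)
  if (any(probs < 0 | probs > 1)) abort("family_spec: probabilities must be in [0,1]")
  if (tsd_min > tsd_max) abort("family_spec: tsd_min > tsd_max")
  if (copy_number < 0L) abort("family_spec: copy_number must be >= 0")
  tibble(
    family_id = family_id, element_len = as.integer(element_len),
    structure = structure, tir_arm_len = as.integer(tir_arm_len),
    copy_number = as.integer(copy_number),
    substitution_rate = substitution_rate,
    truncation_prob = truncation_prob,
    truncation_mean_frac = truncation_mean_frac,
    tsd_model = tsd_model, tsd_prob = tsd_prob,
    tsd_min = as.integer(tsd_min), tsd_max = as.integer(tsd_max),
    target_preference_prob = target_preference_prob,
    gc = gc
  )
}

# build one element matching `spec` (a one-row specs tibble); draws from the
# current RNG stream
.make_element1 <- function(spec) {
  n <- spec$element_len
  ch <- .chars(.rand_dna(n, spec$gc))
  if (spec$structure == "tir") {
    L <- spec$tir_arm_len
    if (n < 2L * L + 10L) abort("make_element: element too short for requested TIRs")
    ch[(n - L + 1L):n] <- .comp_chars(rev(ch[1:L]))
  } else if (spec$structure == "helitron1") {
    if (n < 100L) abort("make_element: helitron1 elements must be >= 100 bp")
    ch[1:2] <- c("T", "C")
    ch[(n - 3L):n] <- c("C", "T", sample(c("A", "G"), 2L, replace = TRUE))
    # 3'-subterminal hairpin: stem 8, loop 5, ending 10 bp before the 3' end
    stem <- .chars(.rand_dna(8L, 0.6))
    sl <- n - 30L
    ch[sl:(sl + 7L)] <- stem
    ch[(sl + 13L):(sl + 20L)] <- .comp_chars(rev(stem))
  } else if (spec$structure == "helitron2") {
    if (n < 100L) abort("make_element: helitron2 elements must be >= 100 bp")
    atir <- c("T", .chars(.rand_dna(9L, 0.6)))
    ch[1:10] <- atir                            # 5'-ATIR at the terminus
    ch[16:25] <- .comp_chars(rev(atir))         # 5' hairpin closes on the ATIR
    ch[(n - 34L):(n - 25L)] <- .comp_chars(rev(atir))  # subterminal 3'-ATIR
    stem <- .chars(.rand_dna(8L, 0.6))
    ch[(n - 23L):(n - 16L)] <- stem             # 3' hairpin, 1 bp downstream
    ch[(n - 11L):(n - 4L)] <- .comp_chars(rev(stem))
  }
  .collapse(ch)
}

.element_ok <- function(spec, seq) {
  elem <- tibble(id = spec$family_id, seq = seq)
  switch(spec$structure,
    none = TRUE,
    tir = {
      hit <- find_tirs(elem, min_len = min(spec$tir_arm_len, 10L))
      nrow(hit) == 1L && hit$arm_len == spec$tir_arm_len &&
        hit$left_offset == 0L && hit$right_offset == 0L && hit$mismatches == 0L
    },
    helitron1 = classify_helitron(elem)$verdict == "helitron1",
    helitron2 = {
      call <- classify_helitron(elem)
      call$verdict == "helitron2" && call$atir_arm_len == 10L &&
        call$atir_left_offset == 0L && call$atir_right_offset == 25L
    }
  )
}

#' Generate one element with the requested terminal structure
#'
#' Builds a random element embedding the requested structure exactly and
#' verifies it with the package's own detectors ([find_tirs()],
#' [classify_helitron()]); in the rare case a random body spoils the planted
#' structure (for example by forming a competing inverted repeat) the element
#' is redrawn, so the construction guarantee holds deterministically under a
#' fixed seed.
#'
#' @param spec A one-row tibble from [family_spec()].
#' @param seed Optional integer seed (the current RNG stream is used, and
#'   left untouched, when `NULL`).
#' @return A tibble with columns `id` (the family id) and `seq`.
#' @export
make_element <- function(spec, seed = NULL) {
  gen <- function() {
    for (i in 1:25) {
      s <- .make_element1(spec)
      if (.element_ok(spec, s)) return(s)
    }
    abort(sprintf("make_element: could not realise structure '%s' at length %d",
                  spec$structure, spec$element_len))
  }
  s <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  tibble(id = spec$family_id, seq = s)
}

.draw_tsd_len <- function(spec) {
  if (spec$tsd_model == "none" || runif(1) >= spec$tsd_prob) return(0L)
  if (spec$tsd_model == "fixed") return(spec$tsd_min)
  sample(spec$tsd_min:spec$tsd_max, 1L)
}

.draw_truncation <- function(spec) {
  if (runif(1) >= spec$truncation_prob) return(0L)
  mean_cut <- max(1, spec$truncation_mean_frac * spec$element_len)
  off <- rgeom(1L, 1 / (1 + mean_cut))
  min(off, spec$element_len - 50L)  # keep a 3' stub of at least 50 bp
}

#' Plant element copies in a random background genome
#'
#' Generates an i.i.d. background of the requested length and GC, builds one
#' master element per family ([make_element()]), and inserts copies at
#' uniformly chosen, well-separated sites. Per copy: a 5' truncation is drawn
#' (geometric length model), the TSD length is drawn from the family's TSD
#' model and the target-adjacent background bases are duplicated on both
#' sides of the copy, target-preferring copies get a T-rich tetranucleotide
#' written immediately 5' of the insertion point, and substitutions are then
#' applied to the element copy and to each TSD copy independently (the
#' background itself is untouched). Insertions never overlap or nest.
#'
#' Every structural claim in the returned truth table (coordinates, TSD
#' placement, truncation arithmetic) is verifiable on the genome string; at
#' substitution rate 0 the recorded `tsd_seq` occurs exactly at both flanks
#' of each copy.
#'
#' @param specs Tibble of family specifications ([family_spec()] rows).
#' @param genome_len Background genome length, bp.
#' @param gc Background GC fraction.
#' @param seed Integer seed; the same seed and parameters reproduce the
#'   genome and truth byte-identically.
#' @param flank_len Flank length recorded in `pre_insertion_locus` and used
#'   by [loci_from_truth()], bp.
#' @return An object of class `"simulated_genome"`: list with `genome` (a
#'   one-row tibble `id`, `seq`), `truth` (one row per planted copy:
#'   `seq_id`, `start`, `end` 1-based inclusive element coordinates,
#'   `strand`, `family_id`, `copy_id`, `truncation_offset`, `tsd_len`,
#'   `tsd_seq` as duplicated at insertion time, `target_tetranucleotide`,
#'   `pre_insertion_locus`), `seed`, and `params` echoing the configuration.
#' @export
plant_copies <- function(specs, genome_len = 100000L, gc = 0.5, seed = 1L,
                         flank_len = 60L) {
  if (!is.data.frame(specs)) {
    abort("`specs` must be a tibble of family_spec() rows")
  }
  genome_len <- as.integer(genome_len)
  flank_len <- as.integer(flank_len)
  withr::with_seed(as.integer(seed), {
    bg <- .chars(.rand_dna(genome_len, gc))
    # master element per family, then per-copy draws
    copies <- list()
    for (f in seq_len(nrow(specs))) {
      spec <- specs[f, ]
      if (spec$copy_number == 0L) next
      master <- make_element(spec)$seq
      for (k in seq_len(spec$copy_number)) {
        trunc <- .draw_truncation(spec)
        copies[[length(copies) + 1L]] <- list(
          family_id = spec$family_id,
          copy_id = sprintf("%s_%d", spec$family_id, k),
          seq = str_sub(master, trunc + 1L, spec$element_len),
          truncation_offset = as.integer(trunc),
          tsd_len = .draw_tsd_len(spec),
          prefer = runif(1) < spec$target_preference_prob,
          rate = spec$substitution_rate
        )
      }
    }
    n_copies <- length(copies)
    truth <- tibble(
      seq_id = character(), start = integer(), end = integer(),
      strand = character(), family_id = character(), copy_id = character(),
      truncation_offset = integer(), tsd_len = integer(),
      tsd_seq = character(), target_tetranucleotide = character(),
      pre_insertion_locus = character()
    )
    if (n_copies == 0L) {
      sim <- list(
        genome = tibble(id = "sim", seq = .collapse(bg)),
        truth = truth, seed = as.integer(seed),
        params = list(specs = specs, genome_len = genome_len, gc = gc,
                      flank_len = flank_len)
      )
      class(sim) <- "simulated_genome"
      return(sim)
    }
    total_inserted <- sum(purrr::map_int(copies, ~ str_length(.x$seq) + 2L * .x$tsd_len))
    if (total_inserted >= genome_len) {
      abort("plant_copies: total planted length exceeds the genome length")
    }
    max_tsd <- max(purrr::map_int(copies, "tsd_len"))
    min_sep <- 2L * flank_len + max_tsd + 10L
    lo <- flank_len + 10L
    hi <- genome_len - flank_len - max_tsd - 10L
    # uniform points with guaranteed pairwise separation: sample in the
    # reduced space and re-add fixed offsets
    avail <- (hi - lo) - (n_copies - 1L) * min_sep
    if (avail < n_copies) {
      abort("plant_copies: could not place copies without overlap; enlarge the genome")
    }
    points <- sort(sample.int(avail, n_copies)) +
      (seq_len(n_copies) - 1L) * min_sep + lo

    copies <- copies[sample.int(n_copies)]  # random copy-to-site assignment

    # target rewriting happens on the background before extraction so the
    # recorded pre-insertion locus is exactly what an empty site would show
    t_rich <- .t_rich_tetramers()
    for (i in seq_len(n_copies)) {
      if (copies[[i]]$prefer) {
        p <- points[i]
        bg[(p - 3L):p] <- .chars(sample(t_rich, 1L))
      }
    }

    pieces <- character(0)
    rows <- vector("list", n_copies)
    prev <- 0L
    at <- 0L  # length of the assembled genome so far
    for (i in seq_len(n_copies)) {
      cp <- copies[[i]]
      p <- points[i]
      tsd <- if (cp$tsd_len > 0L) .collapse(bg[(p + 1L):(p + cp$tsd_len)]) else ""
      seg <- if (p > prev) .collapse(bg[(prev + 1L):p]) else ""
      tsd_l <- .mutate_seq(tsd, cp$rate)
      tsd_r <- .mutate_seq(tsd, cp$rate)
      elem <- .mutate_seq(cp$seq, cp$rate)
      start <- at + str_length(seg) + cp$tsd_len + 1L
      end <- start + str_length(elem) - 1L
      pieces <- c(pieces, seg, tsd_l, elem, tsd_r)
      at <- end + cp$tsd_len
      prev <- p + cp$tsd_len
      rows[[i]] <- tibble(
        seq_id = "sim", start = start, end = end, strand = "+",
        family_id = cp$family_id, copy_id = cp$copy_id,
        truncation_offset = cp$truncation_offset,
        tsd_len = cp$tsd_len, tsd_seq = tsd,
        target_tetranucleotide = .collapse(bg[(p - 3L):p]),
        pre_insertion_locus =
          .collapse(bg[(p - flank_len + cp$tsd_len + 1L):(p + flank_len)])
      )
    }
    pieces <- c(pieces, .collapse(bg[(prev + 1L):genome_len]))
    sim <- list(
      genome = tibble(id = "sim", seq = .collapse(pieces)),
      truth = bind_rows(rows),
      seed = as.integer(seed),
      params = list(specs = specs, genome_len = genome_len, gc = gc,
                    flank_len = flank_len)
    )
    class(sim) <- "simulated_genome"
    sim
  })
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat(sprintf("<simulated_genome> %d bp, %d planted copies (seed %d)\n",
              str_length(x$genome$seq), nrow(x$truth), x$seed))
  invisible(x)
}

#' Extract insertion loci from a simulated genome
#'
#' Builds the [call_tsd()] input table for every planted copy: the
#' `flank_len` bases on either side of the element. With `jitter > 0` each
#' annotated boundary is independently shifted into the element by 0 to
#' `jitter` bp, mimicking the imprecise boundaries of truncated copies; a
#' caller with `slack >= jitter` can still recover the planted TSD.
#'
#' @param sim A [plant_copies()] result.
#' @param flank_len Flank length, bp (at most the simulation's `flank_len`).
#' @param jitter Maximum boundary shift, bp.
#' @return Tibble with `locus_id`, `left_flank`, `right_flank`, and the
#'   applied shifts `jitter_left`, `jitter_right`.
#' @export
loci_from_truth <- function(sim, flank_len = NULL, jitter = 0L) {
  if (!inherits(sim, "simulated_genome")) abort("`sim` must be a simulated_genome")
  flank_len <- as.integer(flank_len %||% sim$params$flank_len)
  g <- sim$genome$seq
  tr <- sim$truth
  jl <- if (jitter > 0L) sample(0:jitter, nrow(tr), replace = TRUE) else rep(0L, nrow(tr))
  jr <- if (jitter > 0L) sample(0:jitter, nrow(tr), replace = TRUE) else rep(0L, nrow(tr))
  tibble(
    locus_id = tr$copy_id,
    left_flank = str_sub(g, tr$start - flank_len + jl, tr$start - 1L + jl),
    right_flank = str_sub(g, tr$end + 1L - jr, tr$end + flank_len - jr),
    jitter_left = jl, jitter_right = jr
  )
}

#' Write the simulation ground truth as TSV
#'
#' One row per planted copy. The first three columns (`seq_id`, `start`,
#' `end`) are BED-compatible, i.e. 0-based half-open; the remaining columns
#' mirror the in-memory truth table.
#'
#' @param sim A [plant_copies()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_truth()]
#' @export
write_truth <- function(sim, path) {
  if (!inherits(sim, "simulated_genome")) abort("`sim` must be a simulated_genome")
  out <- mutate(sim$truth, start = .data$start - 1L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth TSV written by [write_truth()]
#'
#' @param path Path to the TSV.
#' @return The truth tibble with 1-based inclusive `start`/`end`.
#' @export
read_truth <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  df <- as_tibble(df)
  for (col in c("start", "end", "truncation_offset", "tsd_len")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$tsd_seq[is.na(df$tsd_seq)] <- ""
  mutate(df, start = .data$start + 1L)
}
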