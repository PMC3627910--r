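tir_construct <- function(arm_len = 20, mid_len = 100) {
  S <- r_dna(arm_len)
  mid <- strsplit(r_dna(mid_len), "")[[1]]
  # pin the first inward pair to a guaranteed mismatch so the planted arm is
  # the unique maximal one
  mid[1] <- "A"
  mid[mid_len] <- "A"
  paste0(S, paste(mid, collapse = ""), rc(S))
}

test_that("planted perfect TIRs are recovered exactly", {
  set.seed(21)
  for (i in 1:10) {
    elem <- tibble::tibble(id = "e", seq = tir_construct(20, 100))
    hit <- find_tirs(elem)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$arm_len, 20L)
    expect_equal(hit$mismatches, 0L)
    expect_equal(hit$left_offset, 0L)
    expect_equal(hit$right_offset, 0L)
    expect_equal(hit$left_start, 1L)
    expect_equal(hit$right_end, nchar(elem$seq))
  }
  expect_error(find_tirs(tibble::tibble(id = "e", seq = r_dna(50)), min_len = 3),
               "min_len")
})

test_that("TIR finder agrees with the exhaustive all-pairs oracle", {
  set.seed(22)
  n_found <- 0
  for (i in 1:60) {
    seq <- if (i %% 3 == 0) tir_construct(sample(10:16, 1), 60) else r_dna(90)
    got <- find_tirs(tibble::tibble(id = "e", seq = seq))
    exp <- oracle_find_tirs(seq)
    if (is.null(exp)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), 1L)
      expect_equal(got$arm_len, unname(as.integer(exp["arm_len"])))
      expect_equal(got$mismatches, unname(as.integer(exp["mm"])))
      expect_equal(got$left_offset, unname(as.integer(exp["a"])))
      expect_equal(got$right_offset, unname(as.integer(exp["b"])))
      n_found <- n_found + 1
    }
  }
  expect_gt(n_found, 10)  # the comparison exercised real detections
})

test_that("column-shuffled elements lose their TIRs", {
  set.seed(23)
  for (i in 1:10) {
    elem <- tir_construct(20, 100)
    shuf <- paste(sample(strsplit(elem, "")[[1]]), collapse = "")
    got <- find_tirs(tibble::tibble(id = "s", seq = shuf))
    exp <- oracle_find_tirs(shuf)
    if (is.null(exp)) expect_equal(nrow(got), 0L)
    else expect_equal(got$arm_len, unname(as.integer(exp["arm_len"])))
  }
})

test_that("TIR detection is strand-symmetric", {
  set.seed(24)
  for (i in 1:10) {
    seq <- tir_construct(15, 80)
    fwd <- find_tirs(tibble::tibble(id = "f", seq = seq))
    rev <- find_tirs(tibble::tibble(id = "r", seq = revcomp(seq)))
    n <- nchar(seq)
    expect_equal(rev$arm_len, fwd$arm_len)
    expect_equal(rev$mismatches, fwd$mismatches)
    # coordinates reflect: the left arm maps to the right arm
    expect_equal(rev$left_start, n - fwd$right_end + 1L)
    expect_equal(rev$right_end, n - fwd$left_start + 1L)
  }
})

test_that("a constructed stem-loop is found once with exact geometry", {
  hp <- find_hairpins(tibble::tibble(
    id = "h", seq = paste0("AAA", "GGGGGGG", "TTTT", "CCCCCCC", "AAA")
  ))
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$stem_len, 7L)
  expect_equal(hp$loop_len, 4L)
  expect_equal(hp$mismatches, 0L)
  expect_equal(hp$stem_left_start, 4L)
  expect_equal(hp$stem_right_end, 21L)

  expect_equal(nrow(find_hairpins(tibble::tibble(id = "a", seq = strrep("A", 60)))), 0L)
  expect_error(find_hairpins(tibble::tibble(id = "a", seq = strrep("A", 60)),
                             loop_min = 9, loop_max = 3), "loop_min")
})

test_that("hairpin finder agrees with the brute-force triple oracle", {
  set.seed(31)
  n_hp <- 0
  for (i in 1:50) {
    seq <- r_dna(80, gc = 0.5)
    if (i %% 2 == 0) {
      # plant a clean stem-loop at a random internal position
      stem <- r_dna(sample(6:9, 1))
      loop <- r_dna(sample(3:8, 1))
      at <- sample(15:40, 1)
      planted <- paste0(stem, loop, rc(stem))
      seq <- paste0(substr(seq, 1, at), planted,
                    substr(seq, at + 1, nchar(seq)))
    }
    got <- find_hairpins(tibble::tibble(id = "h", seq = seq))
    exp <- oracle_find_hairpins(seq, 1, nchar(seq))
    if (is.null(exp)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(exp))
      expect_equal(got$stem_left_start, exp$stem_left_start)
      expect_equal(got$stem_len, exp$stem_len)
      expect_equal(got$loop_len, exp$loop_len)
      expect_equal(got$mismatches, exp$mismatches)
      n_hp <- n_hp + nrow(exp)
    }
  }
  expect_gt(n_hp, 20)
})

atir_construct <- function(body_len = 300) {
  # 5'-ATIR at the terminus whose downstream complement closes a 5' hairpin,
  # the complementary 3'-ATIR subterminally, then a 3' hairpin and 25 bp to
  # the terminus
  atir <- paste0("T", r_dna(9, gc = 0.6))
  stem <- r_dna(8, gc = 0.6)
  paste0(
    atir, r_dna(5), rc(atir),            # 5' ATIR + hairpin closing on it
    r_dna(body_len),                     # body
    rc(atir),                            # 3' ATIR (right arm)
    "A", stem, r_dna(4), rc(stem),       # 3' hairpin 1 bp downstream
    r_dna(4)                             # 4 bp to the terminus
  )
}

test_that("a constructed ATIR pair is recovered with all flags set", {
  set.seed(41)
  # validated constructs: the planted pair is guaranteed to be the best one
  for (i in 1:10) {
    e <- make_element(family_spec("e", element_len = 360,
                                  structure = "helitron2", copy_number = 0))
    got <- find_atir_pair(e)
    expect_equal(nrow(got), 1L)
    expect_equal(got$arm_len, 10L)
    expect_equal(got$left_offset, 0L)
    expect_equal(got$right_offset, 25L)
    expect_equal(got$mismatches, 0L)
    expect_true(got$five_prime_ok)
    expect_true(got$three_prime_ok)
    expect_true(got$upstream_of_hairpin)
  }
  # a hand construct must always yield a qualifying pair (possibly a chance
  # arm longer than the planted one)
  for (i in 1:10) {
    got <- find_atir_pair(tibble::tibble(id = "c", seq = atir_construct()))
    if (nrow(got) == 1L) {
      expect_gte(got$arm_len, 8L)
      expect_lte(got$left_offset, 2L)
      expect_true(got$right_offset >= 15L && got$right_offset <= 40L)
    }
  }
})

test_that("an ATIR right arm outside the subterminal window disqualifies", {
  set.seed(42)
  atir <- paste0("T", r_dna(9, gc = 0.6))
  stem <- r_dna(8, gc = 0.6)
  far <- paste0(
    atir, r_dna(5), rc(atir), r_dna(300),
    rc(atir),                      # right arm now ends 60 bp from the 3' end
    "A", stem, r_dna(4), rc(stem), r_dna(39)
  )
  got <- find_atir_pair(tibble::tibble(id = "far", seq = far))
  # the planted arm no longer qualifies; only a chance arm could remain
  expect_true(nrow(got) == 0L || got$right_offset <= 40L)
})

test_that("constructed Helitron1 and Helitron2 elements classify correctly", {
  s1 <- family_spec("h1", element_len = 500, structure = "helitron1",
                    copy_number = 0)
  s2 <- family_spec("h2", element_len = 500, structure = "helitron2",
                    copy_number = 0)
  c1 <- classify_helitron(make_element(s1, seed = 7))
  expect_equal(c1$verdict, "helitron1")
  expect_true(c1$five_prime_end_match && c1$three_prime_end_match)
  expect_true(c1$three_prime_hairpin)
  expect_false(c1$atir_pair)

  c2 <- classify_helitron(make_element(s2, seed = 8))
  expect_equal(c2$verdict, "helitron2")
  expect_true(c2$atir_pair && c2$five_prime_hairpin && c2$three_prime_hairpin)

  plain <- tibble::tibble(id = "bg", seq = paste0("G", r_dna(400), "G"))
  expect_equal(classify_helitron(plain)$verdict, "unclassified")
})

test_that("simulator-generated elements classify 100% correctly at rate 0", {
  set.seed(51)
  for (cls in c("helitron1", "helitron2")) {
    elems <- dplyr::bind_rows(lapply(1:25, function(k) {
      e <- make_element(family_spec(sprintf("%s_%d", cls, k), element_len = 400,
                                    structure = cls, copy_number = 0))
      e
    }))
    calls <- classify_helitron(elems)
    expect_equal(calls$verdict, rep(cls, 25))
  }
})

test_that("the verdict is a pure function of the evidence booleans", {
  set.seed(61)
  elems <- dplyr::bind_rows(
    make_element(family_spec("a", element_len = 300, structure = "helitron1",
                             copy_number = 0)),
    make_element(family_spec("b", element_len = 300, structure = "helitron2",
                             copy_number = 0)),
    tibble::tibble(id = "c", seq = paste0("G", r_dna(300), "C"))
  )
  calls <- classify_helitron(elems)
  rederived <- ifelse(
    calls$atir_pair & calls$five_prime_hairpin & calls$three_prime_hairpin &
      substr(elems$seq, 1, 1) == "T",
    "helitron2",
    ifelse(calls$five_prime_end_match & calls$three_prime_end_match &
             calls$three_prime_hairpin & !calls$atir_pair,
           "helitron1", "unclassified")
  )
  expect_equal(calls$verdict, rederived)
})
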