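test_that("dinucleotide positions include overlapping occurrences", {
  expect_identical(find_dinucleotide_positions("AGGTAAG", "GT"), 3L)
  expect_identical(find_dinucleotide_positions("GTGT", "GT"), c(1L, 3L))
  expect_identical(find_dinucleotide_positions("", "GT"), integer())
  set.seed(301)
  for (rep in 1:3) {
    s <- rand_dna(5000, gc = 0.35)
    for (d in c("GT", "AG", "AA")) {
      expect_identical(find_dinucleotide_positions(s, d),
                       as.integer(oracle_dinuc(s, d)))
    }
  }
})

test_that("donor/acceptor pairing is greedy nearest-downstream", {
  expect_equal(pair_donor_acceptor(3L, 10L), data.frame(gt = 3L, ag = 10L))
  # AG exhausted: the GT at 5 is dropped
  expect_equal(pair_donor_acceptor(c(3L, 5L), 10L),
               data.frame(gt = 3L, ag = 10L))
  # no overlap: an AG at gt+1 cannot close the same dinucleotide
  expect_equal(nrow(pair_donor_acceptor(3L, 4L)), 0L)
  set.seed(302)
  for (rep in 1:30) {
    gt <- sort(sample(1000, sample(0:25, 1)))
    ag <- sort(sample(1000, sample(0:25, 1)))
    got <- pair_donor_acceptor(gt, ag)
    want <- oracle_pairs(gt, ag)
    expect_equal(got, want, label = paste("rep", rep))
    expect_equal(nrow(got), length(unique(got$ag)))
  }
})

test_that("no-site anchors sit at pair midpoints, shifted off GT/AG", {
  s <- "AAGTAAAAAAAGAA"   # GT at 3, AG at 11; midpoint 7
  pairs <- pair_donor_acceptor(find_dinucleotide_positions(s, "GT"),
                               find_dinucleotide_positions(s, "AG"))
  expect_identical(derive_no_site_positions(pairs, s), 7L)
  # midpoint lands on a GT: anchor shifts right by one
  s2 <- "AAGTAAGTAAAAAGAA"  # pair (3, 13), midpoint 8 is on "TA"?  check GT at 7
  gt <- find_dinucleotide_positions(s2, "GT")
  ag <- find_dinucleotide_positions(s2, "AG")
  pairs2 <- pair_donor_acceptor(gt, ag)
  anchors <- derive_no_site_positions(pairs2, s2)
  for (a in anchors) {
    expect_false(substr(s2, a, a + 1L) %in% c("GT", "AG"))
  }
  set.seed(303)
  for (rep in 1:20) {
    s <- rand_dna(2000, gc = 0.4)
    pairs <- pair_donor_acceptor(find_dinucleotide_positions(s, "GT"),
                                 find_dinucleotide_positions(s, "AG"))
    anchors <- suppressMessages(derive_no_site_positions(pairs, s))
    expect_true(all(anchors >= (pairs$gt + pairs$ag) %/% 2L))
    di <- substring(s, anchors, anchors + 1L)
    expect_false(any(di %in% c("GT", "AG")))
  }
})

test_that("window extraction centres the site and skips edges and N", {
  set.seed(304)
  s <- rand_dna(100)
  w <- extract_window(s, 30L)
  expect_identical(w, substr(s, 1, 60))
  expect_true(is.na(extract_window(s, 10L)))   # insufficient left flank
  expect_true(is.na(extract_window(s, 80L)))   # insufficient right flank
  sN <- paste0(substr(s, 1, 40), "N", substr(s, 42, 100))
  expect_true(is.na(extract_window(sN, 30L)))
})

test_that("ordinal encoding maps A,G,T,C to 1,2,3,4 and round-trips", {
  expect_identical(encode_windows("AGTC")[1, ], c(1L, 2L, 3L, 4L))
  expect_identical(encode_windows(strrep("A", 60))[1, ], rep(1L, 60))
  expect_error(encode_windows("AGNC"), "cannot encode symbol 'N'")
  set.seed(305)
  wins <- vapply(1:25, function(i) rand_dna(60), character(1))
  expect_identical(decode_windows(encode_windows(wins)), wins)
  # bijection on the alphabet
  expect_identical(decode_windows(matrix(1:4, 1)), "AGTC")
})

test_that("build_dataset emits balanced, invariant-satisfying classes", {
  set.seed(306)
  orfs <- stats::setNames(vapply(1:20, function(i) rand_dna(400, gc = 0.4),
                                 character(1)), paste0("orf", 1:20))
  wins <- build_dataset(orfs)
  expect_s3_class(wins, "splice_windows")
  expect_valid_windows(wins)
  counts <- table(wins$label)
  expect_identical(unname(counts[1]), unname(counts[2]))
  expect_identical(unname(counts[1]), unname(counts[3]))
  # classes are emitted in label order 0, 1, 2
  expect_false(is.unsorted(wins$label))
  # no GT anywhere -> no usable windows at all
  expect_error(build_dataset(c(o = strrep("AC", 200))), "no training windows")
})

test_that("window bookkeeping: k clean pairs yield 3k windows", {
  # one ORF with two well-separated GT..AG pairs, all flanks inside
  set.seed(307)
  mk_flank <- function(n) paste(sample(c("A", "C"), n, TRUE), collapse = "")
  s <- paste0(mk_flank(40), "GT", mk_flank(48), "AG",
              mk_flank(60), "GT", mk_flank(48), "AG", mk_flank(40))
  wins <- build_dataset(c(orf = s))
  expect_equal(nrow(wins), 6L)
  expect_valid_windows(wins)
})

test_that("split_dataset rounds counts, stratifies and conserves rows", {
  set.seed(308)
  wins <- random_windows(40, seed = 9)
  sp <- split_dataset(wins, train_fraction = 0.8, seed = 1)
  expect_equal(nrow(sp$train_x), 96L)   # round(0.8 * 120)
  expect_equal(nrow(sp$test_x), 24L)
  expect_equal(rowSums(sp$train_y), rep(1, 96))
  # stratification: 32/8 per class
  expect_equal(unname(colSums(sp$train_y)), rep(32, 3))
  # conservation: train + test partition the window multiset exactly
  all_rows <- sort(apply(rbind(sp$train_x, sp$test_x), 1, paste, collapse = ""))
  orig <- sort(apply(encode_windows(wins$residues), 1, paste, collapse = ""))
  expect_identical(all_rows, orig)
  # determinism and seed sensitivity
  sp2 <- split_dataset(wins, train_fraction = 0.8, seed = 1)
  expect_identical(sp$train_x, sp2$train_x)
  sp3 <- split_dataset(wins, train_fraction = 0.8, seed = 2)
  expect_false(identical(sp$train_x, sp3$train_x))
  expect_equal(dim(sp3$train_x), dim(sp$train_x))
  # tiny splits and errors
  ten <- wins[c(1:4, 41:44, 81:82), ]
  sp10 <- split_dataset(ten, 0.8, seed = 1)
  expect_equal(nrow(sp10$train_x), 8L)
  expect_equal(nrow(sp10$test_x), 2L)
  expect_error(split_dataset(wins[1:2, ], 0.8, 1), "at least 3")
})

test_that("one_hot builds valid indicator matrices", {
  y <- one_hot(c(0L, 2L, 1L))
  expect_equal(dim(y), c(3L, 3L))
  expect_equal(rowSums(y), rep(1, 3))
  expect_equal(which(y[2, ] == 1L), 3L)
  expect_error(one_hot(3L), "labels")
})
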