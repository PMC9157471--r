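test_that("candidate scanning mirrors training window geometry", {
  set.seed(401)
  flank <- function(n) paste(sample(c("A", "C"), n, TRUE), collapse = "")
  s <- c(chr = paste0(flank(39), "CGTC", flank(57)))
  cand <- scan_candidates(s)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pos, 41L)
  expect_identical(cand$type, "GT")
  expect_identical(substr(cand$residues, 30, 31), "GT")
  # GT too close to the start is skipped by the flank rule
  s2 <- c(chr = paste0(flank(4), "GT", flank(70)))
  expect_equal(nrow(scan_candidates(s2)), 0L)
  # short sequences yield no candidates
  expect_equal(nrow(scan_candidates(c(chr = "ACGTACGT"))), 0L)
})

test_that("candidate count equals flanked GT plus AG occurrences", {
  set.seed(402)
  for (rep in 1:5) {
    s <- c(chr = rand_dna(3000, gc = 0.4))
    cand <- scan_candidates(s)
    n_oracle <- 0L
    for (d in c("GT", "AG")) {
      p <- find_dinucleotide_positions(s, d)
      n_oracle <- n_oracle + sum(p >= 30L & p + 30L <= nchar(s))
    }
    expect_equal(nrow(cand), n_oracle)
  }
})

test_that("classification keeps only type-consistent argmax calls", {
  m <- cached_center_model()
  set.seed(403)
  flank <- function(n) paste(sample(c("A", "C", "T"), n, TRUE,
                                    prob = c(.41, .18, .41)), collapse = "")
  # G-free flanks with C guards: GT/AG occur only at the planted sites
  s <- c(chr = paste0(flank(59), "CGTC", flank(76), "CAGC", flank(59)))
  cand <- scan_candidates(s)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$pos, c(61L, 141L))
  calls <- classify_candidates(m, cand)
  expect_true(all(calls$probability >= 0 & calls$probability <= 1))
  expect_true(all(calls$support == 1L))
  expect_identical(calls$site_type[calls$pos == 61L], "donor")
  expect_identical(calls$site_type[calls$pos == 141L], "acceptor")
  # a GT candidate whose argmax is the acceptor class must be dropped:
  # mislabel the AG candidate as GT and vice versa
  swapped <- cand
  swapped$type <- rev(swapped$type)
  expect_equal(nrow(classify_candidates(m, swapped)), 0L)
})

test_that("intron pairing honours the length constraint", {
  calls <- data.frame(
    seq_id = "chr",
    pos = c(101L, 130L, 195L),
    site_type = c("donor", "acceptor", "acceptor"),
    probability = 1, support = 1L)
  introns <- call_introns(calls, 70, 100)
  expect_equal(nrow(introns), 1L)
  expect_equal(introns$donor_pos, 101L)
  expect_equal(introns$acceptor_pos, 195L)
  expect_equal(introns$length, 96L)       # 195 + 1 - 101 + 1
  expect_equal(introns$end, 196L)
  # donor with no acceptor in range
  none <- call_introns(calls[1:2, ], 70, 100)
  expect_equal(nrow(none), 0L)
  expect_error(call_introns(calls[c(3, 1, 2), ]), "sorted")
})

test_that("greedy pairing matches exhaustive matching on small instances", {
  set.seed(404)
  n_match <- 0L
  n_total <- 40L
  for (rep in seq_len(n_total)) {
    n_sites <- sample(4:12, 1)
    pos <- sort(sample(500, n_sites))
    type <- sample(c("donor", "acceptor"), n_sites, TRUE)
    calls <- data.frame(seq_id = "chr", pos = pos, site_type = type,
                        probability = 1, support = 1L)
    got <- call_introns(calls, 70, 100)
    best <- oracle_max_introns(pos[type == "donor"],
                               pos[type == "acceptor"], 70L, 100L)
    expect_lte(nrow(got), best)
    if (nrow(got) == best) n_match <- n_match + 1L
    expect_true(all(got$length >= 70L & got$length <= 100L))
    if (nrow(got) > 1L) {
      expect_true(all(got$start[-1L] > got$end[-nrow(got)]))
    }
  }
  expect_gte(n_match / n_total, 0.95)
})

test_that("widening the length range never loses intron calls", {
  set.seed(405)
  for (rep in 1:20) {
    pos <- sort(sample(2000, 40))
    calls <- data.frame(seq_id = "chr", pos = pos,
                        site_type = sample(c("donor", "acceptor"), 40, TRUE),
                        probability = 1, support = 1L)
    narrow <- call_introns(calls, 70, 100)
    wide <- call_introns(calls, 60, 120)
    expect_gte(nrow(wide), nrow(narrow))
  }
})

test_that("exon assembly complements introns within the gene span", {
  ex <- assemble_exons(c(1L, 300L),
                       data.frame(start = 101L, end = 196L))
  expect_equal(ex$start, c(1L, 197L))
  expect_equal(ex$end, c(100L, 300L))
  # no introns -> the span itself
  ex0 <- assemble_exons(c(5L, 50L), data.frame(start = integer(),
                                               end = integer()))
  expect_equal(ex0, data.frame(start = 5L, end = 50L, length = 46L))
  expect_error(assemble_exons(c(10L, 50L),
                              data.frame(start = 5L, end = 90L)),
               "outside gene span")
  # conservation: exon + intron lengths tile the span
  set.seed(406)
  for (rep in 1:20) {
    span <- c(1L, 3000L)
    k <- sample(1:6, 1)
    bounds <- sort(sample(2:2998, 2 * k))
    intr <- data.frame(start = bounds[seq(1, 2 * k, 2)],
                       end = bounds[seq(2, 2 * k, 2)])
    ex <- assemble_exons(span, intr)
    expect_equal(sum(ex$length) + sum(intr$end - intr$start + 1), 3000L)
    expect_lte(nrow(ex), k + 1L)
  }
})

test_that("prediction summaries match an independent recomputation", {
  ex <- data.frame(start = c(1L, 197L), end = c(100L, 300L),
                   length = c(100L, 104L))
  s <- summarize_predictions(ex, data.frame(start = 101L, end = 196L,
                                            length = 96L))
  expect_equal(s$n_exons, 2L)
  expect_equal(s$mean_exon_length, 102)
  expect_equal(s$n_introns, 1L)
  s0 <- summarize_predictions(NULL, NULL)
  expect_equal(unlist(s0), c(n_exons = 0, n_introns = 0,
                             mean_exon_length = 0, mean_intron_length = 0))
  set.seed(407)
  for (rep in 1:10) {
    lens_e <- sample(50:500, sample(1:20, 1), TRUE)
    lens_i <- sample(70:100, sample(1:20, 1), TRUE)
    got <- summarize_predictions(data.frame(length = lens_e),
                                 data.frame(length = lens_i))
    expect_equal(got$mean_exon_length, round(sum(lens_e) / length(lens_e)))
    expect_equal(got$mean_intron_length, round(sum(lens_i) / length(lens_i)))
  }
})

test_that("truth comparison metrics equal a set-intersection oracle", {
  calls <- data.frame(pos = c(10L, 20L, 30L),
                      site_type = c("donor", "donor", "acceptor"))
  truth <- list(donors = c(10L, 20L), acceptors = c(30L),
                exons = data.frame(start = 1L, end = 9L))
  ev <- evaluate_against_truth(calls, truth)
  expect_equal(ev$precision, c(1, 1))
  expect_equal(ev$recall, c(1, 1))
  # empty predictions: recall 0, precision reported 0 with a flag
  ev0 <- evaluate_against_truth(calls[0, ], truth)
  expect_equal(ev0$precision, c(0, 0))
  expect_true(all(ev0$precision_undefined))
  # random instances vs brute-force intersection
  set.seed(408)
  for (rep in 1:10) {
    pd <- sample(100, sample(0:20, 1))
    td <- sample(100, sample(1:20, 1))
    ev <- evaluate_against_truth(
      data.frame(pos = pd, site_type = rep("donor", length(pd))),
      list(donors = td, acceptors = integer(),
           exons = data.frame(start = integer(), end = integer())))
    tp <- length(intersect(pd, td))
    row <- ev[ev$category == "donor", ]
    expect_equal(row$tp, tp)
    if (length(pd) > 0) expect_equal(row$precision, tp / length(pd))
    expect_equal(row$recall, tp / length(td))
  }
  # coordinate-system mismatch is detected
  expect_error(
    evaluate_against_truth(calls, truth, seq_length = 5L), "exceed")
})

test_that("aggregation mode reports majority support for planted sites", {
  m <- cached_center_model()
  set.seed(409)
  flank <- function(n) paste(sample(c("A", "C", "T"), n, TRUE,
                                    prob = c(.41, .18, .41)), collapse = "")
  s <- c(chr = paste0(flank(69), "CGTC", flank(69)))
  cand <- scan_candidates(s)
  calls <- classify_candidates(m, cand, seq = s, aggregate = TRUE)
  if (nrow(calls) > 0L) {
    expect_true(all(calls$support >= 1L))
    expect_true(all(calls$support <= 59L))
  }
  succeed()
})
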