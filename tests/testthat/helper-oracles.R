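# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force / enumeration and never
# call the implementation paths they are used to check.

rand_dna <- function(len, gc = 0.4, n_rate = 0) {
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- sample(bases, len, replace = TRUE, prob = p)
  if (n_rate > 0) {
    idx <- which(stats::runif(len) < n_rate)
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

# Exhaustive-pair ORF oracle: tests every (ATG, stop) pair for an in-frame
# stop suffix with no internal stop. Returns the all-starts set; the default
# (maximal) set keeps, per (frame, end), the longest ORF.
oracle_orfs <- function(s, min_len, stop_set, all_starts = FALSE) {
  len <- nchar(s)
  rows <- list()
  for (off in 0:2) {
    ncod <- (len - off) %/% 3L
    if (ncod < 2L) next
    starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% stop_set
    atgs <- which(codons == "ATG")
    stops <- which(is_stop)
    for (a in atgs) {
      for (k in stops) {
        if (k <= a) next
        if (any(is_stop[a:(k - 1L)])) next
        nt <- (k - a + 1L) * 3L
        if (nt < min_len) next
        res <- substr(s, starts[a], starts[k] + 2L)
        rows[[length(rows) + 1L]] <-
          data.frame(start = starts[a], end = starts[k] + 2L, frame = off,
                     has_n = grepl("N", res, fixed = TRUE))
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(), frame = integer()))
  }
  out <- do.call(rbind, rows)
  if (!all_starts) {
    # maximality first (longest span per frame/stop), N exclusion second:
    # an N-containing maximal ORF is dropped, not replaced by a nested start
    out <- out[order(out$frame, out$end, out$start), ]
    out <- out[!duplicated(out[, c("frame", "end")]), ]
  }
  out <- out[!out$has_n, c("start", "end", "frame")]
  out <- out[order(out$start, out$frame), ]
  rownames(out) <- NULL
  out
}

# Sliding 2-mer brute-force scan.
oracle_dinuc <- function(s, d) {
  n <- nchar(s)
  if (n < 2L) return(integer())
  which(vapply(seq_len(n - 1L), function(i) substr(s, i, i + 1L) == d,
               logical(1)))
}

# Literal greedy donor/acceptor matching with an explicit consumed set.
oracle_pairs <- function(gt, ag) {
  used <- rep(FALSE, length(ag))
  res_gt <- integer()
  res_ag <- integer()
  for (g in gt) {
    cand <- which(!used & ag >= g + 2L)
    if (length(cand) == 0L) next
    j <- cand[which.min(ag[cand])]
    used[j] <- TRUE
    res_gt <- c(res_gt, g)
    res_ag <- c(res_ag, ag[j])
  }
  data.frame(gt = res_gt, ag = res_ag)
}

# Exhaustive search for the maximum number of non-overlapping donor-acceptor
# pairs with intron length (a - d + 2) in [min_i, max_i]. Only feasible for
# small instances.
oracle_max_introns <- function(donors, acceptors, min_i, max_i) {
  rec <- function(ds, as_, last_end) {
    if (length(ds) == 0L) return(0L)
    best <- rec(ds[-1L], as_, last_end)
    d <- ds[1L]
    if (d > last_end) {
      ok <- as_[(as_ - d + 2L) >= min_i & (as_ - d + 2L) <= max_i &
                  as_ > last_end]
      for (a in ok) {
        best <- max(best, 1L + rec(ds[ds > a + 1L], setdiff(as_, a), a + 1L))
      }
    }
    best
  }
  rec(sort(donors), sort(acceptors), 0L)
}

expect_valid_windows <- function(wins, window = 60L, left_flank = 29L) {
  expect_true(all(nchar(wins$residues) == window))
  ctr <- substr(wins$residues, left_flank + 1L, left_flank + 2L)
  expect_true(all(ctr[wins$label == 0L] == "GT"))
  expect_true(all(ctr[wins$label == 1L] == "AG"))
  expect_true(all(!(ctr[wins$label == 2L] %in% c("GT", "AG"))))
  expect_length(unique(table(wins$label)), 1L)
}
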