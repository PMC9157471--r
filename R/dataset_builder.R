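#' Find all (possibly overlapping) occurrences of a dinucleotide
#'
#' @param seq A single DNA string (named or not).
#' @param dinuc Two-character pattern, e.g. `"GT"` or `"AG"`.
#' @return Ascending integer vector of 1-based positions of the first base of
#'   each occurrence.
#' @examples
#' find_dinucleotide_positions("GTGT", "GT")  # 1 3
#' @export
find_dinucleotide_positions <- function(seq, dinuc) {
  stopifnot(length(seq) == 1L, nchar(dinuc) == 2L)
  s <- unname(seq)
  if (nchar(s) < 2L) return(integer())
  hits <- gregexpr(paste0("(?=", dinuc, ")"), s, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer())
  as.integer(hits)
}

#' Pair donor GT positions with downstream acceptor AG positions
#'
#' Greedy left-to-right matching: each GT takes the nearest strictly
#' downstream unconsumed AG (`ag >= gt + 2`, so the two dinucleotides do not
#' overlap); GTs with no available downstream AG are dropped. The result has
#' equal donor and acceptor counts by construction.
#'
#' @param gt_positions,ag_positions Ascending integer vectors.
#' @return Data frame with columns `gt` and `ag`, one row per pair.
#' @export
pair_donor_acceptor <- function(gt_positions, ag_positions) {
  stopifnot(!is.unsorted(gt_positions), !is.unsorted(ag_positions))
  n_ag <- length(ag_positions)
  gt_out <- integer(0)
  ag_out <- integer(0)
  j <- 1L
  for (gt in gt_positions) {
    while (j <= n_ag && ag_positions[j] < gt + 2L) j <- j + 1L
    if (j > n_ag) break
    gt_out <- c(gt_out, gt)
    ag_out <- c(ag_out, ag_positions[j])
    j <- j + 1L
  }
  data.frame(gt = gt_out, ag = ag_out)
}

#' Derive no-site anchor positions from donor/acceptor pairs
#'
#' One anchor per pair at `floor((gt + ag) / 2)`, shifted right one base at a
#' time while the dinucleotide at the anchor is GT or AG (or runs past the
#' last full dinucleotide). Pairs admitting no valid anchor inside their span
#' yield nothing (a message is emitted).
#'
#' @param pairs Data frame from [pair_donor_acceptor()].
#' @param seq The DNA string the positions refer to.
#' @return Integer vector of anchor positions (at most one per pair).
#' @export
derive_no_site_positions <- function(pairs, seq) {
  s <- unname(seq)
  len <- nchar(s)
  out <- integer(0)
  dropped <- 0L
  for (i in seq_len(nrow(pairs))) {
    anchor <- (pairs$gt[i] + pairs$ag[i]) %/% 2L
    ok <- FALSE
    while (anchor + 1L <= len && anchor <= pairs$ag[i]) {
      di <- substr(s, anchor, anchor + 1L)
      if (di != "GT" && di != "AG") { ok <- TRUE; break }
      anchor <- anchor + 1L
    }
    if (ok) out <- c(out, anchor) else dropped <- dropped + 1L
  }
  if (dropped > 0L) message(dropped, " pair(s) admitted no no-site anchor")
  out
}

#' Extract a fixed-length window centred on a site
#'
#' Returns the `window`-nt slice whose positions place the site's first base
#' at window position `left_flank + 1` (with the defaults, positions 30-31 of
#' a 60-nt window hold the dinucleotide). Windows whose flanks run off the
#' sequence, or that contain `N`, are skipped (return `NA`), never padded: the
#' ordinal encoding has no padding symbol.
#'
#' @param seq DNA string.
#' @param pos 1-based position of the site's first base.
#' @param window Window length (default 60).
#' @param left_flank Bases upstream of the site inside the window (default 29).
#' @return The window string, or `NA_character_` when skipped.
#' @export
extract_window <- function(seq, pos, window = 60L, left_flank = 29L) {
  s <- unname(seq)
  start <- pos - left_flank
  end <- start + window - 1L
  if (start < 1L || end > nchar(s)) return(NA_character_)
  w <- substr(s, start, end)
  if (grepl("N", w, fixed = TRUE)) return(NA_character_)
  w
}

.NUC <- c("A", "G", "T", "C")

#' Encode windows as ordinal integer vectors
#'
#' Positionwise map A->1, G->2, T->3, C->4 (the categorical numeric encoding
#' used throughout the package, as opposed to one-hot encoding of the bases).
#'
#' @param residues Character vector of equal-length windows over `{A,G,T,C}`.
#' @return Integer matrix, one row per window, values in 1..4.
#' @examples
#' encode_windows("AGTC")  # 1 2 3 4
#' @export
encode_windows <- function(residues) {
  if (length(residues) == 0L) return(matrix(integer(), nrow = 0))
  w <- unique(nchar(residues))
  if (length(w) != 1L) stop("windows must have equal length")
  chars <- strsplit(residues, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  enc <- match(flat, .NUC)
  if (anyNA(enc)) {
    stop("cannot encode symbol '", flat[which(is.na(enc))[1L]],
         "': alphabet is A, G, T, C")
  }
  matrix(enc, ncol = w, byrow = TRUE)
}

#' Decode ordinal integer vectors back to DNA strings
#'
#' @param x Integer matrix (or vector) with values in 1..4.
#' @return Character vector of windows.
#' @export
decode_windows <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (any(!(x %in% 1:4))) stop("encoded values must be in 1..4")
  apply(x, 1L, function(r) paste(.NUC[r], collapse = ""))
}

#' Build the three-class splice-site window dataset from ORF sequences
#'
#' For each ORF record: catalogue every GT and AG dinucleotide position, pair
#' each GT with its nearest downstream unconsumed AG (equalising donor and
#' acceptor counts), derive one no-site anchor per pair at the pair midpoint
#' (shifted off accidental GT/AG), and cut a 60-nt window around each
#' position with the site at window positions 30-31. Labels: 0 = donor (GT),
#' 1 = acceptor (AG), 2 = no-site. Classes are emitted in label order and
#' truncated to the size of the smallest class so that the three class counts
#' are equal.
#'
#' @param orf_seqs Named character vector of ORF sequences (from
#'   [extract_orf_residues()], or any DNA records).
#' @param window,left_flank Window geometry, see [extract_window()].
#' @return Data frame of class `"splice_windows"` with columns `residues`,
#'   `label`, `source_id`, `pos`, plus attributes `window` and `left_flank`.
#' @export
build_dataset <- function(orf_seqs, window = 60L, left_flank = 29L) {
  per_class <- list(`0` = list(), `1` = list(), `2` = list())
  for (id in names(orf_seqs)) {
    s <- orf_seqs[[id]]
    gt <- find_dinucleotide_positions(s, "GT")
    ag <- find_dinucleotide_positions(s, "AG")
    pairs <- pair_donor_acceptor(gt, ag)
    if (nrow(pairs) == 0L) next
    nosite <- suppressMessages(derive_no_site_positions(pairs, s))
    add <- function(positions, label) {
      if (length(positions) == 0L) return(NULL)
      res <- vapply(positions, function(p)
        extract_window(s, p, window, left_flank), character(1))
      keep <- !is.na(res)
      if (!any(keep)) return(NULL)
      data.frame(residues = res[keep], label = label, source_id = id,
                 pos = positions[keep], stringsAsFactors = FALSE)
    }
    per_class[["0"]] <- c(per_class[["0"]], list(add(pairs$gt, 0L)))
    per_class[["1"]] <- c(per_class[["1"]], list(add(pairs$ag, 1L)))
    per_class[["2"]] <- c(per_class[["2"]], list(add(nosite, 2L)))
  }
  blocks <- lapply(per_class, function(x) {
    x <- x[!vapply(x, is.null, logical(1))]
    if (length(x) == 0L) NULL else do.call(rbind, x)
  })
  n_min <- min(vapply(blocks, function(b) if (is.null(b)) 0L else nrow(b),
                      integer(1)))
  if (n_min == 0L) stop("no training windows")
  out <- do.call(rbind, lapply(blocks, function(b) b[seq_len(n_min), ]))
  rownames(out) <- NULL
  .check_window_invariants(out, window, left_flank)
  structure(out, window = window, left_flank = left_flank,
            class = c("splice_windows", "data.frame"))
}

.check_window_invariants <- function(windows, window = 60L, left_flank = 29L) {
  stopifnot(all(nchar(windows$residues) == window))
  center <- substr(windows$residues, left_flank + 1L, left_flank + 2L)
  ok <- (windows$label == 0L & center == "GT") |
        (windows$label == 1L & center == "AG") |
        (windows$label == 2L & center != "GT" & center != "AG")
  if (!all(ok)) {
    stop("window-label consistency violated for ", sum(!ok), " window(s)")
  }
  invisible(TRUE)
}

#' One-hot encode class labels
#'
#' @param labels Integer vector with values in `0:(n_classes - 1)`.
#' @param n_classes Number of classes (default 3).
#' @return Binary matrix with one 1 per row.
#' @export
one_hot <- function(labels, n_classes = 3L) {
  stopifnot(all(labels %in% 0:(n_classes - 1L)))
  m <- matrix(0L, nrow = length(labels), ncol = n_classes)
  m[cbind(seq_along(labels), labels + 1L)] <- 1L
  m
}

#' Split a window dataset into train and test partitions
#'
#' Seeded shuffle, then an 80/20 (by default) partition with
#' `n_train = round(train_fraction * n)`. With `stratified = TRUE` (default)
#' the per-class training counts are apportioned by largest remainder so that
#' they sum exactly to `n_train` while matching the class proportions.
#'
#' @param windows A `splice_windows` data frame (any data frame with
#'   `residues` and `label` columns works).
#' @param train_fraction Proportion of rows assigned to training, in (0,1).
#' @param seed Integer seed for the shuffle.
#' @param stratified Stratify the split by label (default TRUE).
#' @return An object of class `"splice_split"`: list with integer matrices
#'   `train_x`, `test_x` (n x window, values 1..4), one-hot `train_y`,
#'   `test_y`, the row metadata `train_meta`/`test_meta`, and the split
#'   parameters.
#' @export
split_dataset <- function(windows, train_fraction = 0.8, seed = 1L,
                          stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(windows)
  if (n < 3L) stop("need at least 3 examples to split")
  n_train <- round(train_fraction * n)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  if (stratified) {
    labs <- sort(unique(windows$label))
    idx_by <- lapply(labs, function(l) sample(which(windows$label == l)))
    n_k <- vapply(idx_by, length, integer(1))
    raw <- train_fraction * n_k
    base <- floor(raw)
    short <- n_train - sum(base)
    if (short > 0L) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
      base[extra] <- base[extra] + 1L
    } else if (short < 0L) {
      cut <- order(raw - base)[seq_len(-short)]
      base[cut] <- base[cut] - 1L
    }
    train_idx <- unlist(mapply(function(ix, k) ix[seq_len(k)],
                               idx_by, base, SIMPLIFY = FALSE))
    test_idx <- unlist(mapply(function(ix, k) if (k < length(ix))
      ix[(k + 1L):length(ix)] else integer(), idx_by, base, SIMPLIFY = FALSE))
    train_idx <- sample(train_idx)
    test_idx <- sample(test_idx)
  } else {
    perm <- sample(n)
    train_idx <- perm[seq_len(n_train)]
    test_idx <- perm[(n_train + 1L):n]
  }
  structure(list(
    train_x = encode_windows(windows$residues[train_idx]),
    train_y = one_hot(windows$label[train_idx]),
    test_x = encode_windows(windows$residues[test_idx]),
    test_y = one_hot(windows$label[test_idx]),
    train_meta = windows[train_idx,
                         intersect(c("label", "source_id", "pos"),
                                   names(windows)), drop = FALSE],
    test_meta = windows[test_idx,
                        intersect(c("label", "source_id", "pos"),
                                  names(windows)), drop = FALSE],
    train_fraction = train_fraction, seed = seed, stratified = stratified
  ), class = "splice_split")
}

#' @export
print.splice_split <- function(x, ...) {
  cat("splice window train/test split\n")
  cat(sprintf("  train: %d x %d   test: %d x %d  (fraction %.2f, seed %d)\n",
              nrow(x$train_x), ncol(x$train_x), nrow(x$test_x),
              ncol(x$test_x), x$train_fraction, x$seed))
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
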