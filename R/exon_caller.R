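#' Scan a sequence for candidate splice-site windows
#'
#' Builds one classification window per GT and per AG occurrence with full
#' flanks, using the same geometry as training (site's first base at window
#' position `left_flank + 1`, i.e. positions 30-31 of a 60-nt window).
#' Occurrences too close to the sequence ends, or whose window contains `N`,
#' are skipped.
#'
#' @param seq A single named DNA string.
#' @param window,left_flank Window geometry, see [extract_window()].
#' @return Data frame with columns `seq_id`, `pos`, `type` (`"GT"`/`"AG"`)
#'   and `residues`, sorted by `pos`.
#' @export
scan_candidates <- function(seq, window = 60L, left_flank = 29L) {
  stopifnot(length(seq) == 1L)
  id <- names(seq)
  if (is.null(id)) stop("sequence must be named")
  s <- unname(seq)
  empty <- data.frame(seq_id = character(), pos = integer(),
                      type = character(), residues = character(),
                      stringsAsFactors = FALSE)
  if (nchar(s) < window) return(empty)
  grab <- function(dinuc) {
    p <- find_dinucleotide_positions(s, dinuc)
    if (length(p) == 0L) return(NULL)
    res <- vapply(p, function(x) extract_window(s, x, window, left_flank),
                  character(1))
    keep <- !is.na(res)
    if (!any(keep)) return(NULL)
    data.frame(seq_id = id, pos = p[keep], type = dinuc,
               residues = res[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(grab("GT"), grab("AG"))
  if (is.null(out)) return(empty)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify candidate windows into splice-site calls
#'
#' A GT candidate becomes a donor call iff the model's argmax label is 0; an
#' AG candidate becomes an acceptor call iff the argmax label is 1; all other
#' candidates are dropped (type/label mismatches and no-site predictions).
#' Argmax ties resolve to no-site, the conservative choice.
#'
#' With `aggregate = TRUE` every stride-1 window overlapping the site (site's
#' first base at window offsets `1 .. window-1`) is classified and the label
#' is decided by majority vote; `support` records the votes for the winning
#' label. Without aggregation `support` is 1.
#'
#' @param model A trained [splice_rnn()] model.
#' @param candidates Data frame from [scan_candidates()].
#' @param seq The sequence the candidates came from (required for
#'   `aggregate = TRUE`).
#' @param aggregate Use overlapping-window majority voting (default FALSE).
#' @param window,left_flank Window geometry (must match training).
#' @return Data frame with columns `seq_id`, `pos`, `site_type`
#'   (`"donor"`/`"acceptor"`), `probability` and `support`, sorted by `pos`.
#' @export
classify_candidates <- function(model, candidates, seq = NULL,
                                aggregate = FALSE, window = 60L,
                                left_flank = 29L) {
  empty <- data.frame(seq_id = character(), pos = integer(),
                      site_type = character(), probability = numeric(),
                      support = integer(), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(empty)
  if (!aggregate) {
    p <- predict(model, candidates$residues)
    lab <- argmax_labels(p)
    keep_donor <- candidates$type == "GT" & lab == 0L
    keep_acc <- candidates$type == "AG" & lab == 1L
    keep <- keep_donor | keep_acc
    if (!any(keep)) return(empty)
    out <- data.frame(
      seq_id = candidates$seq_id[keep],
      pos = candidates$pos[keep],
      site_type = ifelse(candidates$type[keep] == "GT", "donor", "acceptor"),
      probability = p[cbind(which(keep), lab[keep] + 1L)],
      support = 1L, stringsAsFactors = FALSE)
  } else {
    if (is.null(seq)) stop("aggregate mode needs the source sequence")
    s <- unname(seq)
    rows <- vector("list", nrow(candidates))
    for (i in seq_len(nrow(candidates))) {
      pos <- candidates$pos[i]
      offs <- seq_len(window - 1L)
      starts <- pos - offs + 1L
      ok <- starts >= 1L & (starts + window - 1L) <= nchar(s)
      wins <- substring(s, starts[ok], starts[ok] + window - 1L)
      wins <- wins[!grepl("N", wins, fixed = TRUE)]
      if (length(wins) == 0L) next
      p <- predict(model, wins)
      lab <- argmax_labels(p)
      votes <- tabulate(lab + 1L, nbins = 3L)
      win_lab <- if (votes[3L] >= max(votes)) 2L else which.max(votes) - 1L
      target <- if (candidates$type[i] == "GT") 0L else 1L
      if (win_lab != target) next
      rows[[i]] <- data.frame(
        seq_id = candidates$seq_id[i], pos = pos,
        site_type = if (target == 0L) "donor" else "acceptor",
        probability = mean(p[lab == win_lab, win_lab + 1L]),
        support = votes[win_lab + 1L], stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
  }
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair donor and acceptor calls into introns under a length constraint
#'
#' Greedy left-to-right pairing: each unconsumed donor takes the nearest
#' unconsumed downstream acceptor whose implied intron length (first base of
#' GT through last base of AG, `acceptor_pos + 1 - donor_pos + 1`) lies in
#' `[min_intron, max_intron]`. Consumed sites are removed and introns never
#' overlap.
#'
#' @param calls Splice calls from [classify_candidates()], sorted by `pos`.
#' @param min_intron,max_intron Intron length bounds in nt (defaults 70 and
#'   100).
#' @return Data frame with columns `seq_id`, `donor_pos`, `acceptor_pos`,
#'   `start`, `end`, `length`, sorted and non-overlapping.
#' @export
call_introns <- function(calls, min_intron = 70L, max_intron = 100L) {
  stopifnot(min_intron >= 4L, min_intron <= max_intron)
  empty <- data.frame(seq_id = character(), donor_pos = integer(),
                      acceptor_pos = integer(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  if (is.unsorted(calls$pos)) stop("calls must be sorted by pos")
  out <- list()
  for (sid in unique(calls$seq_id)) {
    cc <- calls[calls$seq_id == sid, , drop = FALSE]
    a_pos <- cc$pos[cc$site_type == "acceptor"]
    a_used <- logical(length(a_pos))
    last_end <- 0L
    for (d in cc$pos[cc$site_type == "donor"]) {
      if (d <= last_end) next
      # implied length a - d + 2 in [min, max] => a in [d+min-2, d+max-2]
      ok <- which(!a_used & a_pos >= d + min_intron - 2L &
                    a_pos <= d + max_intron - 2L & a_pos > last_end)
      if (length(ok) == 0L) next
      j <- ok[1L]
      a_used[j] <- TRUE
      a <- a_pos[j]
      out[[length(out) + 1L]] <- data.frame(
        seq_id = sid, donor_pos = d, acceptor_pos = a,
        start = d, end = a + 1L, length = a - d + 2L,
        stringsAsFactors = FALSE)
      last_end <- a + 1L
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble exons as the complement of introns within a gene span
#'
#' @param gene_span Length-2 vector `c(start, end)`, 1-based inclusive.
#' @param introns Data frame with `start`, `end` columns: non-overlapping,
#'   sorted, fully inside the span (error otherwise).
#' @return Data frame of exons (`start`, `end`, `length`); `k` introns yield
#'   `k + 1` exons unless an intron abuts a span boundary, in which case the
#'   empty leading/trailing exon is dropped.
#' @export
assemble_exons <- function(gene_span, introns) {
  stopifnot(length(gene_span) == 2L, gene_span[1L] <= gene_span[2L])
  if (nrow(introns) == 0L) {
    return(data.frame(start = gene_span[1L], end = gene_span[2L],
                      length = gene_span[2L] - gene_span[1L] + 1L))
  }
  if (is.unsorted(introns$start, strictly = TRUE)) {
    introns <- introns[order(introns$start), , drop = FALSE]
  }
  if (any(introns$start < gene_span[1L]) || any(introns$end > gene_span[2L])) {
    stop("intron outside gene span [", gene_span[1L], ", ",
         gene_span[2L], "]")
  }
  if (nrow(introns) > 1L &&
      any(introns$start[-1L] <= introns$end[-nrow(introns)])) {
    stop("introns overlap")
  }
  starts <- c(gene_span[1L], introns$end + 1L)
  ends <- c(introns$start - 1L, gene_span[2L])
  keep <- starts <= ends
  data.frame(start = starts[keep], end = ends[keep],
             length = ends[keep] - starts[keep] + 1L)
}

#' Summarise predicted exons and introns
#'
#' Counts and arithmetic mean lengths, with means rounded to integers for
#' reporting.
#'
#' @param exons,introns Data frames with a `length` column (or `start`/`end`).
#' @return List with `n_exons`, `n_introns`, `mean_exon_length`,
#'   `mean_intron_length` (0 when empty).
#' @export
summarize_predictions <- function(exons, introns) {
  len <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(integer())
    if ("length" %in% names(df)) df$length else df$end - df$start + 1L
  }
  el <- len(exons); il <- len(introns)
  list(n_exons = length(el), n_introns = length(il),
       mean_exon_length = if (length(el)) round(mean(el)) else 0,
       mean_intron_length = if (length(il)) round(mean(il)) else 0)
}

#' Call splice structure on a sequence end-to-end
#'
#' Runs candidate scanning, classification, intron pairing under the length
#' constraint, and exon assembly. Gene spans for exon assembly default to the
#' predicted forward-strand ORF spans of the input sequence; pass `spans`
#' (data frame with `start`, `end`) to override, e.g. with annotated genes.
#' Introns falling outside every span are still reported but take no part in
#' exon assembly.
#'
#' @param model A trained [splice_rnn()] model.
#' @param seq A single named DNA string.
#' @param spans Optional data frame of gene spans (`start`, `end`).
#' @param min_intron,max_intron Intron length bounds (defaults 70, 100).
#' @param aggregate Majority-vote aggregation, see [classify_candidates()].
#' @param min_orf_length Minimum ORF length for default spans (default 150).
#' @param window,left_flank Window geometry (must match training).
#' @return List of class `"splice_structure"` with `calls`, `introns`,
#'   `exons` (with a `span` index column), `spans` and `summary`.
#' @export
call_splice_structure <- function(model, seq, spans = NULL,
                                  min_intron = 70L, max_intron = 100L,
                                  aggregate = FALSE, min_orf_length = 150L,
                                  window = 60L, left_flank = 29L) {
  cand <- scan_candidates(seq, window, left_flank)
  calls <- classify_candidates(model, cand, seq = seq, aggregate = aggregate,
                               window = window, left_flank = left_flank)
  introns <- call_introns(calls, min_intron, max_intron)
  if (is.null(spans)) {
    orfs <- scan_orfs(seq, min_orf_length = min_orf_length)
    spans <- if (nrow(orfs) == 0L) {
      data.frame(start = 1L, end = nchar(unname(seq)))
    } else {
      orfs[, c("start", "end")]
    }
  }
  exon_list <- lapply(seq_len(nrow(spans)), function(i) {
    sp <- c(spans$start[i], spans$end[i])
    inside <- introns[introns$start >= sp[1L] & introns$end <= sp[2L], ,
                      drop = FALSE]
    ex <- assemble_exons(sp, inside)
    if (nrow(ex) > 0L) ex$span <- i
    ex
  })
  exons <- do.call(rbind, exon_list)
  structure(list(calls = calls, introns = introns, exons = exons,
                 spans = spans,
                 summary = summarize_predictions(exons, introns)),
            class = "splice_structure")
}

#' @export
print.splice_structure <- function(x, ...) {
  s <- x$summary
  cat("splice structure call\n")
  cat(sprintf("  %d splice-site calls -> %d introns (mean length %d)\n",
              nrow(x$calls), s$n_introns, s$mean_intron_length))
  cat(sprintf("  %d exons over %d spans (mean length %d)\n",
              s$n_exons, nrow(x$spans), s$mean_exon_length))
  invisible(x)
}

#' Compare predictions against ground-truth annotation
#'
#' Site-level: a predicted donor/acceptor is a true positive iff its position
#' matches an annotated site exactly. Exon-level: exact `(start, end)` match.
#' Precision with zero predictions is reported as 0 with the
#' `precision_undefined` flag set.
#'
#' @param calls Splice calls (`pos`, `site_type`), e.g. from
#'   [classify_candidates()].
#' @param truth Ground truth: either a `synthetic_genome` truth list
#'   (`donors`, `acceptors`, `exons`), a [simulate_genome()] result, or a
#'   GFF3 data frame from [read_gff3()] with `intron`/`exon` features.
#' @param exons Optional predicted exons (`start`, `end`) for the exon-level
#'   row.
#' @param seq_length Optional sequence length; truth features beyond it
#'   raise a coordinate-system error.
#' @return Data frame with one row per category (`donor`, `acceptor`, and
#'   `exon` when `exons` is given): `n_pred`, `n_truth`, `tp`, `precision`,
#'   `recall`, `f1`, `precision_undefined`.
#' @export
evaluate_against_truth <- function(calls, truth, exons = NULL,
                                   seq_length = NULL) {
  if (inherits(truth, "synthetic_genome")) truth <- truth$truth
  if (is.data.frame(truth)) {
    intr <- truth[truth$type == "intron", , drop = FALSE]
    truth <- list(donors = intr$start, acceptors = intr$end - 1L,
                  exons = truth[truth$type == "exon", c("start", "end")])
  }
  if (!is.null(seq_length)) {
    hi <- max(c(truth$donors + 1L, truth$acceptors + 1L, truth$exons$end, 0L))
    if (hi > seq_length) {
      stop("truth coordinates exceed sequence length (", hi, " > ",
           seq_length, "); coordinate-system mismatch?")
    }
  }
  metric_row <- function(category, pred, tru) {
    tp <- length(intersect(pred, tru))
    undef <- length(pred) == 0L
    prec <- if (undef) 0 else tp / length(pred)
    rec <- if (length(tru) == 0L) 0 else tp / length(tru)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(category = category, n_pred = length(pred),
               n_truth = length(tru), tp = tp, precision = prec,
               recall = rec, f1 = f1, precision_undefined = undef,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    metric_row("donor", calls$pos[calls$site_type == "donor"], truth$donors),
    metric_row("acceptor", calls$pos[calls$site_type == "acceptor"],
               truth$acceptors))
  if (!is.null(exons)) {
    key <- function(df) paste(df$start, df$end, sep = "-")
    out <- rbind(out, metric_row("exon", key(exons), key(truth$exons)))
  }
  out
}
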