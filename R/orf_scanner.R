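#' Scan a sequence for open reading frames
#'
#' Finds every maximal ATG-to-first-in-frame-stop span of at least
#' `min_orf_length` nucleotides (stop codon included), in the selected reading
#' frames and strands. With `all_starts = TRUE`, nested ATGs inside a reported
#' ORF seed additional (shorter) ORFs sharing the same stop.
#'
#' Spans containing `N` are excluded: the downstream window encoding defines
#' only the four unambiguous nucleotides.
#'
#' @param seq A single named DNA string (one element of a [read_fasta()]
#'   result), or an unnamed string plus `seq_id`.
#' @param min_orf_length Minimum ORF length in nucleotides, stop codon
#'   included; must be a multiple of 3 and at least 6. Default 150, the
#'   conventional ORF-finder cutoff.
#' @param stop_set Stop codons terminating an ORF. The default
#'   `c("TAA","TAG","TGA")` is the standard set; `orf_stop_set("code4")` gives
#'   `c("TAA","TAG")` for genomes translated under genetic code 4 (TGA = Trp).
#' @param strands `"forward"` (default) or `"both"`.
#' @param all_starts Report nested ATG starts as separate ORFs (default FALSE).
#' @param seq_id Identifier used when `seq` is unnamed.
#' @return Data frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive, on the forward strand), `strand`, `frame` (0/1/2 offset on the
#'   scanned strand), `residues` (reading orientation, starts with ATG), and
#'   `length`. Sorted by `(start, frame)`.
#' @examples
#' scan_orfs(c(x = "ATGAAATAA"), min_orf_length = 9)
#' @export
scan_orfs <- function(seq, min_orf_length = 150L,
                      stop_set = c("TAA", "TAG", "TGA"),
                      strands = c("forward", "both"),
                      all_starts = FALSE, seq_id = NULL) {
  strands <- match.arg(strands)
  stopifnot(length(seq) == 1L, is.character(seq))
  if (min_orf_length < 6L || min_orf_length %% 3L != 0L) {
    stop("min_orf_length must be >= 6 and a multiple of 3")
  }
  if (length(stop_set) == 0L) stop("stop_set must be non-empty")
  stop_set <- toupper(stop_set)
  id <- if (!is.null(names(seq))) names(seq) else seq_id
  if (is.null(id)) stop("sequence must be named or seq_id given")
  s <- unname(seq)
  len <- nchar(s)

  scan_strand <- function(str, strand) {
    out <- vector("list", 3L)
    for (off in 0:2) {
      ncod <- (nchar(str) - off) %/% 3L
      if (ncod < 2L) next
      starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(str, starts, starts + 2L)
      is_stop <- codons %in% stop_set
      is_atg <- codons == "ATG"
      stop_idx <- which(is_stop)
      if (length(stop_idx) == 0L) next
      recs <- list()
      prev <- 0L
      for (k in stop_idx) {
        cand <- which(is_atg[(prev + 1L):(k - 1L)])
        if (k - 1L >= prev + 1L && length(cand) > 0L) {
          cand <- cand + prev
          if (!all_starts) cand <- cand[1L]
          for (a in cand) {
            nt_len <- (k - a + 1L) * 3L
            if (nt_len < min_orf_length) next
            s1 <- off + (a - 1L) * 3L + 1L
            e1 <- off + k * 3L
            res <- substr(str, s1, e1)
            if (grepl("N", res, fixed = TRUE)) next
            recs[[length(recs) + 1L]] <- list(s1 = s1, e1 = e1, res = res)
          }
        }
        prev <- k
      }
      if (length(recs) == 0L) next
      s1 <- vapply(recs, `[[`, integer(1), "s1")
      e1 <- vapply(recs, `[[`, integer(1), "e1")
      res <- vapply(recs, `[[`, character(1), "res")
      if (strand == "+") {
        start <- s1; end <- e1
      } else {
        start <- len - e1 + 1L; end <- len - s1 + 1L
      }
      out[[off + 1L]] <- data.frame(
        seq_id = id, start = start, end = end, strand = strand,
        frame = off, residues = res, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  }

  parts <- list(scan_strand(s, "+"))
  if (strands == "both") {
    parts <- c(parts, list(scan_strand(reverse_complement(s), "-")))
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), residues = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, parts)
  orfs$length <- orfs$end - orfs$start + 1L
  orfs <- orfs[order(orfs$start, orfs$frame), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Scan every sequence of a genome for ORFs
#'
#' @param genome Named character vector of DNA sequences.
#' @inheritParams scan_orfs
#' @return Combined ORF data frame (see [scan_orfs()]).
#' @export
scan_orfs_genome <- function(genome, min_orf_length = 150L,
                             stop_set = c("TAA", "TAG", "TGA"),
                             strands = c("forward", "both"),
                             all_starts = FALSE) {
  strands <- match.arg(strands)
  parts <- lapply(names(genome), function(id) {
    scan_orfs(genome[id], min_orf_length = min_orf_length,
              stop_set = stop_set, strands = strands,
              all_starts = all_starts)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Stop-codon presets
#'
#' @param preset `"standard"` (TAA/TAG/TGA) or `"code4"` (TAA/TAG; TGA codes
#'   tryptophan under genetic code 4, used e.g. for some protozoa).
#' @return Character vector of stop codons.
#' @export
orf_stop_set <- function(preset = c("standard", "code4")) {
  switch(match.arg(preset),
         standard = c("TAA", "TAG", "TGA"),
         code4 = c("TAA", "TAG"))
}

#' Extract ORF residues as standalone records
#'
#' Produces one named sequence per ORF, in the ORF table's order, with ids
#' `<seq_id>_ORF<k>_<start>_<end>`. Minus-strand ORFs are returned
#' reverse-complemented so every record begins with ATG.
#'
#' @param genome Named character vector of parent sequences.
#' @param orfs ORF data frame from [scan_orfs()] / [scan_orfs_genome()].
#' @return Named character vector of ORF sequences.
#' @export
extract_orf_residues <- function(genome, orfs) {
  if (nrow(orfs) == 0L) return(stats::setNames(character(), character()))
  missing <- setdiff(unique(orfs$seq_id), names(genome))
  if (length(missing) > 0L) {
    stop("ORF references unknown sequence id: ", missing[1L])
  }
  res <- character(nrow(orfs))
  k_within <- stats::ave(seq_len(nrow(orfs)), orfs$seq_id, FUN = seq_along)
  for (i in seq_len(nrow(orfs))) {
    sub <- substr(genome[[orfs$seq_id[i]]], orfs$start[i], orfs$end[i])
    res[i] <- if (orfs$strand[i] == "-") reverse_complement(sub) else sub
  }
  ids <- sprintf("%s_ORF%d_%d_%d", orfs$seq_id, k_within, orfs$start, orfs$end)
  stats::setNames(res, ids)
}
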