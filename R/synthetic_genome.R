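#' Simulate a genome with planted exon/intron gene structures
#'
#' Generates a single chromosome containing `n_genes` genes separated by
#' intergenic spacers. Each gene is an ATG-initiated, stop-codon-terminated
#' coding span built codon-aware (no in-frame stop), interrupted by introns
#' whose first two bases are forced to `GT` and last two to `AG`, with
#' lengths drawn uniformly from `intron_length_range`. Intergenic and
#' intronic ("background") bases are i.i.d. with the given GC content; coding
#' bases are drawn as random non-stop codons whose base composition follows
#' `coding_gc`. The coding/non-coding compositional contrast (default 0.55 vs
#' 0.302) is the deliberate learnable signal of this testbed: splice-site
#' consensus beyond the GT/AG dinucleotides is intentionally not modelled, so
#' flank composition is what distinguishes a true site from a background
#' GT/AG (which are retained on purpose as the negative-class challenge).
#'
#' @param n_genes Number of genes (default 50).
#' @param exon_length_range Uniform range of exon lengths in nt (default
#'   c(80, 250)).
#' @param intron_length_range Uniform range of intron lengths in nt (default
#'   c(70, 100), the intron length constraint used at calling time).
#' @param introns_per_gene Uniform integer range (default c(2, 5)).
#' @param gc_content Background (intergenic + intron interior) GC proportion
#'   (default 0.302, a compact low-GC protozoan-like genome).
#' @param coding_gc Coding (exon) GC proportion used to weight codon sampling
#'   (default 0.55).
#' @param intergenic_length_range Uniform range of spacer lengths (default
#'   c(50, 150)).
#' @param seed Integer seed; identical parameters + seed reproduce the genome
#'   exactly. The caller's RNG state is restored on exit.
#' @param seq_id Chromosome name (default "synthetic_chr1").
#' @return An object of class `"synthetic_genome"`: list with `genome` (named
#'   character vector of length 1) and `truth` (list of data frames `genes`,
#'   `exons`, `introns` and integer vectors `donors`, `acceptors`; all
#'   coordinates 1-based inclusive; donor = first base of the intron's GT,
#'   acceptor = first base of the intron's terminal AG).
#' @export
simulate_genome <- function(n_genes = 50L,
                            exon_length_range = c(80L, 250L),
                            intron_length_range = c(70L, 100L),
                            introns_per_gene = c(2L, 5L),
                            gc_content = 0.302, coding_gc = 0.55,
                            intergenic_length_range = c(50L, 150L),
                            seed = 1L, seq_id = "synthetic_chr1") {
  if (n_genes < 1L) stop("n_genes must be at least 1")
  for (r in list(exon_length_range, intron_length_range, introns_per_gene,
                 intergenic_length_range)) {
    if (length(r) != 2L || r[1L] > r[2L]) {
      stop("ranges must be length-2 with min <= max")
    }
  }
  if (intron_length_range[1L] < 4L) stop("introns need at least 4 nt (GT..AG)")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  if (coding_gc <= 0 || coding_gc >= 1) stop("coding_gc must be in (0,1)")
  if (exon_length_range[1L] < 12L) stop("exons must be at least 12 nt")

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)

  bg_prob <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
               G = gc_content / 2, T = (1 - gc_content) / 2)
  bases <- names(bg_prob)
  background <- function(n) {
    if (n <= 0L) return("")
    paste(sample(bases, n, replace = TRUE, prob = bg_prob), collapse = "")
  }
  # 61 sense codons weighted by per-base probabilities at coding_gc
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  cod_base_p <- c(A = (1 - coding_gc) / 2, C = coding_gc / 2,
                  G = coding_gc / 2, T = (1 - coding_gc) / 2)
  cod_w <- vapply(strsplit(codons, ""), function(b) prod(cod_base_p[b]),
                  numeric(1))
  coding_codons <- function(k) {
    paste(sample(codons, k, replace = TRUE, prob = cod_w), collapse = "")
  }

  pieces <- character(0)
  cursor <- 0L
  genes <- exons <- introns <- list()
  rint <- function(r) sample(seq.int(r[1L], r[2L]), 1L)

  for (g in seq_len(n_genes)) {
    spacer <- rint(intergenic_length_range)
    pieces <- c(pieces, background(spacer))
    cursor <- cursor + spacer

    n_int <- rint(introns_per_gene)
    ex_len <- vapply(seq_len(n_int + 1L), function(i)
      rint(exon_length_range), integer(1))
    total <- sum(ex_len)
    ex_len[length(ex_len)] <- ex_len[length(ex_len)] - total %% 3L
    total <- sum(ex_len)
    n_codons <- total %/% 3L
    cds <- paste0("ATG", coding_codons(n_codons - 2L),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    stopifnot(nchar(cds) == total)

    gene_start <- cursor + 1L
    ex_off <- c(0L, cumsum(ex_len))
    for (i in seq_len(n_int + 1L)) {
      ex_seq <- substr(cds, ex_off[i] + 1L, ex_off[i + 1L])
      pieces <- c(pieces, ex_seq)
      exons[[length(exons) + 1L]] <- c(g, cursor + 1L, cursor + ex_len[i])
      cursor <- cursor + ex_len[i]
      if (i <= n_int) {
        il <- rint(intron_length_range)
        intron_seq <- paste0("GT", background(il - 4L), "AG")
        pieces <- c(pieces, intron_seq)
        introns[[length(introns) + 1L]] <- c(g, cursor + 1L, cursor + il)
        cursor <- cursor + il
      }
    }
    genes[[length(genes) + 1L]] <- c(g, gene_start, cursor)
  }
  tail_spacer <- rint(intergenic_length_range)
  pieces <- c(pieces, background(tail_spacer))
  cursor <- cursor + tail_spacer

  genome <- stats::setNames(paste(pieces, collapse = ""), seq_id)
  stopifnot(nchar(genome) == cursor)
  to_df <- function(lst) {
    m <- do.call(rbind, lst)
    data.frame(gene = m[, 1L], start = m[, 2L], end = m[, 3L])
  }
  intron_df <- to_df(introns)
  truth <- list(genes = to_df(genes), exons = to_df(exons),
                introns = intron_df,
                donors = intron_df$start,
                acceptors = intron_df$end - 1L)
  structure(list(genome = genome, truth = truth,
                 params = list(n_genes = n_genes,
                               exon_length_range = exon_length_range,
                               intron_length_range = intron_length_range,
                               introns_per_gene = introns_per_gene,
                               gc_content = gc_content,
                               coding_gc = coding_gc,
                               intergenic_length_range =
                                 intergenic_length_range,
                               seed = seed)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome '%s': %d nt, %d genes, %d introns (seed %d)\n",
              names(x$genome), nchar(x$genome), nrow(x$truth$genes),
              nrow(x$truth$introns), x$params$seed))
  invisible(x)
}

#' Export a simulated genome's ground truth as GFF3
#'
#' @param sim A [simulate_genome()] result.
#' @param path Output GFF3 path.
#' @return The path, invisibly.
#' @export
write_truth_gff3 <- function(sim, path) {
  stopifnot(inherits(sim, "synthetic_genome"))
  tr <- sim$truth
  feats <- rbind(
    data.frame(type = "gene", start = tr$genes$start, end = tr$genes$end),
    data.frame(type = "exon", start = tr$exons$start, end = tr$exons$end),
    data.frame(type = "intron", start = tr$introns$start,
               end = tr$introns$end))
  write_gff3(feats, names(sim$genome), path)
}

#' Generate a balanced window dataset with planted centre dinucleotides
#'
#' The minimal model-learning testbed: flanks are i.i.d. at the given GC
#' content and the class is carried entirely by the centre dinucleotide
#' (positions 30-31 of the 60-nt window): `GT` for donors, `AG` for
#' acceptors, any other dinucleotide for no-site. Unlike [truth_windows()]
#' there is no coding/non-coding composition structure, so the centre
#' dinucleotide is the only learnable signal.
#'
#' @param n_per_class Windows per class.
#' @param gc_content Flank GC proportion (default 0.302).
#' @param window,left_flank Window geometry, see [extract_window()].
#' @param seed Integer seed.
#' @return A `splice_windows` data frame with `3 * n_per_class` rows,
#'   classes in label order.
#' @export
random_windows <- function(n_per_class, gc_content = 0.302, window = 60L,
                           left_flank = 29L, seed = 1L) {
  stopifnot(n_per_class >= 1L, window >= 4L)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  right_flank <- window - left_flank - 2L
  flanks <- function(n, len) {
    vapply(seq_len(n), function(i)
      paste(sample(bases, len, TRUE, p), collapse = ""), character(1))
  }
  centres_nosite <- function(n) {
    out <- character(0)
    while (length(out) < n) {
      c2 <- paste0(sample(bases, 2L * n, TRUE, p),
                   sample(bases, 2L * n, TRUE, p))
      c2 <- c2[!(c2 %in% c("GT", "AG"))]
      out <- c(out, c2)
    }
    out[seq_len(n)]
  }
  mk <- function(centres, label) {
    n <- length(centres)
    data.frame(
      residues = paste0(flanks(n, left_flank), centres,
                        flanks(n, right_flank)),
      label = label, source_id = "random", pos = seq_len(n),
      stringsAsFactors = FALSE)
  }
  out <- rbind(mk(rep("GT", n_per_class), 0L),
               mk(rep("AG", n_per_class), 1L),
               mk(centres_nosite(n_per_class), 2L))
  rownames(out) <- NULL
  .check_window_invariants(out, window, left_flank)
  structure(out, window = window, left_flank = left_flank,
            class = c("splice_windows", "data.frame"))
}

#' Build ground-truth training windows from a simulated genome
#'
#' The ground-truth analogue of [build_dataset()]: one donor window per truth
#' donor, one acceptor window per truth acceptor, and an equal count of
#' no-site windows anchored in truth-exon interiors (whole window inside the
#' exon, centre dinucleotide neither GT nor AG). Geometry, labels and
#' encoding match the Algorithm-1 dataset builder exactly, so the two sources
#' are interchangeable for training.
#'
#' @param sim A [simulate_genome()] result (or a list with `genome` and
#'   `truth` of the same shape).
#' @param window,left_flank Window geometry, see [extract_window()].
#' @param seed Seed for sampling no-site anchors.
#' @return A `splice_windows` data frame (see [build_dataset()]), classes in
#'   label order with equal counts.
#' @export
truth_windows <- function(sim, window = 60L, left_flank = 29L, seed = 1L) {
  genome <- sim$genome
  truth <- sim$truth
  s <- unname(genome[1L])
  id <- names(genome)[1L]
  di_at <- function(p) substring(s, p, p + 1L)
  if (!all(di_at(truth$donors) == "GT") ||
      !all(di_at(truth$acceptors) == "AG")) {
    stop("truth annotation does not match genome ",
         "(donor/acceptor dinucleotides are not GT/AG)")
  }
  grab <- function(positions, label) {
    res <- vapply(positions, function(p)
      extract_window(s, p, window, left_flank), character(1))
    keep <- !is.na(res)
    data.frame(residues = res[keep], label = label, source_id = id,
               pos = positions[keep], stringsAsFactors = FALSE)
  }
  don <- grab(truth$donors, 0L)
  acc <- grab(truth$acceptors, 1L)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  # candidate no-site anchors: window fully inside an exon, centre not GT/AG
  cand <- unlist(lapply(seq_len(nrow(truth$exons)), function(i) {
    lo <- truth$exons$start[i] + left_flank
    hi <- truth$exons$end[i] - (window - left_flank - 1L)
    if (hi < lo) return(integer())
    seq.int(lo, hi)
  }))
  cand <- cand[!(di_at(cand) %in% c("GT", "AG"))]
  n_target <- min(nrow(don), nrow(acc))
  if (length(cand) < n_target) {
    stop("not enough no-site anchor candidates in exon interiors")
  }
  nos <- grab(sort(sample(cand, n_target)), 2L)
  n_min <- min(nrow(don), nrow(acc), nrow(nos))
  if (n_min == 0L) stop("no training windows")
  out <- rbind(don[seq_len(n_min), ], acc[seq_len(n_min), ],
               nos[seq_len(n_min), ])
  rownames(out) <- NULL
  .check_window_invariants(out, window, left_flank)
  structure(out, window = window, left_flank = left_flank,
            class = c("splice_windows", "data.frame"))
}
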