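#' Read genomic DNA sequences from a FASTA file
#'
#' Reads one or more DNA records and normalises them for downstream scanning:
#' residues are uppercased, RNA `U` is converted to `T`, and IUPAC ambiguity
#' codes other than `N` are collapsed to `N` (with a warning). Characters
#' outside the IUPAC nucleotide alphabet abort with an error naming the record
#' and the first offending position.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A named character vector, one element per record in file order.
#'   Names are the record identifiers (first whitespace-delimited token of the
#'   header); values are uppercase strings over `{A,C,G,T,N}`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("empty sequence identifier in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1L])
  }
  res <- toupper(as.character(set))
  res <- chartr("U", "T", res)
  # IUPAC ambiguity codes other than N are not representable in the 4-symbol
  # ordinal encoding; collapse them to N so downstream stages skip them.
  ambig <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  has_ambig <- grepl(paste0("[", paste(ambig, collapse = ""), "]"), res)
  if (any(has_ambig)) {
    warning("ambiguity codes in record(s) ",
            paste(ids[has_ambig], collapse = ", "), " mapped to N")
    res <- chartr(paste(ambig, collapse = ""),
                  strrep("N", length(ambig)), res)
  }
  bad <- regexpr("[^ACGTN]", res)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("invalid character '", substr(res[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i])
  }
  stats::setNames(res, ids)
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences (as returned by
#'   [read_fasta()]).
#' @param path Output file path.
#' @param width Line-wrap width in columns (default 60).
#' @return The output path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (length(seqs) == 0L) stop("no sequences to write")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write exon/intron calls to a GFF3 file
#'
#' Emits 1-based inclusive coordinates (GFF3 convention). The score column
#' carries the call's support fraction when a `score` column is present,
#' otherwise `.`. Features are sorted by start position.
#'
#' @param features A data frame with columns `type` (values `"exon"`,
#'   `"intron"`, `"gene"`, `"donor"` or `"acceptor"`), `start`, `end`, and
#'   optionally `score` and `strand`.
#' @param seq_id Sequence identifier for column 1.
#' @param path Output file path.
#' @return The output path, invisibly.
#' @export
write_gff3 <- function(features, seq_id, path) {
  stopifnot(is.data.frame(features))
  if (nrow(features) > 0L) {
    if (!all(c("type", "start", "end") %in% names(features))) {
      stop("features need columns type, start, end")
    }
    if (any(features$start > features$end)) {
      bad <- which(features$start > features$end)[1L]
      stop("feature ", bad, " has start > end (", features$start[bad], " > ",
           features$end[bad], ")")
    }
    if (any(features$start < 1L)) stop("GFF3 coordinates are 1-based")
    features <- features[order(features$start, features$end), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = seq_id,
      ranges = IRanges::IRanges(start = features$start, end = features$end),
      strand = if ("strand" %in% names(features)) features$strand else "+"
    )
    gr$type <- features$type
    gr$source <- "spliceRNN"
    if ("score" %in% names(features)) gr$score <- features$score
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read features from a GFF3 file
#'
#' Thin wrapper over [rtracklayer::import()] returning a plain data frame in
#' the 1-based inclusive coordinates used throughout the package.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `seq_id`, `type`, `start`, `end`, `strand`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Reverse complement of each element.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
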