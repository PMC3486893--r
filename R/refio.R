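#' Construct a circular reference genome
#'
#' A circular reference is an immutable nucleotide sequence over `{A,C,G,T}`
#' with 1-based, modular position arithmetic: position `p` and `p + L` refer
#' to the same base, matching the rCRS numbering convention used for the
#' human mitochondrial genome.
#'
#' @param seq Nucleotide string; coerced to upper case. Ambiguity codes are
#'   rejected because the downstream calling model has no semantics for them.
#' @param name Text label for the sequence.
#' @return An object of class `circular_reference` with fields `name`, `seq`
#'   and `length`.
#' @export
circular_reference <- function(seq, name = "ref") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("reference sequence is empty")
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    stop("reference contains non-ACGT characters: ", paste(bad, collapse = ", "))
  }
  structure(
    list(name = as.character(name), seq = seq, length = nchar(seq)),
    class = "circular_reference"
  )
}

#' @export
print.circular_reference <- function(x, ...) {
  cat(sprintf(
    "<circular_reference> %s: %d bp (circular)\n  %s%s\n",
    x$name, x$length,
    substr(x$seq, 1, min(60, x$length)),
    if (x$length > 60) "..." else ""
  ))
  invisible(x)
}

#' Load a single-record FASTA file as a circular reference
#'
#' @param path Path to a FASTA file holding exactly one sequence.
#' @return A [circular_reference()].
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: expected exactly one sequence")
  if (length(set) > 1L) stop("expected exactly one sequence, found ", length(set))
  circular_reference(as.character(set[[1]]), name = names(set)[1])
}

#' Extract a subsequence with wrap-around
#'
#' Reads `length` bases forward from `start`, wrapping past position `L`
#' back to position 1.
#'
#' @param ref A [circular_reference()].
#' @param start 1-based start position in `1..L`.
#' @param length Number of bases to read (may exceed `L`; the sequence then
#'   repeats).
#' @return A nucleotide string of `length` bases.
#' @export
circular_subseq <- function(ref, start, length) {
  stopifnot(inherits(ref, "circular_reference"))
  if (length < 0) stop("length must be >= 0")
  if (length == 0) return("")
  L <- ref$length
  start <- ((start - 1) %% L) + 1
  idx <- ((start - 1 + seq_len(length) - 1) %% L) + 1
  paste(strsplit(ref$seq, "", fixed = TRUE)[[1]][idx], collapse = "")
}

# Per-position homopolymer run lengths, runs computed circularly.
# Returns an integer vector of length L.
hp_run_lengths <- function(ref) {
  stopifnot(inherits(ref, "circular_reference"))
  b <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  L <- length(b)
  if (length(unique(b)) == 1L) return(rep(L, L))
  r <- rle(b)
  len <- rep(r$lengths, r$lengths)
  # merge the first and last runs when they share a base (run wraps the origin)
  if (b[1] == b[L]) {
    k <- r$lengths[1] + r$lengths[length(r$lengths)]
    len[seq_len(r$lengths[1])] <- k
    len[(L - r$lengths[length(r$lengths)] + 1):L] <- k
  }
  len
}

#' Homopolymer run length at a position
#'
#' Length of the maximal run of identical bases containing `pos`, computed
#' circularly (a run spanning the origin is counted as one run, capped at
#' the genome length).
#'
#' @param ref A [circular_reference()].
#' @param pos Position(s), 1-based; reduced modulo the genome length.
#' @return Integer vector of run lengths, one per input position.
#' @export
hp_run_length <- function(ref, pos) {
  len <- hp_run_lengths(ref)
  len[((pos - 1) %% ref$length) + 1]
}

# 1-based ids of homopolymer runs (circular); companion to hp_run_lengths().
# Positions in the same maximal run share an id.
hp_run_ids <- function(ref) {
  b <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  L <- length(b)
  if (length(unique(b)) == 1L) return(rep(1L, L))
  r <- rle(b)
  id <- rep(seq_along(r$lengths), r$lengths)
  if (b[1] == b[L]) id[id == max(id)] <- 1L
  id
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Order and ids are preserved. Quality strings are parsed but ignored:
#' the calling model downstream is deliberately quality-score free. Reads
#' containing `N` are retained here; removing them is the job of the read
#' filters, not of I/O.
#'
#' @param path Path to the read file.
#' @param format `"fasta"` or `"fastq"`; guessed from the file extension when
#'   omitted.
#' @return A tibble with columns `id` and `bases`.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  set <- Biostrings::readBStringSet(path, format = format)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate read ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tibble::tibble(id = ids, bases = unname(toupper(as.character(set))))
}

#' Write reads to FASTA or FASTQ
#'
#' FASTQ output carries a constant quality character (`I`), since no stage of
#' the pipeline consumes quality scores.
#'
#' @param reads Tibble with columns `id`, `bases`.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(rbind(paste0(">", reads$id), reads$bases), path)
  } else {
    writeLines(rbind(
      paste0("@", reads$id), reads$bases, "+",
      vapply(nchar(reads$bases), function(n) strrep("I", n), character(1))
    ), path)
  }
  invisible(path)
}

#' Read an amplicon definition table
#'
#' Four tab-separated columns: `id`, `fwd_primer`, `rev_primer` and `span`
#' written as `"start-end"` (1-based inclusive; `start > end` means the
#' amplicon wraps through the origin). `fwd_primer` is given on the L-strand;
#' `rev_primer` is the reverse-strand oligo (the reverse complement of the
#' reference at the 3' span boundary).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `fwd_primer`, `rev_primer`, `start`,
#'   `end`.
#' @export
read_amplicons <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "fwd_primer", "rev_primer", "span") %in% names(df)))
  parts <- strsplit(df$span, "-", fixed = TRUE)
  tibble::tibble(
    id = as.character(df$id),
    fwd_primer = toupper(df$fwd_primer),
    rev_primer = toupper(df$rev_primer),
    start = as.integer(vapply(parts, `[`, "", 1L)),
    end = as.integer(vapply(parts, `[`, "", 2L))
  )
}

#' Positions covered by a circular interval
#'
#' @param start,end 1-based inclusive bounds; `start > end` wraps the origin.
#' @param L Genome length.
#' @return Integer vector of covered positions.
#' @export
circular_positions <- function(start, end, L) {
  if (start <= end) start:end else c(start:L, 1:end)
}

# length of a circular interval
circular_span_length <- function(start, end, L) {
  if (start <= end) end - start + 1L else L - start + 1L + end
}

#' Reverse complement of plain nucleotide strings
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}
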