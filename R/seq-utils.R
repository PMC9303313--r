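#' Normalize a DNA/RNA string to the DNA alphabet
#'
#' Uppercases and converts U to T. Any other non-ACGT character is an
#' error: ambiguity codes are not supported anywhere in the pipeline.
#'
#' @param seq character vector of sequences.
#' @return character vector over A/C/G/T.
#' @export
normalize_dna <- function(seq) {
  out <- chartr("u", "t", toupper(seq))
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGT]", out)
  if (any(bad)) {
    abort(paste0("Non-ACGT character in sequence: ",
                 paste(head(out[bad], 3), collapse = ", ")),
          class = "gapmertox_alphabet_error")
  }
  out
}

#' Reverse complement of a DNA string
#'
#' ASO:RNA hybridization has a fixed orientation, so complementary regions
#' are always searched as the reverse complement of the ASO along the
#' transcript sense strand; this is the primitive behind that.
#'
#' @param seq character vector of DNA strings (A/C/G/T; U accepted and
#'   normalized to T).
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("GTTATGCCACCCTA")  # "TAGGGTGGCATAAC"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_dna(seq)
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    comp <- chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Count (possibly overlapping) motif occurrences
#'
#' Counts every start offset at which a motif matches, so overlapping
#' copies such as the two TGC in "TGCTGC" both count. This is the counting
#' convention behind the TGC/TCC hepatotoxicity-motif columns.
#'
#' @param seq a single DNA string.
#' @param motifs character vector of motifs (default the hepatotoxicity
#'   consensus motifs TGC and TCC). Longer user-supplied lists, e.g.
#'   dinucleotide motif sets, work the same way.
#' @return named integer vector, one count per motif; a motif absent from
#'   `seq` counts 0.
#' @examples
#' count_motifs("GTTATGCCACCCTA")            # TGC 1, TCC 0
#' count_motifs("TGCTGC", "TGC")             # 2
#' @export
count_motifs <- function(seq, motifs = c("TGC", "TCC")) {
  seq <- normalize_dna(seq)
  if (length(seq) != 1L) abort("`seq` must be a single string.")
  motifs <- normalize_dna(motifs)
  if (length(motifs) == 0L || any(nchar(motifs) == 0L)) {
    abort("Motifs must be non-empty strings.")
  }
  n <- nchar(seq)
  counts <- vapply(motifs, function(m) {
    k <- nchar(m)
    if (k > n) return(0L)
    starts <- seq_len(n - k + 1L)
    sum(substring(seq, starts, starts + k - 1L) == m)
  }, integer(1))
  names(counts) <- motifs
  counts
}

#' Read a transcriptome (or candidate) FASTA into a named character vector
#'
#' @param path FASTA file. U is normalized to T.
#' @return named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(normalize_dna(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of DNA strings.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a transcript-to-gene mapping TSV
#'
#' Two columns, `transcript_id` and `gene_id` (header optional if the
#' columns come in that order).
#'
#' @param path TSV file.
#' @return tibble with columns `transcript_id`, `gene_id`.
#' @export
read_tx2gene <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% names(tab))) {
    names(tab)[1:2] <- c("transcript_id", "gene_id")
  }
  tibble::as_tibble(tab[, c("transcript_id", "gene_id")])
}
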