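# Plain-text I/O for reads and tag counts.

#' Read raw reads from disk
#'
#' Accepts plain text (one read per line), FASTA, or FASTQ (detected from
#' the first character unless `format` is given).
#'
#' @param path File path.
#' @param format `"auto"`, `"lines"`, `"fasta"` or `"fastq"`.
#' @return Character vector of uppercase reads.
#' @export
read_reads <- function(path, format = c("auto", "lines", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    format <- switch(first, ">" = "fasta", "@" = "fastq", "lines")
  }
  reads <- switch(
    format,
    lines = readLines(path),
    fasta = unname(as.character(Biostrings::readDNAStringSet(path))),
    fastq = {
      lines <- readLines(path)
      lines[seq(2L, length(lines), by = 4L)]
    }
  )
  toupper(unname(reads))
}

#' Write / read clean tag counts as TSV
#'
#' `tag_sequence<TAB>count`, sorted by descending count.
#'
#' @param library A `tag_library` (write) or file path (read).
#' @param path File path.
#' @param library_id Label for the reconstructed library.
#' @return The path (write) or a `tag_library` rebuilt with
#'   [tag_library_from_counts()] (read).
#' @export
write_tag_counts <- function(library, path) {
  stopifnot(inherits(library, "tag_library"))
  readr::write_tsv(library$tag_counts, path)
  invisible(path)
}

#' @rdname write_tag_counts
#' @export
read_tag_counts <- function(path, library_id = "L1") {
  tc <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(tag = "c", count = "i"))
  tag_library_from_counts(tc, library_id = library_id)
}
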