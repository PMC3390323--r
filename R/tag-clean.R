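#' Clean raw 35-bp reads into 21-bp tags
#'
#' Applies the standard DGE tag-cleaning rules, in order: (1) trim the 3'
#' adaptor by keeping the first 21 bases; (2) drop empty reads (adaptor
#' sequence with no tag); (3) drop tags containing `N`; (4) drop tags that
#' are not exactly 21 bp after trimming; (5) drop tags whose trimmed prefix
#' lacks the CATG anchor (`no_anchor`, kept as its own ledger entry so the
#' downstream unknown-tag accounting stays clean); (6) aggregate identical
#' tags to counts and drop copy-number-1 tags (likely sequencing error).
#' What survives are the clean tags.
#'
#' @param reads Character vector of uppercase reads (nucleotides and `N`).
#' @param library_id Label carried through to summaries.
#' @param adaptor Adaptor sequence used to recognise empty reads.
#' @param min_count Minimum copy number of a clean tag (default 2).
#' @return An object of class `tag_library`: a list with `library_id`,
#'   `tag_counts` (tibble `tag`, `count`, sorted by descending count),
#'   `raw_total`, `raw_distinct`, `clean_total`, `distinct_count`, and
#'   `ledger` -- a named integer vector of reads removed per rule
#'   (`empty`, `n_base`, `bad_length`, `no_anchor`, `singleton`), disjoint
#'   and exhaustive so `raw_total = clean_total + sum(ledger)`.
#' @export
#' @examples
#' clean_reads(rep(paste0("CATG", strrep("A", 17), strrep("T", 14)), 3))
clean_reads <- function(reads, library_id = "L1", adaptor = ADAPTOR_14,
                        min_count = 2L) {
  if (length(reads) > 0 && (!is.character(reads) || anyNA(reads))) {
    abort("`reads` must be a character vector without NA.")
  }
  ledger <- c(empty = 0L, n_base = 0L, bad_length = 0L, no_anchor = 0L,
              singleton = 0L)
  raw_total <- length(reads)
  raw_distinct <- dplyr::n_distinct(reads)

  tags <- substr(reads, 1L, TAG_WIDTH)

  is_empty <- startsWith(reads, adaptor)
  ledger[["empty"]] <- sum(is_empty)
  tags <- tags[!is_empty]

  has_n <- stringr::str_detect(tags, stringr::fixed("N"))
  ledger[["n_base"]] <- sum(has_n)
  tags <- tags[!has_n]

  bad_len <- nchar(tags) != TAG_WIDTH
  ledger[["bad_length"]] <- sum(bad_len)
  tags <- tags[!bad_len]

  no_anchor <- !startsWith(tags, NLAIII_ANCHOR)
  ledger[["no_anchor"]] <- sum(no_anchor)
  tags <- tags[!no_anchor]

  if (length(tags) > 0) {
    tab <- table(tags)
    singles <- tab < min_count
    ledger[["singleton"]] <- sum(tab[singles])
    tab <- tab[!singles]
    tag_counts <- tibble(tag = names(tab), count = as.integer(tab)) |>
      arrange(desc(.data$count), .data$tag)
  } else {
    tag_counts <- tibble(tag = character(0), count = integer(0))
  }

  structure(
    list(
      library_id = library_id,
      tag_counts = tag_counts,
      raw_total = raw_total,
      raw_distinct = raw_distinct,
      clean_total = sum(tag_counts$count),
      distinct_count = nrow(tag_counts),
      ledger = ledger
    ),
    class = "tag_library"
  )
}

#' Build a tag library directly from tag counts
#'
#' For inputs already aggregated to `tag count` pairs (the usual
#' distribution format for DGE data). The same cleaning rules apply except
#' adaptor trimming: counts below `min_count`, tags with `N`, wrong length
#' or missing anchor are dropped into the ledger (weighted by count).
#'
#' @param tag_counts Tibble/data frame with `tag` and `count` columns.
#' @inheritParams clean_reads
#' @return A `tag_library`.
#' @export
tag_library_from_counts <- function(tag_counts, library_id = "L1",
                                    min_count = 2L) {
  stopifnot(all(c("tag", "count") %in% names(tag_counts)))
  assert_counts(tag_counts$count, "count")
  tc <- as_tibble(tag_counts) |>
    group_by(.data$tag) |>
    summarise(count = as.integer(sum(.data$count)), .groups = "drop")
  raw_total <- sum(tc$count)
  raw_distinct <- nrow(tc)
  bad_n <- stringr::str_detect(tc$tag, stringr::fixed("N"))
  bad_len <- nchar(tc$tag) != TAG_WIDTH
  bad_anchor <- !startsWith(tc$tag, NLAIII_ANCHOR)
  ledger <- c(
    empty = 0L,
    n_base = sum(tc$count[bad_n]),
    bad_length = sum(tc$count[bad_len & !bad_n]),
    no_anchor = sum(tc$count[bad_anchor & !bad_len & !bad_n]),
    singleton = 0L
  )
  tc <- tc[!(bad_n | bad_len | bad_anchor), ]
  singles <- tc$count < min_count
  ledger[["singleton"]] <- sum(tc$count[singles])
  tc <- tc[!singles, ] |> arrange(desc(.data$count), .data$tag)
  structure(
    list(
      library_id = library_id, tag_counts = tc, raw_total = raw_total,
      raw_distinct = raw_distinct, clean_total = sum(tc$count),
      distinct_count = nrow(tc), ledger = ledger
    ),
    class = "tag_library"
  )
}

#' One-row summary of a cleaned tag library
#'
#' The per-library accounting row: raw totals, clean totals and distinct
#' counts, plus the removal ledger.
#'
#' @param library A `tag_library` from [clean_reads()].
#' @return A one-row tibble.
#' @export
library_summary <- function(library) {
  stopifnot(inherits(library, "tag_library"))
  bind_rows(tibble(
    library_id = library$library_id,
    raw_total = library$raw_total,
    raw_distinct = library$raw_distinct,
    clean_total = library$clean_total,
    distinct_count = library$distinct_count,
    removed_total = sum(library$ledger)
  ))
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf(
    "<tag_library %s> raw %d -> clean %d (%d distinct); removed: %s\n",
    x$library_id, x$raw_total, x$clean_total, x$distinct_count,
    paste(names(x$ledger), x$ledger, sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tag_library <- function(x, ...) {
  mutate(x$tag_counts, library_id = x$library_id, .before = 1)
}

#' @exportS3Method generics::glance
glance.tag_library <- function(x, ...) {
  library_summary(x)
}
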