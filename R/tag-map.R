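# Tag-to-gene assignment against the virtual CATG+17 index.

MAP_CATEGORIES <- c("gene_unambiguous", "gene_ambiguous", "mitochondrion",
                    "chloroplast", "genome", "unknown")

# All 21-mers at Hamming distance 1 from `tags` whose mismatch lies in the
# 17-bp variable region (positions 5..21); the CATG anchor is an enzymatic
# constant and must match exactly. Returns a character matrix with one row
# per tag; identity "variants" are NA.
one_mismatch_variants <- function(tags) {
  n <- length(tags)
  cols <- vector("list", 4L * (TAG_WIDTH - 4L))
  j <- 0L
  for (pos in 5:TAG_WIDTH) {
    pre <- substr(tags, 1L, pos - 1L)
    cur <- substr(tags, pos, pos)
    post <- substr(tags, pos + 1L, TAG_WIDTH)
    for (b in DNA_BASES) {
      var <- paste0(pre, b, post)
      var[cur == b] <- NA_character_
      j <- j + 1L
      cols[[j]] <- var
    }
  }
  matrix(unlist(cols), nrow = n)
}

#' Map clean tags to the virtual tag index
#'
#' Assigns every distinct clean tag to a category by a tiered search.
#' Within each compartment an exact match beats a 1-mismatch match
#' (mismatches are allowed only in the 17-bp variable region, never in the
#' CATG anchor), and compartments are tried in the order gene >
#' mitochondrion > chloroplast > genome; tags hitting nothing are
#' `unknown`. A tag whose best gene-tier hits name a single gene (either
#' strand, possibly several sites of that gene) is `gene_unambiguous`;
#' hits spread over several genes are `gene_ambiguous` and excluded from
#' per-gene counts. The category totals partition the library's clean
#' totals exactly, for both tag mass and distinct tags.
#'
#' @param library A `tag_library` from [clean_reads()].
#' @param index A `tag_index` from [build_tag_index()].
#' @return An object of class `mapping_result`: a list with `assignments`
#'   (tibble `tag`, `count`, `category`, `match_type` in
#'   exact/mismatch/none, `gene_id`, `strand`), `gene_counts` (tibble
#'   `gene_id`, `sense_count`, `antisense_count` over unambiguous tags),
#'   `category_summary` (tibble `category`, `total`, `distinct`),
#'   `library_id` and `clean_total`.
#' @export
map_tags <- function(library, index) {
  stopifnot(inherits(library, "tag_library"))
  tags <- library$tag_counts$tag
  counts <- library$tag_counts$count
  if (any(nchar(tags) != TAG_WIDTH)) {
    abort("All tags must be exactly 21 bp; re-run cleaning.")
  }
  idx <- as_tibble(index)
  entry_split <- split(seq_len(nrow(idx)), idx$tag)
  keys <- names(entry_split)
  comp <- idx$compartment
  gid <- idx$gene_id
  strd <- idx$strand

  n <- length(tags)
  category <- rep("unknown", n)
  match_type <- rep("none", n)
  gene_id <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)

  classify_gene <- function(rows) {
    ids <- unique(gid[rows])
    if (length(ids) == 1L) {
      list("gene_unambiguous", ids,
           if (any(strd[rows] == "sense")) "sense" else "antisense")
    } else {
      list("gene_ambiguous", NA_character_, NA_character_)
    }
  }

  if (n > 0) {
    exact_pos <- match(tags, keys)
    exact_rows <- vector("list", n)
    has_exact <- !is.na(exact_pos)
    exact_rows[has_exact] <- entry_split[exact_pos[has_exact]]

    # the mismatch tier only matters when the exact tier has no gene hit
    exact_gene <- vapply(exact_rows, function(r) {
      !is.null(r) && any(comp[r] == "gene")
    }, logical(1))
    need_mm <- which(!exact_gene)
    mm_rows <- vector("list", n)
    if (length(need_mm) > 0) {
      vars <- one_mismatch_variants(tags[need_mm])
      vpos <- matrix(match(vars, keys), nrow = length(need_mm))
      for (k in seq_along(need_mm)) {
        vp <- vpos[k, ]
        vp <- vp[!is.na(vp)]
        if (length(vp) > 0) {
          mm_rows[[need_mm[k]]] <-
            unlist(entry_split[vp], use.names = FALSE)
        }
      }
    }

    for (i in seq_len(n)) {
      ex <- exact_rows[[i]] %||% integer(0)
      mm <- mm_rows[[i]] %||% integer(0)
      res <- NULL
      tier <- NA_character_
      g_ex <- ex[comp[ex] == "gene"]
      if (length(g_ex) > 0) {
        res <- classify_gene(g_ex); tier <- "exact"
      } else {
        g_mm <- mm[comp[mm] == "gene"]
        if (length(g_mm) > 0) {
          res <- classify_gene(g_mm); tier <- "mismatch"
        } else {
          for (cp in c("mitochondrion", "chloroplast", "genome")) {
            if (any(comp[ex] == cp)) {
              res <- list(cp, NA_character_, NA_character_)
              tier <- "exact"; break
            }
            if (any(comp[mm] == cp)) {
              res <- list(cp, NA_character_, NA_character_)
              tier <- "mismatch"; break
            }
          }
        }
      }
      if (!is.null(res)) {
        category[i] <- res[[1]]
        gene_id[i] <- res[[2]]
        strand[i] <- res[[3]]
        match_type[i] <- tier
      }
    }
  }

  assignments <- tibble(
    tag = tags, count = counts, category = category,
    match_type = match_type, gene_id = gene_id, strand = strand
  )
  unamb <- assignments |> filter(.data$category == "gene_unambiguous")
  gene_counts <- unamb |>
    group_by(.data$gene_id) |>
    summarise(
      sense_count = sum(.data$count[.data$strand == "sense"]),
      antisense_count = sum(.data$count[.data$strand == "antisense"]),
      .groups = "drop"
    )
  category_summary <- assignments |>
    mutate(category = factor(.data$category, levels = MAP_CATEGORIES)) |>
    group_by(.data$category, .drop = FALSE) |>
    summarise(total = sum(.data$count), distinct = dplyr::n(),
              .groups = "drop") |>
    mutate(category = as.character(.data$category))

  structure(
    list(
      assignments = assignments,
      gene_counts = gene_counts,
      category_summary = category_summary,
      library_id = library$library_id,
      clean_total = library$clean_total
    ),
    class = "mapping_result"
  )
}

#' Antisense transcription summary of a mapping
#'
#' Fraction of unambiguous gene-mapped tag mass assigned to the antisense
#' strand, the signature of antisense transcription in DGE data.
#'
#' @param mapping A `mapping_result` from [map_tags()].
#' @return One-row tibble with `library_id`, `sense_total`,
#'   `antisense_total`, `antisense_fraction` (`NA` when nothing mapped
#'   unambiguously).
#' @export
antisense_report <- function(mapping) {
  stopifnot(inherits(mapping, "mapping_result"))
  s <- sum(mapping$gene_counts$sense_count)
  a <- sum(mapping$gene_counts$antisense_count)
  tibble(
    library_id = mapping$library_id,
    sense_total = s, antisense_total = a,
    antisense_fraction = if (s + a == 0) NA_real_ else a / (s + a)
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result %s> %d distinct tags, clean total %d\n",
              x$library_id, nrow(x$assignments), x$clean_total))
  print(x$category_summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mapping_result <- function(x, ...) {
  mutate(x$gene_counts, library_id = x$library_id, .before = 1)
}

#' @exportS3Method generics::glance
glance.mapping_result <- function(x, ...) {
  wide <- x$category_summary |>
    tidyr::pivot_wider(names_from = "category",
                       values_from = c("total", "distinct"))
  dplyr::bind_cols(
    tibble(library_id = x$library_id, clean_total = x$clean_total), wide
  )
}
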