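#' Species abbreviations with collision resolution
#'
#' Abbreviations are built as the upper-case genus initial plus a
#' lower-case prefix of the species epithet, starting with a single
#' epithet letter. When a later species collides with an
#' already-assigned abbreviation, it jumps to a four-letter epithet
#' prefix and then extends one letter at a time until unique, while the
#' earlier species keeps its short form: *Capsella rubella* stays `Cr`
#' and *Chlamydomonas reinhardtii* becomes `Crein`. A `"minimal"`
#' policy that instead grows the prefix one letter at a time from two
#' is also available.
#'
#' @param species A tibble with columns `genus` and `species_epithet`.
#' @param policy `"jump4"` (default, see above) or `"minimal"`.
#' @param order Priority order for collision resolution:
#'   `"alphabetical"` by (genus, epithet) (default, reproducible for
#'   unordered input) or `"input"`.
#' @return A tibble `genus`, `species_epithet`, `abbrev`, in the input
#'   row order; abbreviations are unique.
#' @examples
#' make_abbrevs(tibble::tibble(
#'   genus = c("Capsella", "Chlamydomonas"),
#'   species_epithet = c("rubella", "reinhardtii")))
#' @export
make_abbrevs <- function(species, policy = c("jump4", "minimal"),
                         order = c("alphabetical", "input")) {
  policy <- match.arg(policy)
  order <- match.arg(order)
  if (any(!nzchar(species$genus)) || any(!nzchar(species$species_epithet)) ||
      any(is.na(species$genus)) || any(is.na(species$species_epithet))) {
    abort("Every species needs a non-empty genus and epithet.")
  }
  key <- paste(species$genus, species$species_epithet)
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate species: %s.", key[duplicated(key)][1]),
          class = "cblkit_duplicate_species_error")
  }
  idx <- if (order == "alphabetical") {
    base::order(tolower(species$genus), tolower(species$species_epithet))
  } else {
    seq_len(nrow(species))
  }
  taken <- character(0)
  abbrevs <- character(nrow(species))
  for (i in idx) {
    g <- toupper(substr(species$genus[i], 1, 1))
    ep <- tolower(species$species_epithet[i])
    cand <- paste0(g, substr(ep, 1, 1))
    if (cand %in% taken) {
      k <- if (policy == "jump4") 4L else 2L
      repeat {
        if (k > nchar(ep)) {
          abort(sprintf(
            "Cannot disambiguate %s %s: species epithet exhausted.",
            species$genus[i], species$species_epithet[i]),
            class = "cblkit_collision_error")
        }
        cand <- paste0(g, substr(ep, 1, k))
        if (!cand %in% taken) break
        k <- k + 1L
      }
    }
    taken <- c(taken, cand)
    abbrevs[i] <- cand
  }
  tibble::tibble(genus = species$genus,
                 species_epithet = species$species_epithet,
                 abbrev = abbrevs)
}

align_score <- function(query, ref, gap_open = 10, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global", scoreOnly = TRUE)
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Best reference ortholog by global alignment score
#'
#' Each query is globally aligned (BLOSUM62, affine gaps, open 10 /
#' extend 1 by default) against every reference; the reference with the
#' maximal score wins. Ties go to the lower reference CBL number, then
#' the lexicographically smaller reference id.
#'
#' @param records Query record tibble.
#' @param references A tibble with columns `id`, `cbl_number`
#'   (positive integer) and `sequence`.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A tibble per query: `record_id`, `ref_id`, `cbl_number`,
#'   `score`.
#' @export
best_ortholog <- function(records, references, gap_open = 10,
                          gap_extend = 1) {
  if (nrow(references) == 0) {
    abort("The reference set is empty.",
          class = "cblkit_config_error")
  }
  rows <- purrr::map2(records$id, records$sequence, function(id, seq) {
    scores <- vapply(references$sequence, align_score, numeric(1),
                     query = seq, gap_open = gap_open,
                     gap_extend = gap_extend, USE.NAMES = FALSE)
    ord <- base::order(-scores, references$cbl_number, references$id)
    best <- ord[1]
    tibble::tibble(record_id = id,
                   ref_id = references$id[best],
                   cbl_number = references$cbl_number[best],
                   score = scores[best])
  })
  dplyr::bind_rows(rows)
}

#' Assign orthology-based CBL gene names
#'
#' Names follow the pattern `<abbrev>CBL<number>[-<paralog>]`: the
#' species abbreviation from [make_abbrevs()], the CBL number of the
#' best-matching reference ortholog (rice references for monocots,
#' Arabidopsis references for dicots and all other lineages), and a
#' hyphenated paralog index when two or more records of a species share
#' a reference number. Paralog indices 1..c are ordered by descending
#' alignment score, ties by record id.
#'
#' @param records Query record tibble; `genus` and `species_epithet`
#'   must be filled in.
#' @param refs_monocot,refs_other Reference tibbles (`id`,
#'   `cbl_number`, `sequence`): the rice and Arabidopsis CBL sets.
#' @param lineage A tibble `genus`, `species_epithet`, `lineage` with
#'   lineage in `monocot`, `dicot`, `other`.
#' @param ... Passed to [make_abbrevs()] (`policy`, `order`).
#' @return A tibble per record: `record_id`, `abbrev`,
#'   `ortholog_number`, `paralog_index` (`NA` for singletons), `score`,
#'   `final_name`.
#' @export
assign_names <- function(records, refs_monocot, refs_other, lineage,
                         ...) {
  sp <- dplyr::distinct(records[, c("genus", "species_epithet")])
  ab <- make_abbrevs(sp, ...)
  joined <- dplyr::left_join(records, ab,
                             by = c("genus", "species_epithet"))
  lin <- dplyr::left_join(joined, lineage,
                          by = c("genus", "species_epithet"))
  if (any(is.na(lin$lineage))) {
    miss <- unique(paste(lin$genus, lin$species_epithet)[is.na(lin$lineage)])
    abort(sprintf("No lineage label for: %s.",
                  paste(head(miss, 5), collapse = ", ")),
          class = "cblkit_label_error")
  }
  if (any(!lin$lineage %in% c("monocot", "dicot", "other"))) {
    abort("Lineage labels must be monocot, dicot or other.",
          class = "cblkit_label_error")
  }
  hits <- purrr::map(seq_len(nrow(lin)), function(i) {
    refs <- if (lin$lineage[i] == "monocot") refs_monocot else refs_other
    best_ortholog(lin[i, , drop = FALSE], refs)
  })
  hits <- dplyr::bind_rows(hits)
  out <- dplyr::bind_cols(
    lin[, c("id", "genus", "species_epithet", "abbrev")],
    hits[, c("cbl_number", "score")])
  out <- out |>
    dplyr::group_by(.data$genus, .data$species_epithet,
                    .data$cbl_number) |>
    dplyr::mutate(
      .n_shared = dplyr::n(),
      paralog_index = if (dplyr::n() >= 2) {
        rank_order <- base::order(-.data$score, .data$id)
        match(seq_along(rank_order), rank_order)
      } else NA_integer_) |>
    dplyr::ungroup()
  tibble::tibble(
    record_id = out$id,
    abbrev = out$abbrev,
    ortholog_number = out$cbl_number,
    paralog_index = out$paralog_index,
    score = out$score,
    final_name = paste0(
      out$abbrev, "CBL", out$cbl_number,
      ifelse(is.na(out$paralog_index), "",
             paste0("-", out$paralog_index)))
  )
}

#' Parse a CBL gene name back into its components
#'
#' Inverse of the naming scheme: `"OsCBL3-2"` gives abbrev `"Os"`,
#' ortholog number 3, paralog index 2.
#'
#' @param name Character vector of names.
#' @return A tibble `final_name`, `abbrev`, `ortholog_number`,
#'   `paralog_index` (`NA` when no suffix).
#' @export
parse_cbl_name <- function(name) {
  m <- stringr::str_match(name,
                          "^([A-Z][a-z]*)CBL([0-9]+)(?:-([0-9]+))?$")
  if (any(is.na(m[, 1]))) {
    abort(sprintf("Not a CBL gene name: %s.",
                  paste(name[is.na(m[, 1])], collapse = ", ")))
  }
  tibble::tibble(
    final_name = name,
    abbrev = m[, 2],
    ortholog_number = as.integer(m[, 3]),
    paralog_index = as.integer(m[, 4])
  )
}
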