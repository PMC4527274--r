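#' Predict N-terminal myristoylation from the glycine position rule
#'
#' Myristate is attached co-translationally to an N-terminal glycine.
#' In CBLs that glycine sits at position 2 (immediately after the
#' initiator Met) or, in a secondary configuration, at position 7. The
#' rule is position-only: Gly at 2 wins over Gly at 7.
#'
#' @param records A record tibble (see [protein_records()]).
#' @return A tibble per record: `record_id`, `myristoylation` (flag),
#'   `myristoylation_position` (2, 7 or `NA`).
#' @export
predict_myristoylation <- function(records) {
  pos <- purrr::map_int(records$sequence, function(seq) {
    chars <- seq_chars(toupper(seq))
    if (length(chars) < 7) {
      abort("Myristoylation rule needs at least 7 residues.")
    }
    if (chars[2] == "G") 2L else if (chars[7] == "G") 7L else NA_integer_
  })
  tibble::tibble(
    record_id = records$id,
    myristoylation = !is.na(pos),
    myristoylation_position = pos
  )
}

#' Predict N-terminal palmitoylation from cysteine positions
#'
#' Palmitate attaches to N-terminal cysteines. Cys anywhere in the
#' first 25 residues is a candidate site; a Cys at position 3, 4, 5 or
#' 6 is the canonical configuration. Optionally, N-terminal lysines can
#' be reported as secondary candidate sites (mostly a prokaryotic
#' configuration, off by default).
#'
#' @param records A record tibble.
#' @param include_lys Also report Lys positions in the first 25
#'   residues (default `FALSE`).
#' @return A tibble per record: `record_id`,
#'   `palmitoylation_positions` (list-column of 1-based Cys positions
#'   within 1..25), `canonical_palmitoylation` (any Cys at 3-6),
#'   `short_sequence` (flag: fewer than 25 residues were available).
#' @export
predict_palmitoylation <- function(records, include_lys = FALSE) {
  rows <- purrr::map2(records$id, records$sequence, function(id, seq) {
    chars <- seq_chars(toupper(seq))
    short <- length(chars) < 25
    if (short) {
      warn(sprintf(
        "Record '%s' has only %d residues; palmitoylation scanned over the available prefix.",
        id, length(chars)))
    }
    prefix <- chars[seq_len(min(25L, length(chars)))]
    targets <- if (include_lys) c("C", "K") else "C"
    pos <- which(prefix %in% targets)
    tibble::tibble(
      record_id = id,
      palmitoylation_positions = list(pos),
      canonical_palmitoylation = any(pos %in% 3:6 & prefix[pos] == "C"),
      short_sequence = short
    )
  })
  dplyr::bind_rows(rows)
}

#' Full lipidation calls for a set of records
#'
#' Combines [predict_myristoylation()] and [predict_palmitoylation()]
#' and flags the group-B-like configuration (no N-terminal Cys at all).
#' Myristoylation is a biological prerequisite for palmitoylation; the
#' call table reports, but does not enforce, that relationship via
#' `palmitoylated_not_myristoylated`.
#'
#' @inheritParams predict_palmitoylation
#' @return A tibble per record with both call sets plus `group_b_like`
#'   and `palmitoylated_not_myristoylated`.
#' @export
lipidation_calls <- function(records, include_lys = FALSE) {
  out <- dplyr::left_join(predict_myristoylation(records),
                          predict_palmitoylation(records, include_lys),
                          by = "record_id")
  out$group_b_like <-
    vapply(out$palmitoylation_positions, length, integer(1)) == 0L
  out$palmitoylated_not_myristoylated <-
    out$canonical_palmitoylation & !out$myristoylation
  out
}

#' Group-level lipidation pattern summary
#'
#' CBL phylogenetic groups differ systematically: group B (the CBL10
#' clade) lacks N-terminal cysteines while groups A, C and D carry
#' them. Given per-record calls and group labels, reports per-group
#' fractions and flags departures from that expectation.
#'
#' @param calls Output of [lipidation_calls()].
#' @param groups A tibble with columns `record_id` and `group`
#'   (letters among A, B, C, D).
#' @return A tibble per group: `group`, `n`, `frac_canonical_palmitoylation`,
#'   `frac_myristoylation`, `expected_palmitoylation`, `violation`.
#'   Fractions of an empty group are `NA`, never 0.
#' @export
group_pattern_check <- function(calls, groups) {
  bad <- setdiff(unique(groups$group), c("A", "B", "C", "D"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown group label(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "cblkit_label_error")
  }
  missing <- setdiff(calls$record_id, groups$record_id)
  if (length(missing) > 0) {
    abort(sprintf("No group label for record(s): %s.",
                  paste(head(missing, 5), collapse = ", ")),
          class = "cblkit_label_error")
  }
  joined <- dplyr::left_join(calls, groups, by = "record_id")
  all_groups <- tibble::tibble(group = sort(unique(groups$group)))
  summ <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_canonical_palmitoylation =
        mean(.data$canonical_palmitoylation),
      frac_myristoylation = mean(.data$myristoylation),
      .groups = "drop")
  out <- dplyr::left_join(all_groups, summ, by = "group")
  out$n[is.na(out$n)] <- 0L
  out$expected_palmitoylation <- out$group != "B"
  out$violation <- !is.na(out$frac_canonical_palmitoylation) &
    ifelse(out$expected_palmitoylation,
           out$frac_canonical_palmitoylation == 0,
           out$frac_canonical_palmitoylation > 0)
  out
}
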