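#' Parse a degenerate motif pattern
#'
#' Patterns use the compact dash notation common in the EF-hand
#' literature: tokens separated by `-`, alternatives joined by `/`
#' (`D/E` = Asp or Glu), `x` a wildcard, and `x4` (or `x_4`) a run of
#' four wildcards. `"D/E-x-D"` therefore expands to three tokens and
#' `"E/D-D-P-E-x4-E-x6-E"` to sixteen.
#'
#' @param spec Pattern string.
#' @return An object of class `motif_pattern`: a list of per-position
#'   allowed-residue sets (`NULL` = wildcard) with the original string as
#'   its `label` attribute.
#' @examples
#' parse_motif_pattern("D/E-x-D")
#' @export
parse_motif_pattern <- function(spec) {
  raw <- strsplit(spec, "-", fixed = TRUE)[[1]]
  if (length(raw) == 0 || any(!nzchar(raw))) {
    abort(sprintf("Empty token in pattern '%s'.", spec),
          class = "cblkit_pattern_error")
  }
  tokens <- list()
  for (tok in raw) {
    if (grepl("^[xX](_?[0-9]+)?$", tok)) {
      k <- sub("^[xX]_?", "", tok)
      k <- if (nzchar(k)) as.integer(k) else 1L
      tokens <- c(tokens, rep(list(NULL), k))
    } else {
      alts <- toupper(strsplit(tok, "/", fixed = TRUE)[[1]])
      if (any(!nzchar(alts)) || any(!alts %in% AA20) ||
          any(nchar(alts) != 1)) {
        abort(sprintf("Unknown residue token '%s' in pattern '%s'.",
                      tok, spec),
              class = "cblkit_pattern_error")
      }
      tokens <- c(tokens, list(alts))
    }
  }
  if (length(tokens) < 2 || all(vapply(tokens, is.null, logical(1)))) {
    abort(sprintf(
      "Pattern '%s' needs at least 2 tokens with at least one informative (non-wildcard) position.",
      spec), class = "cblkit_pattern_error")
  }
  structure(tokens, label = spec, class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  sets <- vapply(unclass(x), function(t) {
    if (is.null(t)) "x" else paste(t, collapse = "/")
  }, character(1))
  cat("<motif_pattern> ", attr(x, "label"), "  [",
      paste(sets, collapse = " "), "]\n", sep = "")
  invisible(x)
}

pattern_matches_at <- function(chars, pattern, start) {
  for (j in seq_along(pattern)) {
    allowed <- pattern[[j]]
    if (!is.null(allowed) && !chars[start + j - 1] %in% allowed) {
      return(FALSE)
    }
  }
  TRUE
}

#' Find all occurrences of a motif pattern in a sequence
#'
#' Every matching window is reported, overlapping occurrences included.
#'
#' @param seq Amino-acid sequence (single string).
#' @param pattern A `motif_pattern` or a pattern string (parsed on the
#'   fly).
#' @return Integer vector of 1-based start positions (possibly empty).
#' @examples
#' find_motifs("KEADG", "D/E-x-D")
#' @export
find_motifs <- function(seq, pattern) {
  if (is.character(pattern)) pattern <- parse_motif_pattern(pattern)
  chars <- seq_chars(toupper(seq))
  k <- length(pattern)
  if (k > length(chars)) return(integer(0))
  starts <- seq_len(length(chars) - k + 1)
  hits <- vapply(starts, function(s) pattern_matches_at(chars, pattern, s),
                 logical(1))
  starts[hits]
}

# Window geometry: 36-residue helix(12)-loop(12)-helix(12). Loop ligand
# positions 1,3,5,7,9,12 map onto window positions 13,15,17,19,21,24.
EFHAND_WINDOW <- 36L
LOOP_LIGAND_OFFSETS <- c(13L, 15L, 17L, 19L, 21L, 24L)

# Per-start rule evaluation over a whole sequence, vectorized.
# Returns a tibble of every offset with its checks; selection happens in
# scan_ef_hands().
efhand_rule_table <- function(chars, loop_min_donors = 3L) {
  L <- length(chars)
  is_de <- chars %in% c("D", "E")
  is_donor <- chars %in% OXYGEN_DONORS
  starts <- seq_len(L - EFHAND_WINDOW + 1L)
  ok14 <- is_de[starts + 13L]
  ok22 <- is_de[starts + 21L]
  donor_hits <- Reduce(`+`, lapply(LOOP_LIGAND_OFFSETS, function(off) {
    as.integer(is_donor[starts + off - 1L])
  }))
  ok_loop12 <- is_de[starts + 23L]
  score <- (as.integer(ok14) + as.integer(ok22) +
              donor_hits) / 8
  tibble::tibble(
    start = starts,
    ok14 = ok14, ok22 = ok22, ok_loop12 = ok_loop12,
    loop_donor_matches = donor_hits,
    strict_pass = ok14 & ok22 & ok_loop12 &
      donor_hits >= loop_min_donors,
    score = score
  )
}

greedy_nonoverlap <- function(starts, width = EFHAND_WINDOW) {
  kept <- integer(0)
  next_free <- 1L
  for (s in sort(starts)) {
    if (s >= next_free) {
      kept <- c(kept, s)
      next_free <- s + width
    }
  }
  kept
}

#' Scan a protein for 36-residue EF-hand windows
#'
#' An EF-hand is modeled as a 36-residue helix-loop-helix window. The
#' default (strict) rule requires Asp or Glu at window positions 14 and
#' 22, Asp or Glu at the bidentate loop ligand (loop position 12, window
#' position 24), and at least `loop_min_donors` oxygen-donor residues
#' (D, E, N, Q, S, T) at the six canonical loop ligand positions 1, 3,
#' 5, 7, 9, 12 (window positions 13, 15, 17, 19, 21, 24). Overlapping
#' candidate windows are resolved greedily left to right, so hands are
#' reported in first/second/third order. The score is the fraction of
#' the 8 positional checks satisfied (the two key positions plus the six
#' loop donors); a fully canonical hand scores 1.
#'
#' @param seq Amino-acid sequence (single string), length >= 36.
#' @param strict If `TRUE` (default) only windows passing every
#'   mandatory check are reported; if `FALSE`, windows with
#'   `score >= min_score` are reported with their fractional score.
#' @param loop_min_donors Minimum oxygen-donor count among the six loop
#'   ligand positions (default 3).
#' @param min_score Score floor for permissive mode (default 0.5).
#' @return A tibble with one row per hit: `start`, `loop_start`
#'   (= start + 12), `key7`, `key14`, `key22` (the residue when it is
#'   D/E, otherwise `NA`), `loop_donor_matches`, `score`; sorted by
#'   `start`, non-overlapping.
#' @export
scan_ef_hands <- function(seq, strict = TRUE, loop_min_donors = 3L,
                          min_score = 0.5) {
  chars <- seq_chars(toupper(seq))
  if (length(chars) < EFHAND_WINDOW) {
    abort(sprintf(
      "Sequence of %d residues is shorter than one 36-residue EF-hand window.",
      length(chars)), class = "cblkit_too_short_error")
  }
  tab <- efhand_rule_table(chars, loop_min_donors)
  cand <- if (strict) tab$start[tab$strict_pass] else
    tab$start[tab$score >= min_score]
  kept <- greedy_nonoverlap(cand)
  tab <- tab[tab$start %in% kept, , drop = FALSE]
  key_res <- function(starts, off) {
    r <- chars[starts + off]
    ifelse(r %in% c("D", "E"), r, NA_character_)
  }
  tibble::tibble(
    start = tab$start,
    loop_start = tab$start + 12L,
    key7 = key_res(tab$start, 6L),
    key14 = key_res(tab$start, 13L),
    key22 = key_res(tab$start, 21L),
    loop_donor_matches = tab$loop_donor_matches,
    score = tab$score
  )
}

#' Classify proteins as CBL by their EF-hand count
#'
#' CBL calcium sensors carry exactly three EF-hands (calmodulins and
#' CPK regulatory domains carry four); a record is called CBL iff the
#' strict scanner finds exactly 3 hands.
#'
#' @param records A record tibble (see [protein_records()]).
#' @inheritParams scan_ef_hands
#' @return A tibble with one row per record: `record_id`, `n_hands`,
#'   `hand_starts` (list-column of integer start vectors), `is_cbl`.
#' @export
classify_cbl <- function(records, strict = TRUE, loop_min_donors = 3L) {
  res <- purrr::map(records$sequence, scan_ef_hands, strict = strict,
                    loop_min_donors = loop_min_donors)
  tibble::tibble(
    record_id = records$id,
    n_hands = vapply(res, nrow, integer(1)),
    hand_starts = purrr::map(res, "start"),
    is_cbl = vapply(res, nrow, integer(1)) == 3L
  )
}

#' Per-position D/E conservation profile of an EF-hand window
#'
#' Over a family alignment, reports for each of the 36 window positions
#' the fraction of members carrying Asp, Glu, and Asp-or-Glu. Gap
#' characters are excluded from the denominator of their column rather
#' than counted as mismatches.
#'
#' @param block An alignment tibble.
#' @param window_start_column 1-based alignment column where the
#'   36-column window starts.
#' @return A tibble of class `efhand_profile` with 36 rows: `position`
#'   (1..36), `column`, `n_ungapped`, `freq_d`, `freq_e`, `freq_de`;
#'   attribute `n_members`.
#' @export
conservation_profile <- function(block, window_start_column) {
  nc <- n_columns(block)
  if (window_start_column < 1 ||
      window_start_column + EFHAND_WINDOW - 1L > nc) {
    abort(sprintf(
      "A 36-column window starting at %d does not fit in a %d-column alignment.",
      window_start_column, nc), class = "cblkit_range_error")
  }
  mat <- alignment_matrix(block)
  cols <- window_start_column:(window_start_column + EFHAND_WINDOW - 1L)
  rows <- purrr::map(seq_along(cols), function(i) {
    col <- mat[, cols[i]]
    res <- col[col != "-"]
    n <- length(res)
    tibble::tibble(
      position = i,
      column = cols[i],
      n_ungapped = n,
      freq_d = if (n) mean(res == "D") else NA_real_,
      freq_e = if (n) mean(res == "E") else NA_real_,
      freq_de = if (n) mean(res %in% c("D", "E")) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_members") <- nrow(block)
  class(out) <- c("efhand_profile", class(out))
  out
}

#' Check group-specific N-terminal motifs
#'
#' Group D CBLs carry an E-E/D-P motif at residues 16-18 of the
#' N-terminal region; group A CBLs carry a D/E-x-E/D motif at residues
#' 31-33. Positions are counted from the initiator Met (= 1).
#'
#' @param records A record tibble.
#' @param group `"A"` or `"D"`.
#' @return A tibble per record: `record_id`, `group`, `start`,
#'   `residues` (the residues at the checked positions), `match`.
#' @export
nterminal_motif_check <- function(records, group = c("A", "D")) {
  group <- match.arg(group)
  pat <- switch(group,
                A = parse_motif_pattern("D/E-x-E/D"),
                D = parse_motif_pattern("E-E/D-P"))
  start <- switch(group, A = 31L, D = 16L)
  k <- length(pat)
  rows <- purrr::map2(records$id, records$sequence, function(id, seq) {
    chars <- seq_chars(toupper(seq))
    fits <- start + k - 1L <= length(chars)
    tibble::tibble(
      record_id = id,
      group = group,
      start = start,
      residues = if (fits)
        paste(chars[start:(start + k - 1L)], collapse = "") else
          NA_character_,
      match = fits && pattern_matches_at(chars, pat, start)
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot a D/E conservation profile
#'
#' @param profile An `efhand_profile` tibble from
#'   [conservation_profile()].
#' @return A ggplot object: per-position D, E and D-or-E frequencies
#'   across the 36-residue window.
#' @export
plot_conservation_profile <- function(profile) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(profile)[, c("position", "freq_d", "freq_e", "freq_de")],
    -"position", names_to = "measure", values_to = "frequency")
  long$measure <- factor(long$measure, c("freq_d", "freq_e", "freq_de"),
                         c("Asp", "Glu", "Asp or Glu"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$position, y = .data$frequency,
                               colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 36, 4)) +
    ggplot2::labs(x = "EF-hand window position", y = "Frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
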