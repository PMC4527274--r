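#' Build a tibble of protein records
#'
#' The unit flowing through scanning, naming and composition is a plain
#' tibble with one row per protein: `id`, `genus`, `species_epithet`,
#' `sequence`. Sequences use the 20 standard upper-case one-letter codes;
#' residue positions are 1-based with the initiator Met at position 1.
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param genus,species_epithet Optional species metadata (recycled).
#' @param aligned If `TRUE`, the gap symbol `-` is permitted and all
#'   sequences must have equal length.
#' @return A tibble with columns `id`, `genus`, `species_epithet`,
#'   `sequence`. When `aligned`, it carries class `cbl_alignment` and an
#'   `n_columns` attribute.
#' @examples
#' protein_records(c("p1", "p2"), c("MGCFH", "MGCYH"))
#' @export
protein_records <- function(id, sequence, genus = NA_character_,
                            species_epithet = NA_character_,
                            aligned = FALSE) {
  if (length(id) != length(sequence)) {
    abort("`id` and `sequence` must have the same length.")
  }
  sequence <- unname(toupper(sequence))
  validate_sequences(id, sequence, allow_gap = aligned)
  out <- tibble::tibble(
    id = as.character(id),
    genus = rep_len(as.character(genus), length(id)),
    species_epithet = rep_len(as.character(species_epithet), length(id)),
    sequence = sequence
  )
  if (aligned) out <- as_alignment(out)
  out
}

validate_sequences <- function(id, sequence, allow_gap = FALSE) {
  alphabet <- AA20
  if (allow_gap) alphabet <- c(alphabet, "-")
  for (i in seq_along(sequence)) {
    if (!nzchar(sequence[[i]])) {
      abort(sprintf("Record '%s' has an empty sequence.", id[[i]]))
    }
    chars <- strsplit(sequence[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% alphabet)
    if (length(bad) > 0) {
      abort(sprintf(
        "Record '%s' contains illegal residue '%s' at position %d (only the 20 standard one-letter codes%s are accepted).",
        id[[i]], chars[bad[1]], bad[1], if (allow_gap) " and '-'" else ""),
        class = "cblkit_alphabet_error")
    }
  }
  invisible(TRUE)
}

as_alignment <- function(records) {
  lens <- nchar(records$sequence)
  if (nrow(records) < 2) {
    abort("An alignment needs at least 2 member sequences.",
          class = "cblkit_alignment_shape_error")
  }
  if (length(unique(lens)) != 1) {
    abort(sprintf(
      "Aligned sequences must share one length; found lengths %s.",
      paste(sort(unique(lens)), collapse = ", ")),
      class = "cblkit_alignment_shape_error")
  }
  structure(records,
            n_columns = lens[[1]],
            class = c("cbl_alignment", class(tibble::tibble())))
}

#' Number of columns in an alignment tibble
#' @param block An alignment tibble from [protein_records()] or
#'   [read_fasta()] with `aligned = TRUE`.
#' @return Integer column count.
#' @export
n_columns <- function(block) {
  nc <- attr(block, "n_columns")
  if (is.null(nc)) nc <- unique(nchar(block$sequence))
  if (length(nc) != 1) {
    abort("Not an alignment: member sequences differ in length.",
          class = "cblkit_alignment_shape_error")
  }
  as.integer(nc)
}

#' Read protein sequences or a gapped alignment from FASTA
#'
#' Identifiers are parsed from the header up to the first whitespace;
#' record order is preserved. Residues outside the 20-letter alphabet
#' (plus `-` when `aligned`) raise an error naming the record and its
#' 1-based offset; ambiguity codes such as `X` or `B` are rejected rather
#' than skipped so downstream counting stays well-defined.
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE`, parse as a gapped alignment: gap symbols are
#'   retained and all sequences must have equal length.
#' @return A tibble of records; see [protein_records()].
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  protein_records(ids, as.character(set), aligned = aligned)
}

#' Write protein records to FASTA
#'
#' Headers are `>` + id; sequences wrap at 60 columns. Round-tripping
#' through [read_fasta()] reproduces sequences byte-identically.
#'
#' @param records A record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Protein length encoded by an open reading frame
#'
#' An ORF of `orf_nt` nucleotides (stop codon included) encodes
#' `orf_nt / 3 - 1` residues: e.g. a 3048-nt ORF encodes 1015 amino acids
#' and a 426-nt ORF encodes 141.
#'
#' @param orf_nt Nucleotide count(s), each >= 6 and divisible by 3.
#' @return Integer residue count(s).
#' @examples
#' orf_to_protein_length(c(3048, 426))
#' @export
orf_to_protein_length <- function(orf_nt) {
  if (any(orf_nt %% 3 != 0)) {
    abort("ORF length must be divisible by 3 (complete codons).",
          class = "cblkit_frame_error")
  }
  if (any(orf_nt < 6)) {
    abort("ORF must be at least 6 nt (start codon + stop codon).",
          class = "cblkit_frame_error")
  }
  as.integer(orf_nt / 3 - 1)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Character matrix view of an alignment: rows = members, cols = columns.
alignment_matrix <- function(block) {
  nc <- n_columns(block)
  matrix(unlist(strsplit(block$sequence, "", fixed = TRUE)),
         nrow = nrow(block), ncol = nc, byrow = TRUE,
         dimnames = list(block$id, NULL))
}
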