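species_tbl <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(genus = m[, 1], species_epithet = m[, 2])
}

test_that("species abbreviations resolve collisions by epithet extension", {
  ab <- make_abbrevs(species_tbl("Capsella", "rubella",
                                 "Chlamydomonas", "reinhardtii"))
  expect_identical(ab$abbrev, c("Cr", "Crein"))

  expect_identical(
    make_abbrevs(species_tbl("Arabidopsis", "thaliana"))$abbrev, "At")

  # no collision at the genus-initial + first-epithet-letter level
  ab2 <- make_abbrevs(species_tbl("Citrus", "clementina",
                                  "Citrus", "sinensis"))
  expect_identical(ab2$abbrev, c("Cc", "Cs"))

  expect_error(
    make_abbrevs(species_tbl("Oryza", "sativa", "Oryza", "sativa")),
    class = "cblkit_duplicate_species_error")

  # minimal policy grows one letter at a time instead of jumping to 4
  ab3 <- make_abbrevs(species_tbl("Capsella", "rubella",
                                  "Chlamydomonas", "reinhardtii"),
                      policy = "minimal")
  expect_identical(ab3$abbrev, c("Cr", "Cre"))
})

test_that("abbreviations are unique and deterministic over a realistic species panel", {
  panel <- species_tbl(
    "Aquilegia", "coerulea", "Arabidopsis", "thaliana",
    "Brachypodium", "distachyon", "Brassica", "rapa",
    "Capsella", "rubella", "Carica", "papaya",
    "Chlamydomonas", "reinhardtii", "Citrus", "clementina",
    "Citrus", "sinensis", "Cucumis", "sativus",
    "Eucalyptus", "grandis", "Fragaria", "vesca",
    "Glycine", "max", "Gossypium", "raimondii",
    "Malus", "domestica", "Manihot", "esculenta",
    "Medicago", "truncatula", "Micromonas", "pusilla",
    "Mimulus", "guttatus", "Oryza", "sativa",
    "Physcomitrella", "patens", "Picea", "abies",
    "Populus", "trichocarpa", "Prunus", "persica",
    "Selaginella", "moellendorffii", "Solanum", "lycopersicum",
    "Solanum", "tuberosum", "Zea", "mays")
  ab <- make_abbrevs(panel)
  expect_false(any(duplicated(ab$abbrev)))
  expect_identical(ab, make_abbrevs(panel))
  # shuffling the input rows changes nothing but row order under
  # alphabetical priority
  idx <- rev(seq_len(nrow(panel)))
  ab_rev <- make_abbrevs(panel[idx, ])
  merged <- dplyr::inner_join(ab, ab_rev,
                              by = c("genus", "species_epithet"))
  expect_identical(merged$abbrev.x, merged$abbrev.y)
})

ref_set <- function() {
  set.seed(303)
  tibble::tibble(
    id = paste0("OsCBL", 1:5),
    cbl_number = 1:5,
    sequence = vapply(1:5, function(i) random_protein(80), character(1)))
}

test_that("best ortholog maximizes alignment score with documented tie-breaks", {
  refs <- ref_set()
  q <- protein_records("q", refs$sequence[4])
  hit <- best_ortholog(q, refs)
  expect_identical(hit$cbl_number, 4L)

  # equidistant by construction: identical reference sequences
  refs_tie <- tibble::tibble(
    id = c("AtCBL7", "AtCBL2"), cbl_number = c(7L, 2L),
    sequence = rep(refs$sequence[1], 2))
  tie <- best_ortholog(protein_records("q2", refs$sequence[1]), refs_tie)
  expect_identical(tie$cbl_number, 2L)

  expect_error(best_ortholog(q, refs[0, ]),
               class = "cblkit_config_error")
})

test_that("point-mutated queries return to their source reference", {
  refs <- ref_set()
  set.seed(17)
  for (rep in 1:25) {
    base <- strsplit(refs$sequence[3], "")[[1]]
    pos <- sample(seq_along(base), 5)
    base[pos] <- vapply(base[pos], function(old) {
      sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], old), 1)
    }, character(1))
    hit <- best_ortholog(
      protein_records("mut", paste(base, collapse = "")), refs)
    expect_identical(hit$cbl_number, 3L)
  }
})

test_that("name assignment produces hyphenated paralog suffixes and round-trips", {
  refs <- ref_set()
  lineage <- tibble::tibble(genus = "Oryza", species_epithet = "sativa",
                            lineage = "monocot")
  # three rice paralogs of reference 3 (increasing divergence) plus a
  # singleton match to reference 5
  set.seed(29)
  mutate_seq <- function(seq, k) {
    chars <- strsplit(seq, "")[[1]]
    pos <- sample(seq_along(chars), k)
    chars[pos] <- vapply(chars[pos], function(old) {
      sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], old), 1)
    }, character(1))
    paste(chars, collapse = "")
  }
  recs <- protein_records(
    c("r_b", "r_a", "r_c", "r_single"),
    c(mutate_seq(refs$sequence[3], 4), refs$sequence[3],
      mutate_seq(refs$sequence[3], 8), refs$sequence[5]),
    genus = "Oryza", species_epithet = "sativa")
  names_tbl <- assign_names(recs, refs_monocot = refs,
                            refs_other = refs, lineage = lineage)
  by_id <- setNames(names_tbl$final_name, names_tbl$record_id)
  expect_identical(unname(by_id["r_a"]), "OsCBL3-1") # best score
  expect_identical(unname(by_id["r_b"]), "OsCBL3-2")
  expect_identical(unname(by_id["r_c"]), "OsCBL3-3")
  expect_identical(unname(by_id["r_single"]), "OsCBL5")

  # suffixes for a shared number are exactly 1..c
  shared <- names_tbl[names_tbl$ortholog_number == 3, ]
  expect_setequal(shared$paralog_index, 1:3)

  parsed <- parse_cbl_name(names_tbl$final_name)
  expect_identical(parsed$abbrev, names_tbl$abbrev)
  expect_identical(parsed$ortholog_number, names_tbl$ortholog_number)
  expect_identical(parsed$paralog_index, names_tbl$paralog_index)

  expect_error(
    assign_names(recs, refs, refs,
                 tibble::tibble(genus = "Zea", species_epithet = "mays",
                                lineage = "monocot")),
    class = "cblkit_label_error")
})
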