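test_that("motif pattern parsing expands alternatives and wildcards", {
  p <- parse_motif_pattern("D/E-x-D")
  expect_length(p, 3)
  expect_setequal(p[[1]], c("D", "E"))
  expect_null(p[[2]])
  expect_equal(p[[3]], "D")

  expect_length(parse_motif_pattern("P-S-F-V-F-x-S-E-V-D-E"), 11)
  expect_length(parse_motif_pattern("E/D-D-P-E-x4-E-x6-E"), 16)

  expect_error(parse_motif_pattern("x"), class = "cblkit_pattern_error")
  expect_error(parse_motif_pattern("D--E"), class = "cblkit_pattern_error")
  expect_error(parse_motif_pattern("D-Z"), class = "cblkit_pattern_error")
})

test_that("find_motifs reports every occurrence, overlaps included", {
  expect_equal(find_motifs("KEADG", "D/E-x-D"), 2L)
  expect_equal(find_motifs("DDDD", "D-x-D"), c(1L, 2L))
  expect_equal(find_motifs("AAAA", "D-x-D"), integer(0))
  # planted occurrence in a random background, cross-checked by a
  # sliding-window brute force
  set.seed(11)
  for (rep in 1:20) {
    chars <- strsplit(random_protein(200), "")[[1]]
    chars[50:54] <- c("V", "F", "H", "P", "N")
    seq <- paste(chars, collapse = "")
    hits <- find_motifs(seq, "V-F-H-P-N")
    brute <- which(vapply(1:196, function(s) {
      all(chars[s:(s + 4)] == c("V", "F", "H", "P", "N"))
    }, logical(1)))
    expect_identical(hits, as.integer(brute))
    expect_true(50L %in% hits)
  }
})

test_that("EF-hand scanner agrees with the exhaustive brute-force oracle", {
  expect_equal(nrow(scan_ef_hands(strrep("A", 100))), 0)
  expect_error(scan_ef_hands("MKT"), class = "cblkit_too_short_error")
  set.seed(42)
  for (rep in 1:150) {
    seq <- random_protein(sample(36:200, 1))
    hits <- scan_ef_hands(seq)
    expect_identical(hits$start, oracle_scan(seq),
                     info = paste("seq rep", rep))
  }
})

test_that("planted hands are recovered at exact positions", {
  for (seed in 1:25) {
    fam <- simulate_family(n_proteins = 4, seed = seed)
    for (i in 1:4) {
      hits <- scan_ef_hands(fam$records$sequence[i])
      expect_identical(hits$start, c(40L, 120L, 200L))
      expect_true(all(hits$score == 1))
      expect_identical(hits$loop_start, hits$start + 12L)
    }
  }
})

test_that("relaxing the loop-donor threshold never removes a hit", {
  set.seed(99)
  for (rep in 1:50) {
    seq <- random_protein(200)
    # candidate windows under the stricter threshold are a subset of
    # those under the relaxed one (greedy selection may then shift)
    t3 <- cblkit:::efhand_rule_table(strsplit(seq, "")[[1]], 3)
    t2 <- cblkit:::efhand_rule_table(strsplit(seq, "")[[1]], 2)
    expect_true(all(t3$start[t3$strict_pass] %in% t2$start[t2$strict_pass]))
  }
})

test_that("classification calls CBL iff exactly three hands", {
  fam <- simulate_family(n_proteins = 3, seed = 5)
  cls <- classify_cbl(fam$records)
  expect_true(all(cls$is_cbl))
  expect_true(all(cls$n_hands == 3))

  # CaM-like: four planted hands in one longer sequence
  set.seed(8)
  chars <- strsplit(random_protein(320), "")[[1]]
  for (p in c(40L, 120L, 200L, 280L)) {
    chars <- cblkit:::canonical_hand(chars, p)
  }
  chars <- cblkit:::repair_spurious_hands(chars, c(40L, 120L, 200L, 280L), 1L)
  cam <- protein_records("cam_like", paste(chars, collapse = ""))
  cls4 <- classify_cbl(cam)
  expect_identical(cls4$n_hands, 4L)
  expect_false(cls4$is_cbl)

  none <- protein_records("poly_a", strrep("A", 100))
  expect_false(classify_cbl(none)$is_cbl)
})

test_that("conservation profile counts non-gap residues per column", {
  block <- protein_records(
    paste0("m", 1:4),
    c(paste0(strrep("A", 10), "D", strrep("A", 30)),
      paste0(strrep("A", 10), "D", strrep("A", 30)),
      paste0(strrep("A", 10), "D", strrep("A", 30)),
      paste0(strrep("A", 10), "-", strrep("A", 30))),
    aligned = TRUE)
  prof <- conservation_profile(block, 3)
  row <- prof[prof$column == 11, ]
  expect_equal(row$freq_d, 1.0)       # gap member excluded
  expect_equal(row$n_ungapped, 3)
  expect_true(all(prof$freq_de >= pmax(prof$freq_d, prof$freq_e),
                  na.rm = TRUE))
  expect_true(all(prof$freq_d + prof$freq_e <= prof$freq_de + 1e-12,
                  na.rm = TRUE))
  expect_error(conservation_profile(block, 10),
               class = "cblkit_range_error")
})

test_that("profile recovers a planted 90% conservation level", {
  fam <- simulate_family(n_proteins = 200, conservation_level = 0.9,
                         seed = 21)
  block <- protein_records(fam$records$id, fam$records$sequence,
                           aligned = TRUE) # equal lengths, ungapped
  prof <- conservation_profile(block, 40) # first hand window
  expect_lt(abs(prof$freq_de[prof$position == 14] - 0.9), 0.05)
  # direct counting oracle on the same data
  direct <- mean(substr(fam$records$sequence, 53, 53) %in% c("D", "E"))
  expect_equal(prof$freq_de[prof$position == 14], direct)
})

test_that("group-specific N-terminal motifs are detected positionally", {
  seq_d <- paste0("MG", strrep("A", 13), "EEP", strrep("A", 22))
  seq_a <- paste0("MG", strrep("A", 28), "DAE", strrep("A", 7))
  recs <- protein_records(c("d", "a", "g"),
                          c(seq_d, seq_a, paste0("M", strrep("G", 39))))
  d_check <- nterminal_motif_check(recs, "D")
  expect_identical(d_check$match, c(TRUE, FALSE, FALSE))
  a_check <- nterminal_motif_check(recs, "A")
  expect_identical(a_check$match, c(FALSE, TRUE, FALSE))
  expect_equal(unique(d_check$start), 16L)
  expect_equal(unique(a_check$start), 31L)
})
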