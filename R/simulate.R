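# Seeded generators for every input class the pipeline consumes, each a
# pure function of its spec (seed included) and each returning planted
# ground truth alongside the data.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

sample_background <- function(n, probs = NULL) {
  if (is.null(probs)) {
    ref <- aa_reference_data()
    probs <- setNames(ref$composition_pct, ref$residue)
  }
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Fill one 36-residue window so it satisfies the strict scanner rule
# (fully canonical: all six loop ligands are oxygen donors). Loop
# donors other than the bidentate position avoid D/E to keep
# accidental key-position matches of overlapping windows rare.
canonical_hand <- function(chars, start, key_de = TRUE) {
  de <- c("D", "E")
  nonacidic_donors <- c("N", "Q", "S", "T")
  if (key_de) {
    chars[start + 13L] <- sample(de, 1, prob = c(0.7, 0.3))
    chars[start + 21L] <- sample(de, 1, prob = c(0.3, 0.7))
    chars[start + 23L] <- sample(de, 1)
  } else {
    chars[start + 13L] <- "A"
    chars[start + 21L] <- "A"
    chars[start + 23L] <- sample(nonacidic_donors, 1)
  }
  for (off in c(12L, 14L, 16L, 18L, 20L)) {
    chars[start + off] <- sample(nonacidic_donors, 1)
  }
  chars[start + 6L] <- sample(de, 1) # accessory key position 7
  chars
}

# Absolute positions a repair mutation must not touch: the rule-bearing
# positions of each planted hand plus fixed N-terminal sites.
protected_positions <- function(hand_positions, nterm_protect) {
  rule_offsets <- c(6L, 12L, 13L, 14L, 16L, 18L, 20L, 21L, 23L)
  c(unlist(lapply(hand_positions, function(p) p + rule_offsets)),
    nterm_protect)
}

repair_spurious_hands <- function(chars, hand_positions, nterm_protect,
                                  loop_min_donors = 3L) {
  protected <- protected_positions(hand_positions, nterm_protect)
  expected <- hand_positions[vapply(hand_positions, function(p) {
    tab <- efhand_rule_table(chars[p:(p + 35L)], loop_min_donors)
    tab$strict_pass[1]
  }, logical(1))]
  for (iter in 1:200) {
    tab <- efhand_rule_table(chars, loop_min_donors)
    selected <- greedy_nonoverlap(tab$start[tab$strict_pass])
    if (identical(as.integer(selected), as.integer(expected))) {
      return(chars)
    }
    spurious <- setdiff(selected, expected)
    if (length(spurious) == 0) {
      abort("Cannot reconcile planted hands with the scanner rule.",
            class = "cblkit_spec_error")
    }
    s <- spurious[1]
    # break a mandatory check of the spurious window at a free position
    targets <- c(s + 13L, s + 21L, s + 23L,
                 s + c(12L, 14L, 16L, 18L, 20L))
    free <- setdiff(targets, protected)
    if (length(free) == 0) {
      abort("Planted hand layout leaves an unrepairable spurious window.",
            class = "cblkit_spec_error")
    }
    chars[free[1]] <- "L"
  }
  abort("Spurious-window repair did not converge.",
        class = "cblkit_spec_error")
}

#' Generate a synthetic CBL-like protein family with planted truth
#'
#' Each member carries three 36-residue EF-hand windows satisfying the
#' strict scanner rule at the planted starts (subject to
#' `conservation_level`, below), drawn over a background following the
#' packaged family-average residue composition. Phylogenetic group
#' membership drives the N-terminus: groups A, C and D get Gly at
#' position 2 and one Cys at a position in 3..6; group B members get
#' neither an N-terminal Gly (positions 2 and 7) nor any Cys in the
#' first 25 residues. Group D additionally carries E-E/D-P at 16-18
#' and group A carries D/E-x-E/D at 31-33. After planting, background
#' positions are minimally mutated (to Leu) so that no spurious window
#' passes the strict rule: the planted truth is exact by construction.
#'
#' @param n_proteins Number of members (default 40).
#' @param length Protein length in residues (default 240).
#' @param group_mix Named proportions for groups A, B, C, D (default
#'   reflects the relative clade sizes of the family: A 0.4, B 0.1,
#'   C 0.2, D 0.3); must sum to 1.
#' @param hand_positions Three non-overlapping 1-based window starts;
#'   the first must be > 33 so the N-terminal region stays intact
#'   (default 40, 120, 200).
#' @param conservation_level Probability that a planted hand carries
#'   D/E at its key positions (default 1: every hand passes the strict
#'   rule). Lower values emulate families with degenerate hands for
#'   conservation profiling.
#' @param seed Integer seed; identical specs give identical output.
#' @return A list: `records` (record tibble) and `truth` (per record:
#'   `record_id`, `group`, `hand_starts` list-column,
#'   `hands_canonical` list-column of per-hand strict flags,
#'   `myristoylation_position`, `palmitoylation_position`).
#' @export
simulate_family <- function(n_proteins = 40, length = 240,
                            group_mix = c(A = 0.4, B = 0.1,
                                          C = 0.2, D = 0.3),
                            hand_positions = c(40L, 120L, 200L),
                            conservation_level = 1,
                            seed = 1L) {
  hand_positions <- sort(as.integer(hand_positions))
  if (length(hand_positions) != 3) {
    abort("Exactly three hand positions are required.",
          class = "cblkit_spec_error")
  }
  if (any(diff(hand_positions) < 37L)) {
    abort("Planted hands must be non-overlapping and at least 1 apart.",
          class = "cblkit_spec_error")
  }
  if (hand_positions[1] <= 33L) {
    abort("The first hand must start after the 33-residue N-terminal region.",
          class = "cblkit_spec_error")
  }
  if (hand_positions[3] + 35L > length) {
    abort("Protein length does not accommodate the third hand.",
          class = "cblkit_spec_error")
  }
  if (abs(sum(group_mix) - 1) > 1e-8) {
    abort("Group proportions must sum to 1.",
          class = "cblkit_spec_error")
  }
  with_local_seed(seed, {
    groups <- sample(names(group_mix), n_proteins, replace = TRUE,
                     prob = group_mix)
    built <- purrr::map(seq_len(n_proteins), function(i) {
      grp <- groups[i]
      chars <- sample_background(length)
      chars[1] <- "M"
      canon <- runif(3) <= conservation_level
      for (h in 1:3) {
        chars <- canonical_hand(chars, hand_positions[h],
                                key_de = canon[h])
      }
      nterm_protect <- 1L
      myr_pos <- NA_integer_
      palm_pos <- NA_integer_
      if (grp == "B") {
        # no myristoylation glycine, no N-terminal cysteine
        for (p in c(2L, 7L)) if (chars[p] == "G") chars[p] <- "A"
        idx <- which(chars[1:25] == "C")
        chars[idx] <- "S"
        nterm_protect <- c(1L, 2L, 7L)
      } else {
        chars[2] <- "G"
        myr_pos <- 2L
        palm_pos <- sample(3:6, 1)
        # a single unambiguous N-terminal cysteine
        idx <- setdiff(which(chars[1:25] == "C"), palm_pos)
        chars[idx] <- "S"
        chars[palm_pos] <- "C"
        nterm_protect <- c(1L, 2L, 7L, palm_pos)
      }
      if (grp == "D") {
        chars[16:18] <- c("E", sample(c("E", "D"), 1), "P")
        nterm_protect <- c(nterm_protect, 16:18)
      }
      if (grp == "A") {
        chars[31] <- sample(c("D", "E"), 1)
        chars[33] <- sample(c("E", "D"), 1)
        nterm_protect <- c(nterm_protect, 31:33)
      }
      # repairs mutate to Leu, which can neither create a Gly/Cys
      # N-terminal site nor satisfy a D/E or donor check
      chars <- repair_spurious_hands(chars, hand_positions,
                                     nterm_protect)
      list(sequence = paste(chars, collapse = ""), group = grp,
           canonical = canon, myr = myr_pos, palm = palm_pos)
    })
    ids <- sprintf("synthetic_cbl_%03d", seq_len(n_proteins))
    records <- protein_records(
      ids, vapply(built, `[[`, character(1), "sequence"),
      genus = "Synthetica", species_epithet = "exemplaris")
    truth <- tibble::tibble(
      record_id = ids,
      group = groups,
      hand_starts = rep(list(hand_positions), n_proteins),
      hands_canonical = purrr::map(built, "canonical"),
      myristoylation_position =
        vapply(built, `[[`, integer(1), "myr"),
      palmitoylation_position =
        vapply(built, `[[`, integer(1), "palm"))
    list(records = records, truth = truth)
  })
}

#' Generate an alignment with an exact number of segregating columns
#'
#' Builds `m` gap-free aligned sequences of `n` columns of which
#' exactly `S` are segregating (each carrying
#' `states_per_column` distinct residues). The truth diversity is
#' computed at generation time by an exhaustive loop over all sequence
#' pairs.
#'
#' @param m Number of sequences (>= 4).
#' @param n Number of columns.
#' @param S Number of segregating columns (<= n).
#' @param states_per_column Distinct residues per segregating column
#'   (default 2).
#' @param seed Integer seed.
#' @return A list: `block` (alignment tibble) and `truth` (one-row
#'   tibble `m`, `n`, `S`, `pi`).
#' @export
simulate_alignment <- function(m = 20, n = 100, S = 40,
                               states_per_column = 2, seed = 1L) {
  if (S > n) {
    abort("Cannot plant more segregating columns than columns.",
          class = "cblkit_spec_error")
  }
  if (m < 4) abort("Need at least 4 sequences.",
                   class = "cblkit_spec_error")
  with_local_seed(seed, {
    mat <- matrix(rep(sample_background(n), each = m), nrow = m)
    seg_cols <- if (S > 0) sample.int(n, S) else integer(0)
    for (col in seg_cols) {
      states <- sample(AA20, states_per_column)
      repeat {
        assign_idx <- sample.int(states_per_column, m, replace = TRUE)
        if (length(unique(assign_idx)) >= 2) break
      }
      mat[, col] <- states[assign_idx]
    }
    # exhaustive pairwise truth
    total <- 0; n_pairs <- 0
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        total <- total + sum(mat[i, ] != mat[j, ]) / n
        n_pairs <- n_pairs + 1
      }
    }
    block <- protein_records(
      sprintf("aln_seq_%03d", seq_len(m)),
      apply(mat, 1, paste, collapse = ""), aligned = TRUE)
    list(block = block,
         truth = tibble::tibble(m = m, n = n, S = S,
                                pi = total / n_pairs))
  })
}

#' Generate a three-sequence alignment with requested site patterns
#'
#' Plants exactly the requested numbers of identical, lineage-unique
#' and all-divergent columns (gap-free), then shuffles column order,
#' so [trio_counts()] on the output returns the request.
#'
#' @param unique_a,unique_b,unique_c Columns where only that sequence
#'   differs.
#' @param identical Columns identical in all three sequences.
#' @param divergent_all Columns where all three differ.
#' @param seed Integer seed.
#' @return An alignment tibble with members `seq_a`, `seq_b`, `seq_c`.
#' @export
simulate_trio <- function(unique_a = 0, unique_b = 0, unique_c = 0,
                          identical = 0, divergent_all = 0,
                          seed = 1L) {
  counts <- c(unique_a, unique_b, unique_c, identical, divergent_all)
  if (any(counts < 0)) {
    abort("Pattern counts must be non-negative.",
          class = "cblkit_spec_error")
  }
  n <- sum(counts)
  if (n == 0) abort("At least one column is required.",
                    class = "cblkit_spec_error")
  with_local_seed(seed, {
    cols <- matrix("", nrow = 3, ncol = n)
    kind <- rep(c("ua", "ub", "uc", "id", "div"), times = counts)
    kind <- sample(kind)
    for (j in seq_len(n)) {
      res <- sample(AA20, 3) # three distinct residues
      cols[, j] <- switch(kind[j],
        id = rep(res[1], 3),
        ua = c(res[2], res[1], res[1]),
        ub = c(res[1], res[2], res[1]),
        uc = c(res[1], res[1], res[2]),
        div = res)
    }
    protein_records(c("seq_a", "seq_b", "seq_c"),
                    apply(cols, 1, paste, collapse = ""),
                    aligned = TRUE)
  })
}

#' Generate a replicated qPCR Ct table with known fold changes
#'
#' Emulates a triplicate design: a reference gene plus target genes
#' measured under a calibrator and a treated condition. The treated
#' replicate dCt mean equals the calibrator dCt mean minus
#' log2(fold change); Gaussian noise of `noise_sd` cycles is added to
#' each target Ct measurement. With `noise_sd = 0` the estimated RQ
#' equals the planted fold change exactly.
#'
#' @param genes Character vector of target gene names.
#' @param fold_changes Numeric vector (recycled over `genes`), > 0.
#' @param replicates Replicates per cell (>= 2, default 3).
#' @param noise_sd Ct noise standard deviation in cycles (default
#'   0.1).
#' @param seed Integer seed.
#' @param reference_gene,calibrator_condition,treated_condition,timepoint
#'   Labels used in the emitted table.
#' @return A list: `ct` (Ct table tibble) and `truth` (per gene:
#'   `gene`, `fold_change`).
#' @export
simulate_ct_table <- function(genes, fold_changes, replicates = 3,
                              noise_sd = 0.1, seed = 1L,
                              reference_gene = "reference",
                              calibrator_condition = "control",
                              treated_condition = "treated",
                              timepoint = "t1") {
  if (any(fold_changes <= 0)) {
    abort("Fold changes must be positive.",
          class = "cblkit_spec_error")
  }
  if (replicates < 2) {
    abort("At least 2 replicates are required.",
          class = "cblkit_spec_error")
  }
  fold_changes <- rep_len(fold_changes, length(genes))
  with_local_seed(seed, {
    ref_ct <- 18
    base_dct <- setNames(runif(length(genes), 3, 7), genes)
    rows <- list()
    for (cond in c(calibrator_condition, treated_condition)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = reference_gene, condition = cond,
        timepoint = timepoint, replicate = seq_len(replicates),
        ct = ref_ct)
      for (k in seq_along(genes)) {
        shift <- if (cond == treated_condition)
          -log2(fold_changes[k]) else 0
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = genes[k], condition = cond, timepoint = timepoint,
          replicate = seq_len(replicates),
          ct = ref_ct + base_dct[k] + shift +
            stats::rnorm(replicates, 0, noise_sd))
      }
    }
    list(ct = dplyr::bind_rows(rows),
         truth = tibble::tibble(gene = genes,
                                fold_change = fold_changes))
  })
}
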