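#' Validate a pipeline run configuration
#'
#' A run configuration is a plain named list (or a YAML file holding
#' one) with at least `fasta` (protein FASTA of the family to
#' characterize) and `out_dir`. Optional entries: `groups` (TSV
#' `record_id`, `group`), `refs_monocot` / `refs_other` (reference
#' FASTA files whose record ids end in their CBL number, e.g.
#' `OsCBL3`), `lineage` (TSV `genus`, `species_epithet`, `lineage`),
#' `alignment` (gapped family FASTA for the neutrality test), `trio`
#' (3-sequence gapped FASTA for the relative rate test),
#' `loop_min_donors`, `strict`, `seed`. Configurations round-trip
#' through YAML unchanged.
#'
#' @param config A named list or path to a YAML file.
#' @return The validated config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$fasta) || is.null(config$out_dir)) {
    abort("A run config needs at least `fasta` and `out_dir`.",
          class = "cblkit_config_error")
  }
  paths <- c("fasta", "groups", "refs_monocot", "refs_other",
             "lineage", "alignment", "trio")
  for (p in paths) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      abort(sprintf("Config path `%s` does not exist: %s",
                    p, config[[p]]),
            class = "cblkit_config_error")
    }
  }
  config$strict <- if (is.null(config$strict)) TRUE else config$strict
  config$loop_min_donors <-
    if (is.null(config$loop_min_donors)) 3L else
      as.integer(config$loop_min_donors)
  config$seed <- if (is.null(config$seed)) 1L else
    as.integer(config$seed)
  config
}

write_tsv_file <- function(x, path) {
  listish <- vapply(x, is.list, logical(1))
  for (col in names(x)[listish]) {
    x[[col]] <- vapply(x[[col]], paste, character(1), collapse = ",")
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_reference_fasta <- function(path) {
  recs <- read_fasta(path)
  num <- suppressWarnings(
    as.integer(stringr::str_match(recs$id, "([0-9]+)$")[, 2]))
  if (any(is.na(num))) {
    abort(sprintf(
      "Reference ids in %s must end in their CBL number.", path),
      class = "cblkit_config_error")
  }
  tibble::tibble(id = recs$id, cbl_number = num,
                 sequence = recs$sequence)
}

#' Run the end-to-end CBL characterization pipeline
#'
#' Stages: EF-hand scan and CBL classification; lipidation calls (plus
#' the group-level pattern check when group labels are supplied);
#' orthology-based naming (when reference sets and lineage labels are
#' supplied); family amino-acid composition and its association with
#' biosynthetic cost; Tajima's neutrality test (when a family
#' alignment is supplied) and the relative rate test (when a trio
#' alignment is supplied). Per-stage TSV tables and a machine-readable
#' JSON summary are written under `out_dir`; reruns with the same
#' config produce byte-identical output.
#'
#' @param config See [validate_run_config()].
#' @return Invisibly, a list with every stage result and
#'   `summary_path`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_fasta(config$fasta)
  if (nrow(records) == 0) {
    abort("Input FASTA holds no records.",
          class = "cblkit_config_error")
  }
  out <- list()

  out$classification <- classify_cbl(
    records, strict = config$strict,
    loop_min_donors = config$loop_min_donors)
  write_tsv_file(out$classification,
                 file.path(config$out_dir, "classification.tsv"))

  out$lipidation <- lipidation_calls(records)
  write_tsv_file(out$lipidation,
                 file.path(config$out_dir, "lipidation.tsv"))

  if (!is.null(config$groups)) {
    groups <- tibble::as_tibble(utils::read.delim(config$groups,
                                                  sep = "\t"))
    out$group_summary <- group_pattern_check(out$lipidation, groups)
    write_tsv_file(out$group_summary,
                   file.path(config$out_dir, "group_summary.tsv"))
  }

  if (!is.null(config$refs_monocot) && !is.null(config$refs_other) &&
      !is.null(config$lineage)) {
    lineage <- tibble::as_tibble(utils::read.delim(config$lineage,
                                                   sep = "\t"))
    out$names <- assign_names(
      records,
      refs_monocot = read_reference_fasta(config$refs_monocot),
      refs_other = read_reference_fasta(config$refs_other),
      lineage = lineage)
    write_tsv_file(out$names,
                   file.path(config$out_dir, "names.tsv"))
  }

  out$composition <- aa_composition(records)
  write_tsv_file(out$composition,
                 file.path(config$out_dir, "composition.tsv"))
  out$cost_association <- cost_abundance_association(out$composition)

  if (!is.null(config$alignment)) {
    block <- read_fasta(config$alignment, aligned = TRUE)
    out$tajima <- tajima_test(block)
  }
  if (!is.null(config$trio)) {
    trio <- read_fasta(config$trio, aligned = TRUE)
    out$relative_rate <- relative_rate_test(trio_counts(trio))
  }

  summary <- list(
    n_records = nrow(records),
    n_cbl = sum(out$classification$is_cbl),
    mean_hands = mean(out$classification$n_hands),
    frac_myristoylated = mean(out$lipidation$myristoylation),
    frac_canonical_palmitoylation =
      mean(out$lipidation$canonical_palmitoylation),
    cost_abundance_rho = out$cost_association$rho)
  if (!is.null(out$tajima)) {
    g <- glance(out$tajima)
    summary$tajima_d <- g$D
    summary$theta_per_site <- g$theta_per_site
  }
  if (!is.null(out$relative_rate)) {
    summary$relative_rate_chi2 <- out$relative_rate$chi2
    summary$relative_rate_p <- out$relative_rate$p
  }
  out$summary <- summary
  out$summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, out$summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}
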