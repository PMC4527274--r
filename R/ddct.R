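#' Relative expression by the 2^-ddCt (Livak) method
#'
#' For every target gene and (condition, timepoint) cell, replicate
#' dCt = Ct_target - Ct_reference is formed by pairing replicates with
#' the reference gene by replicate index; ddCt subtracts the mean dCt
#' of the gene's calibrator cell, and relative quantity RQ = 2^-ddCt.
#' The standard error is computed on the cycle scale (sample SD of
#' replicate dCt / sqrt(r)) and mapped onto RQ as 2^-(ddCt +/- SE);
#' significance comes from a two-sided Welch t-test of replicate dCt
#' against the calibrator's replicate dCt (`"*"` p < 0.05, `"**"`
#' p < 0.01, `"ns"` otherwise).
#'
#' @param ct A Ct table: columns `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct` (cycles, in (0, 45)).
#' @param reference_gene Name of the normalizer gene; it must be
#'   measured in every (condition, timepoint) cell.
#' @param calibrator_condition Condition used as calibrator.
#' @param calibrator_timepoint Optional: timepoint of the calibrator
#'   cell. If omitted and the calibrator condition holds a single
#'   timepoint, that one calibrates all cells; otherwise each cell is
#'   calibrated by the same timepoint under the calibrator condition.
#' @return A tibble per (gene, condition, timepoint):
#'   `n_replicates`, `mean_delta_ct`, `delta_delta_ct`, `rq`, `se`,
#'   `rq_lo`, `rq_hi`, `p_value`, `significance`,
#'   `too_few_replicates`. For every row `log2(rq) == -delta_delta_ct`
#'   exactly.
#' @export
relative_expression <- function(ct, reference_gene,
                                calibrator_condition,
                                calibrator_timepoint = NULL) {
  stopifnot(all(c("gene", "condition", "timepoint", "replicate", "ct")
                %in% names(ct)))
  if (any(ct$ct <= 0 | ct$ct >= 45)) {
    abort("Ct values must lie in (0, 45) cycles.")
  }
  ref <- ct[ct$gene == reference_gene,
            c("condition", "timepoint", "replicate", "ct")]
  if (nrow(ref) == 0) {
    abort(sprintf("Reference gene '%s' not found.", reference_gene),
          class = "cblkit_pairing_error")
  }
  names(ref)[names(ref) == "ct"] <- "ct_ref"
  targets <- ct[ct$gene != reference_gene, ]
  paired <- dplyr::left_join(
    targets, ref, by = c("condition", "timepoint", "replicate"))
  if (any(is.na(paired$ct_ref))) {
    bad <- paired[is.na(paired$ct_ref), ]
    abort(sprintf(
      "Reference gene missing for %s / %s / replicate %s.",
      bad$condition[1], bad$timepoint[1], bad$replicate[1]),
      class = "cblkit_pairing_error")
  }
  paired$delta_ct <- paired$ct - paired$ct_ref

  cal_tps <- unique(paired$timepoint[paired$condition ==
                                       calibrator_condition])
  if (length(cal_tps) == 0) {
    abort(sprintf("Calibrator condition '%s' not found.",
                  calibrator_condition),
          class = "cblkit_pairing_error")
  }
  single_cal_tp <- if (!is.null(calibrator_timepoint)) {
    calibrator_timepoint
  } else if (length(cal_tps) == 1) {
    cal_tps
  } else {
    NULL # per-timepoint calibration
  }

  cells <- paired |>
    dplyr::group_by(.data$gene, .data$condition, .data$timepoint) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_delta_ct = mean(.data$delta_ct),
      sd_delta_ct = if (dplyr::n() >= 2) sd(.data$delta_ct) else NA_real_,
      delta_ct_reps = list(.data$delta_ct),
      .groups = "drop")

  cal_for <- function(gene, timepoint) {
    tp <- if (is.null(single_cal_tp)) timepoint else single_cal_tp
    hit <- cells$gene == gene &
      cells$condition == calibrator_condition & cells$timepoint == tp
    if (!any(hit)) {
      abort(sprintf(
        "No calibrator cell for gene '%s' (condition '%s', timepoint '%s').",
        gene, calibrator_condition, tp),
        class = "cblkit_pairing_error")
    }
    cells[which(hit)[1], ]
  }

  rows <- purrr::map(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    cal <- cal_for(cell$gene, cell$timepoint)
    ddct <- cell$mean_delta_ct - cal$mean_delta_ct
    rq <- 2^(-ddct)
    se <- if (cell$n_replicates >= 2) {
      cell$sd_delta_ct / sqrt(cell$n_replicates)
    } else NA_real_
    is_cal_cell <- cell$condition == calibrator_condition &&
      cell$timepoint == cal$timepoint
    p <- NA_real_
    if (!is_cal_cell && cell$n_replicates >= 2 &&
        cal$n_replicates >= 2) {
      x <- cell$delta_ct_reps[[1]]
      y <- cal$delta_ct_reps[[1]]
      if (sd(c(x, y)) > 0) {
        p <- tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
      }
    }
    tibble::tibble(
      gene = cell$gene, condition = cell$condition,
      timepoint = cell$timepoint, n_replicates = cell$n_replicates,
      mean_delta_ct = cell$mean_delta_ct,
      delta_delta_ct = ddct, rq = rq, se = se,
      rq_lo = 2^(-(ddct + se)), rq_hi = 2^(-(ddct - se)),
      p_value = p,
      significance = if (is.na(p)) NA_character_ else
        if (p < 0.01) "**" else if (p < 0.05) "*" else "ns",
      too_few_replicates = cell$n_replicates < 2)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cbl_expression", class(out))
  out
}

#' Filter genes by qPCR primer efficiency
#'
#' Retains genes whose primer efficiency lies in the 90-105 percent
#' window, both bounds inclusive.
#'
#' @param eff A tibble with columns `gene` and `efficiency`
#'   (percent).
#' @param lower,upper Window bounds (defaults 90, 105).
#' @return The retained rows of `eff`.
#' @export
primer_efficiency_filter <- function(eff, lower = 90, upper = 105) {
  eff[eff$efficiency >= lower & eff$efficiency <= upper, ,
      drop = FALSE]
}

#' Plot relative expression with error bars and significance flags
#'
#' @param results A `cbl_expression` tibble from
#'   [relative_expression()].
#' @return A ggplot bar chart of RQ per gene, faceted by condition,
#'   with 2^-(ddCt +/- SE) error bars and asterisk annotations.
#' @export
plot_expression <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$timepoint, y = .data$rq,
                               fill = .data$gene)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rq_lo, ymax = .data$rq_hi),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$significance) |
                                    .data$significance == "ns",
                                  "", .data$significance),
                   y = .data$rq_hi),
      position = ggplot2::position_dodge(width = 0.9), vjust = -0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "Timepoint", y = expression(2^{-Delta*Delta*C[t]}),
                  fill = "Gene") +
    ggplot2::theme_minimal()
}
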