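# Packaged per-residue reference data: published average amino-acid
# composition of plant CBL proteins (percent) and the biosynthetic
# energy cost of each amino acid (arbitrary high-energy-bond units),
# plus average residue masses (Da) and the EMBOSS pKa set.
aa_reference_data <- function() {
  tibble::tibble(
    residue = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
    name = c("Ala", "Cys", "Asp", "Glu", "Phe", "Gly", "His", "Ile",
             "Lys", "Leu", "Met", "Asn", "Pro", "Gln", "Arg", "Ser",
             "Thr", "Val", "Trp", "Tyr"),
    composition_pct = c(5.99, 1.27, 8.07, 8.94, 7.97, 3.96, 2.12,
                        6.25, 7.03, 10.84, 2.24, 3.79, 3.29, 2.89,
                        4.54, 7.18, 4.75, 6.19, 0.62, 1.98),
    energy_cost = c(11.7, 24.7, 12.7, 15.3, 52.0, 11.7, 38.3, 32.3,
                    30.3, 27.3, 34.3, 14.7, 20.3, 16.3, 27.3, 11.7,
                    18.7, 23.3, 74.3, 50.0)
  )
}

AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

# EMBOSS pKa values for ionizable groups.
PKA_EMBOSS <- c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5,
                H = 6.5, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Packaged amino-acid biosynthetic cost table
#'
#' @return A 20-row tibble: `residue`, `name`, `energy_cost`
#'   (biosynthetic cost per residue, high-energy-bond units). Swap in
#'   a custom table anywhere a `costs` argument is accepted.
#' @export
cbl_cost_table <- function() {
  aa_reference_data()[, c("residue", "name", "energy_cost")]
}

#' Reference average composition of CBL proteins
#'
#' @return A 20-row tibble: `residue`, `name`, `composition_pct` —
#'   the published family-average composition used as the default
#'   background distribution of the synthetic family generator.
#' @export
cbl_reference_composition <- function() {
  aa_reference_data()[, c("residue", "name", "composition_pct")]
}

#' Average amino-acid composition of a protein set
#'
#' Per-protein residue percentages (summing to exactly 100 for every
#' protein) averaged with equal weight per protein, so long proteins
#' do not dominate the family average.
#'
#' @param records A record tibble (>= 1 row).
#' @return A 20-row tibble: `residue`, `percent`; attribute
#'   `n_proteins`.
#' @export
aa_composition <- function(records) {
  if (nrow(records) == 0) {
    abort("Composition of an empty record set is undefined.")
  }
  per_protein <- purrr::map(records$sequence, function(seq) {
    chars <- seq_chars(toupper(seq))
    100 * vapply(AA20, function(a) mean(chars == a), numeric(1))
  })
  avg <- Reduce(`+`, per_protein) / length(per_protein)
  out <- tibble::tibble(residue = AA20, percent = unname(avg))
  attr(out, "n_proteins") <- nrow(records)
  out
}

#' Association between residue abundance and biosynthetic cost
#'
#' Spearman rank correlation across the 20 residues between average
#' abundance and per-residue biosynthetic cost (ties take average
#' ranks). Costly residues such as Trp are scarce in CBL proteins, so
#' the expected sign is negative. Being rank-based, the result is
#' invariant to any strictly monotone transform of the costs.
#'
#' @param comp Output of [aa_composition()] (columns `residue`,
#'   `percent`).
#' @param costs A cost table as from [cbl_cost_table()].
#' @return A list of class `cbl_cost_assoc`: `rho` (Spearman
#'   correlation, `NA` when a variable has zero variance), `method`,
#'   and `pairs`, the 20-row paired tibble.
#' @export
cost_abundance_association <- function(comp, costs = cbl_cost_table()) {
  pairs <- dplyr::inner_join(comp, costs, by = "residue")
  if (nrow(pairs) != 20) {
    abort("All 20 residues must be present in both tables.")
  }
  rho <- if (sd(pairs$percent) == 0 || sd(pairs$energy_cost) == 0) {
    NA_real_
  } else {
    cor(pairs$percent, pairs$energy_cost, method = "spearman")
  }
  structure(list(rho = rho, method = "spearman", pairs = pairs),
            class = "cbl_cost_assoc")
}

#' @export
print.cbl_cost_assoc <- function(x, ...) {
  cat(sprintf(
    "Abundance vs biosynthetic cost over 20 residues: Spearman rho = %s\n",
    if (is.na(x$rho)) "undefined (zero variance)" else
      sprintf("%.3f", x$rho)))
  invisible(x)
}

#' Plot residue abundance against biosynthetic cost
#'
#' @param assoc A `cbl_cost_assoc` object.
#' @return A ggplot scatter of percent abundance vs energy cost with
#'   residue labels.
#' @export
plot_cost_abundance <- function(assoc) {
  ggplot2::ggplot(assoc$pairs,
                  ggplot2::aes(x = .data$energy_cost,
                               y = .data$percent)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$name),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "Biosynthetic energy cost (units/residue)",
                  y = "Average abundance (%)") +
    ggplot2::theme_minimal()
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, in kilodaltons.
#'
#' @param seq Character vector of amino-acid sequences.
#' @return Numeric vector of masses (kDa).
#' @examples
#' molecular_weight("G") # 0.07507 kDa
#' @export
molecular_weight <- function(seq) {
  vapply(seq, function(s) {
    chars <- seq_chars(toupper(s))
    if (length(chars) == 0 || !nzchar(s)) {
      abort("Cannot compute the mass of an empty sequence.")
    }
    validate_sequences("(input)", s)
    (sum(AA_RESIDUE_MASS[chars]) + WATER_MASS) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

protein_net_charge <- function(counts, n_term = 1, c_term = 1, pH,
                               pka = PKA_EMBOSS) {
  pos <- n_term / (1 + 10^(pH - pka[["Nterm"]])) +
    sum(vapply(c("K", "R", "H"), function(a) {
      counts[[a]] / (1 + 10^(pH - pka[[a]]))
    }, numeric(1)))
  neg <- c_term / (1 + 10^(pka[["Cterm"]] - pH)) +
    sum(vapply(c("D", "E", "C", "Y"), function(a) {
      counts[[a]] / (1 + 10^(pka[[a]] - pH))
    }, numeric(1)))
  pos - neg
}

#' Protein isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge (side chains D, E,
#' C, Y, H, K, R plus free termini) is zero, found by bisection on
#' \[0, 14\] to a tolerance of 1e-4. The pKa set defaults to the EMBOSS
#' values and can be replaced.
#'
#' @param seq Character vector of amino-acid sequences.
#' @param pka Named pKa vector with entries `Nterm`, `Cterm`, `K`,
#'   `R`, `H`, `D`, `E`, `C`, `Y`.
#' @return Numeric vector of pI values.
#' @export
isoelectric_point <- function(seq, pka = PKA_EMBOSS) {
  vapply(seq, function(s) {
    chars <- seq_chars(toupper(s))
    counts <- as.list(table(factor(chars, levels = AA20)))
    lo <- 0; hi <- 14
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (protein_net_charge(counts, pH = mid, pka = pka) > 0) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}
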