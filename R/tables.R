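#' Residue-level lookup tables for amphipathicity scoring
#'
#' Bundles the per-residue constants used throughout element detection and
#' scoring: a hydrophobicity scale (default Fauchere-Pliska, the scale used
#' by HELIQUEST-style helical-wheel analysis), the set of residues counted
#' as hydrophobic on the wheel face, the polar/negative set used by the
#' helix-break rule, formal side-chain charges at neutral pH, and the
#' Kyte-Doolittle hydropathy values backing the built-in disorder proxy.
#'
#' @param hydrophobicity named numeric vector over the 20 canonical one-letter
#'   codes. Defaults to the Fauchere-Pliska octanol/water scale.
#' @param face_set character vector of residues treated as hydrophobic when
#'   projected on the helical wheel. The default is every residue with a
#'   Fauchere-Pliska value above 0.25 excluding proline and glycine, which
#'   keeps the weakly hydrophobic alanine and threonine on the face.
#' @param polar_set residues counted by the "run of polar/negative residues"
#'   helix-break rule. Default: S, T, N, Q, C, H plus the negatives D, E.
#'   Positives and hydrophobics are excluded by construction.
#' @param charge named numeric vector of formal charges; default K=R=+1,
#'   D=E=-1, everything else (including histidine) 0.
#' @return an object of class `residue_tables` (a list with the four tables
#'   plus the Kyte-Doolittle scale).
#' @export
residue_tables <- function(hydrophobicity = NULL, face_set = NULL,
                           polar_set = NULL, charge = NULL) {
  hy <- if (is.null(hydrophobicity)) fauchere_pliska() else hydrophobicity
  stopifnot(all(AA20 %in% names(hy)))
  fs <- if (is.null(face_set)) {
    setdiff(names(hy)[hy > 0.25], c("P", "G"))
  } else toupper(face_set)
  ps <- if (is.null(polar_set)) c("S", "T", "N", "Q", "C", "H", "D", "E")
        else toupper(polar_set)
  ch <- if (is.null(charge)) {
    z <- stats::setNames(numeric(20), AA20)
    z[c("K", "R")] <- 1
    z[c("D", "E")] <- -1
    z
  } else charge
  stopifnot(all(AA20 %in% names(ch)))
  structure(
    list(hydrophobicity = hy[AA20], face_set = fs, polar_set = ps,
         charge = ch[AA20], kyte_doolittle = kyte_doolittle()),
    class = "residue_tables")
}

#' Canonical amino-acid alphabet
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Fauchere-Pliska side-chain hydrophobicity scale
#'
#' Octanol/water transfer free energies as used by HELIQUEST for mean
#' hydrophobicity and hydrophobic-moment calculations.
#' @return named numeric vector over the 20 canonical residues.
#' @export
fauchere_pliska <- function() {
  c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
    Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
    L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
    S = -0.04, T = 0.26, V = 1.22, W = 2.25, Y = 0.96)[AA20]
}

#' Kyte-Doolittle hydropathy scale
#' @return named numeric vector over the 20 canonical residues.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)[AA20]
}
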