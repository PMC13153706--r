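#' Residue property tables
#'
#' Fixed tables used throughout the physicochemical characterization:
#' average residue masses in Daltons, the mass of water, a
#' Bjellqvist-style pKa set (N-terminus, C-terminus and the ionizable
#' side chains of Asp, Glu, Cys, Tyr, His, Lys, Arg), and the
#' hydropathy sets used for composition counts. The hydrophobic set is
#' the eight residues Gly, Ala, Val, Leu, Pro, Met, Phe and Trp; the
#' hydrophilic set is the eleven residues Ser, Thr, Tyr, Cys, Asn, Gln,
#' Asp, Glu, Arg, Lys and His. Isoleucine belongs to neither set, so
#' hydropathy counts of an Ile-containing peptide do not sum to its
#' length.
#'
#' Average (not monoisotopic) masses are used because population-level
#' molecular-weight summaries of peptidomes are conventionally reported
#' on the average-mass scale.
#'
#' @param masses optional named replacement for the average residue
#'   mass table (Da).
#' @param pka optional named replacement for the pKa table; names
#'   `Nterm`, `Cterm`, `C`, `D`, `E`, `H`, `K`, `R`, `Y`.
#' @return a list with elements `masses`, `water`, `pka`,
#'   `hydrophobic`, `hydrophilic`.
#' @examples
#' tab <- residue_tables()
#' tab$masses[["G"]]
#' @export
residue_tables <- function(masses = NULL, pka = NULL) {
  default_masses <- c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
  )
  default_pka <- c(
    Nterm = 7.50, Cterm = 3.55,
    C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00, R = 12.00, Y = 10.00
  )
  if (!is.null(masses)) {
    stopifnot(all(AA_LETTERS %in% names(masses)))
    default_masses <- masses[AA_LETTERS]
  }
  if (!is.null(pka)) {
    stopifnot(all(names(default_pka) %in% names(pka)))
    default_pka <- pka[names(default_pka)]
  }
  hydrophobic <- c("G", "A", "V", "L", "P", "M", "F", "W")
  hydrophilic <- c("S", "T", "Y", "C", "N", "Q", "D", "E", "R", "K", "H")
  stopifnot(
    length(intersect(hydrophobic, hydrophilic)) == 0L,
    length(union(hydrophobic, hydrophilic)) == 19L,
    all(default_masses > 0)
  )
  list(masses = default_masses, water = 18.0153, pka = default_pka,
       hydrophobic = hydrophobic, hydrophilic = hydrophilic)
}
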