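# Standard average residue masses (Da): amino-acid residue = free amino acid
# minus one water. One water (18.0153 Da) is added back per chain.
AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MASS <- 18.0153
AVOGADRO <- 6.02214076e23

#' Human Abeta(1-40) sequence
#'
#' One-letter sequence of the 40-residue amyloid-beta peptide used as the
#' repeat unit of the tandem-dimer construct.
#' @return A length-one character string (40 residues).
#' @export
ab40_sequence <- function() {
  "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV"
}

#' Average molecular mass of a peptide sequence
#'
#' Sum of standard average residue masses plus one water (18.02 Da).
#' Average (not monoisotopic) masses are used throughout, the convention
#' under which the 101-residue tandem dimer weighs 10.0 kDa.
#'
#' @param sequence one-letter amino-acid string; only the 20 canonical
#'   letters are accepted.
#' @return Average mass, Da.
#' @examples
#' average_mass("G")  # 75.07 Da
#' @export
average_mass <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      nchar(sequence) == 0)
    stop("sequence must be a non-empty character string", call. = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(AA_RESIDUE_MASS))
  if (length(bad) > 0)
    stop("non-canonical residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
}

#' Build the tandem-dimer Abeta construct (dimAb)
#'
#' Assembles the engineered construct: an N-terminal methionine, an Ab40
#' unit, a (G4S)x4 linker, and a second Ab40 unit — 101 residues, average
#' mass 10.03 kDa.
#'
#' @return An object of class `peptide_construct` with fields `name`,
#'   `sequence`, `residue_count` and `average_mass` (Da).
#' @examples
#' dimab <- build_dimab()
#' dimab$residue_count          # 101
#' dimab$average_mass / 1000    # ~10.0 kDa
#' @export
build_dimab <- function() {
  seq <- paste0("M", ab40_sequence(),
                strrep("GGGGS", 4), ab40_sequence())
  peptide_construct("dimAb", seq)
}

#' Construct a peptide record from a sequence
#'
#' @param name construct name.
#' @param sequence one-letter amino-acid string.
#' @return An object of class `peptide_construct`.
#' @export
peptide_construct <- function(name, sequence) {
  mass <- average_mass(sequence)
  structure(list(name = name, sequence = sequence,
                 residue_count = nchar(sequence), average_mass = mass),
            class = "peptide_construct")
}

#' @export
print.peptide_construct <- function(x, ...) {
  cat(sprintf("Peptide construct '%s': %d residues, %.2f kDa (average mass)\n",
              x$name, x$residue_count, x$average_mass / 1000))
  invisible(x)
}

#' Read peptide constructs from a FASTA file
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return A list of `peptide_construct` objects.
#' @export
peptides_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required to read FASTA files",
         call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  mapply(peptide_construct, names(aas), as.character(aas),
         SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Oligomer stoichiometry from assembly and monomer masses
#'
#' @param assembly_mass assembly mass, kDa (or any unit shared with
#'   `monomer_mass`).
#' @param monomer_mass monomer mass, same unit.
#' @return List with `count` (nearest-integer chain count) and `ratio`
#'   (unrounded mass ratio).
#' @examples
#' oligomer_stoichiometry(62, build_dimab()$average_mass / 1000)$count  # 6
#' @export
oligomer_stoichiometry <- function(assembly_mass, monomer_mass) {
  if (!is.finite(assembly_mass) || assembly_mass <= 0 ||
      !is.finite(monomer_mass) || monomer_mass <= 0)
    stop("masses must be positive", call. = FALSE)
  ratio <- assembly_mass / monomer_mass
  list(count = as.integer(round(ratio)), ratio = ratio)
}

#' Convert between protein mass and enclosed volume
#'
#' Uses the average protein specific volume (0.714 ml/g) to convert a
#' molecular mass to the volume it occupies, the convention used to
#' threshold density maps: V\[A^3\] = m\[kDa\] * 1000 * v_bar / N_A * 1e24.
#'
#' @param value mass in kDa (`direction = "mass_to_volume"`) or volume in
#'   cubic Angstroms (`direction = "volume_to_mass"`). Positive.
#' @param direction conversion direction.
#' @param specific_volume protein specific volume, ml/g.
#' @return Volume (A^3) or mass (kDa).
#' @examples
#' mass_volume_convert(62, "mass_to_volume")  # ~7.35e4 A^3
#' @export
mass_volume_convert <- function(value,
                                direction = c("mass_to_volume",
                                              "volume_to_mass"),
                                specific_volume = 0.714) {
  direction <- match.arg(direction)
  if (!is.finite(value) || value <= 0)
    stop("value must be positive", call. = FALSE)
  if (!is.finite(specific_volume) || specific_volume <= 0)
    stop("specific_volume must be positive", call. = FALSE)
  # 1 kDa = 1000 g/mol; v_bar in cm^3/g; 1 cm^3 = 1e24 A^3
  a3_per_kda <- 1000 * specific_volume / AVOGADRO * 1e24
  switch(direction,
         mass_to_volume = value * a3_per_kda,
         volume_to_mass = value / a3_per_kda)
}

#' Mean molecule count in a vesicle
#'
#' N = C * V * N_A with C in uM (1e-6 mol/L) and V in um^3 (1e-15 L).
#' The endo-lysosomal benchmark 2.5 uM in 0.3 um^3 gives ~450 molecules.
#'
#' @param concentration_uM luminal concentration, uM; non-negative.
#' @param volume_um3 vesicle volume, um^3; positive.
#' @return Mean molecule count (real; no rounding).
#' @examples
#' vesicle_copy_number(2.5, 0.3)  # ~451.7
#' @export
vesicle_copy_number <- function(concentration_uM, volume_um3) {
  if (!is.finite(concentration_uM) || concentration_uM < 0)
    stop("concentration must be non-negative", call. = FALSE)
  if (!is.finite(volume_um3) || volume_um3 <= 0)
    stop("volume must be positive", call. = FALSE)
  concentration_uM * 1e-6 * volume_um3 * 1e-15 * AVOGADRO
}
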