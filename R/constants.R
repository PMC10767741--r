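## Physical constants and residue chemistry tables.
##
## All masses are monoisotopic, in Da, from the standard IUPAC atomic mass
## and isotopic composition tables. They are embedded here (and mirrored in
## inst/extdata/residue_masses.tsv) so the package is fully deterministic
## and never consults an external source.

#' Mass of a proton in Da (positive-mode ESI charging)
#' @export
PROTON_MASS <- 1.007276466

#' C13 - C12 mass spacing in Da; the spacing used for aggregated
#' isotopologue positions within an envelope.
#' @export
ISOTOPE_SPACING <- 1.0033548

MASS_WATER <- 18.0105646

## Monoisotopic element masses
ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.007825032,
  N = 14.003074005,
  O = 15.994914620,
  S = 31.972071000
)

## Natural isotopic abundances per element, indexed by nucleon offset
## j = 0, 1, 2, ... relative to the lightest isotope. Values are the IUPAC
## representative abundances. O-17/O-18 and the sulfur isotopes occupy
## offsets 1 and 2 (and 4 for S-36).
ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
)

## Residue elemental compositions (residue = amino acid minus water)
RESIDUE_COMPOSITION <- list(
  G = c(C = 2, H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

AMINO_ACIDS <- names(RESIDUE_COMPOSITION)

## The three basic residues; together with an unmodified N-terminus these
## are the protonatable basic sites counted throughout.
BASIC_RESIDUES <- c("R", "K", "H")
NONBASIC_AMINO_ACIDS <- setdiff(AMINO_ACIDS, BASIC_RESIDUES)

## Supported modifications: elemental deltas and placement rules.
## target "C"/"M" = residue-specific; "nterm" = peptide N-terminus.
MODIFICATIONS <- list(
  `carbamidomethyl-C` = list(target = "C",     delta = c(C = 2, H = 3, N = 1, O = 1, S = 0)),
  `oxidation-M`       = list(target = "M",     delta = c(C = 0, H = 0, N = 0, O = 1, S = 0)),
  `acetyl-Nterm`      = list(target = "nterm", delta = c(C = 2, H = 2, N = 0, O = 1, S = 0)),
  `NEM-C`             = list(target = "C",     delta = c(C = 6, H = 7, N = 1, O = 2, S = 0))
)

element_vector_mass <- function(counts) {
  sum(counts * ELEMENT_MASS[names(counts)])
}

#' Monoisotopic residue masses
#'
#' @param modified_c One of `"none"`, `"carbamidomethyl"`, `"nem"`; when not
#'   `"none"`, the C slot carries the corresponding fixed modification
#'   ("C*": the run's cysteine chemistry).
#' @return Named numeric vector of the 20 residue masses in Da.
#' @export
residue_masses <- function(modified_c = c("none", "carbamidomethyl", "nem")) {
  modified_c <- match.arg(modified_c)
  m <- vapply(RESIDUE_COMPOSITION, element_vector_mass, numeric(1))
  if (modified_c == "carbamidomethyl")
    m["C"] <- m["C"] + element_vector_mass(MODIFICATIONS[["carbamidomethyl-C"]]$delta)
  if (modified_c == "nem")
    m["C"] <- m["C"] + element_vector_mass(MODIFICATIONS[["NEM-C"]]$delta)
  m
}

#' Path to the residue/modification mass table shipped with the package
#'
#' A TSV resource mirroring the embedded constants, for external tooling.
#' @return File path.
#' @export
residue_mass_table_path <- function() {
  system.file("extdata", "residue_masses.tsv", package = "csdtools")
}
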