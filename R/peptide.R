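## Peptide parsing, elemental composition, monoisotopic mass, theoretical
## isotope envelopes, m/z prediction and basic-site counting.

#' Construct a peptide object
#'
#' @param sequence String over the 20 standard one-letter residues.
#' @param modifications Data frame with columns `pos` (integer residue index,
#'   or 0 for the N-terminus) and `name` (a supported modification name:
#'   `"carbamidomethyl-C"`, `"oxidation-M"`, `"acetyl-Nterm"`, `"NEM-C"`).
#' @param id Optional run-scoped identifier.
#' @return Object of class `peptide`.
#' @export
peptide <- function(sequence, modifications = NULL, id = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a single non-empty string")
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, AMINO_ACIDS)
  if (length(bad))
    stop(sprintf("unknown residue letter '%s' in '%s'", bad[1], sequence))
  if (is.null(modifications))
    modifications <- data.frame(pos = integer(0), name = character(0),
                                stringsAsFactors = FALSE)
  modifications <- as.data.frame(modifications, stringsAsFactors = FALSE)
  stopifnot(all(c("pos", "name") %in% names(modifications)))
  for (i in seq_len(nrow(modifications))) {
    nm <- modifications$name[i]
    pos <- modifications$pos[i]
    spec <- MODIFICATIONS[[nm]]
    if (is.null(spec))
      stop(sprintf("unknown modification '%s'", nm))
    if (spec$target == "nterm") {
      if (pos != 0L) stop(sprintf("'%s' must be placed at the N-terminus (pos 0)", nm))
    } else {
      if (pos < 1L || pos > length(residues))
        stop(sprintf("modification position %d outside sequence", pos))
      if (residues[pos] != spec$target)
        stop(sprintf("'%s' only valid on %s (found %s at %d)",
                     nm, spec$target, residues[pos], pos))
    }
  }
  structure(list(sequence = sequence, residues = residues,
                 modifications = modifications, id = id),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide>", write_peptide(x), "\n")
  invisible(x)
}

## Token map for MaxQuant-style modified sequence strings.
MOD_TOKENS <- c(`ac` = "acetyl-Nterm", `ox` = "oxidation-M",
                `cam` = "carbamidomethyl-C", `nem` = "NEM-C")

#' Parse a (possibly modified) peptide sequence string
#'
#' Accepts plain sequences (`"TNSTFNQVVLKR"`) and MaxQuant-style modified
#' strings with underscore delimiters and parenthesised lowercase tokens,
#' e.g. `"_(ac)PEPTM(ox)IDEK_"`. Supported tokens: `(ac)` N-terminal
#' acetylation, `(ox)` methionine oxidation, `(cam)` carbamidomethyl
#' cysteine, `(nem)` N-ethylmaleimide cysteine.
#'
#' @param text Modified-sequence string.
#' @param id Optional run-scoped identifier.
#' @return A [peptide()] object. `parse_peptide()` and [write_peptide()] are
#'   inverse up to the canonical form.
#' @export
parse_peptide <- function(text, id = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("text must be a single non-empty string")
  s <- gsub("^_|_$", "", text)
  seq_chars <- character(0)
  mods <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      close <- regexpr(")", substr(s, i, n), fixed = TRUE)
      if (close < 0) stop(sprintf("unbalanced '(' in '%s'", text))
      token <- substr(s, i + 1L, i + close - 2L)
      name <- MOD_TOKENS[token]
      if (is.na(name)) stop(sprintf("unknown modification token '(%s)' in '%s'", token, text))
      pos <- if (MODIFICATIONS[[name]]$target == "nterm") {
        if (length(seq_chars) != 0L)
          stop(sprintf("'(%s)' must precede the first residue in '%s'", token, text))
        0L
      } else {
        if (length(seq_chars) == 0L)
          stop(sprintf("'(%s)' must follow a residue in '%s'", token, text))
        length(seq_chars)
      }
      mods[[length(mods) + 1L]] <- data.frame(pos = pos, name = unname(name),
                                              stringsAsFactors = FALSE)
      i <- i + close
    } else {
      if (!ch %in% AMINO_ACIDS)
        stop(sprintf("unknown residue letter '%s' in '%s'", ch, text))
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  if (length(seq_chars) == 0L) stop(sprintf("no residues in '%s'", text))
  modifications <- if (length(mods)) do.call(rbind, mods) else NULL
  peptide(paste(seq_chars, collapse = ""), modifications, id = id)
}

#' Write a peptide back to its canonical modified-sequence string
#'
#' @param p A [peptide()].
#' @return String such that `parse_peptide(write_peptide(p))` equals `p`.
#' @export
write_peptide <- function(p) {
  stopifnot(inherits(p, "peptide"))
  mods <- p$modifications
  tokens <- names(MOD_TOKENS)[match(mods$name, MOD_TOKENS)]
  out <- character(0)
  nt <- mods$pos == 0L
  if (any(nt)) out <- paste0("(", tokens[nt], ")")
  for (i in seq_along(p$residues)) {
    out <- c(out, p$residues[i])
    here <- which(mods$pos == i)
    if (length(here)) out <- c(out, paste0("(", tokens[here], ")"))
  }
  body <- paste(out, collapse = "")
  if (nrow(mods)) paste0("_", body, "_") else body
}

#' Elemental composition and monoisotopic mass of a peptide
#'
#' Sums residue compositions, adds one water, and applies modification
#' deltas.
#'
#' @param p A [peptide()].
#' @return List with `composition` (named integer vector over C,H,N,O,S)
#'   and `mass` (monoisotopic, Da).
#' @export
composition_and_mass <- function(p) {
  stopifnot(inherits(p, "peptide"))
  comp <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # water
  for (r in p$residues) comp <- comp + RESIDUE_COMPOSITION[[r]]
  for (nm in p$modifications$name) comp <- comp + MODIFICATIONS[[nm]]$delta
  list(composition = comp, mass = element_vector_mass(comp))
}

#' @rdname composition_and_mass
#' @export
peptide_mass <- function(p) composition_and_mass(p)$mass

#' Count a peptide's basic sites
#'
#' Basic sites are arginine, lysine and histidine residues plus an
#' unmodified (non-acetylated) N-terminus.
#'
#' @param p A [peptide()].
#' @return Non-negative integer count.
#' @export
count_basic_sites <- function(p) {
  stopifnot(inherits(p, "peptide"))
  n <- sum(p$residues %in% BASIC_RESIDUES)
  if (!any(p$modifications$name == "acetyl-Nterm")) n <- n + 1L
  as.integer(n)
}

#' Theoretical isotope envelope of an elemental composition
#'
#' Computes the aggregated isotopologue distribution (probability per
#' nucleon offset j = 0, 1, 2, ...) by iterated convolution of the
#' per-element natural isotope distributions, truncated to the minimal
#' length whose omitted tail mass is below `tail_cutoff`, then
#' renormalized.
#'
#' @param composition Named non-negative integer vector over C,H,N,O,S.
#' @param tail_cutoff Maximum truncated tail probability (default `1e-4`).
#' @return Numeric vector of relative abundances summing to 1.
#' @export
isotope_envelope <- function(composition, tail_cutoff = 1e-4) {
  stopifnot(tail_cutoff > 0, tail_cutoff < 1)
  if (any(composition < 0)) stop("negative element count")
  dist <- 1.0
  for (el in names(composition)) {
    n <- composition[[el]]
    if (n == 0) next
    base <- ELEMENT_ISOTOPES[[el]]
    if (is.null(base)) stop(sprintf("no isotope table for element '%s'", el))
    dist <- convolve_dist(dist, dist_power(base, n, tail_cutoff * 1e-3),
                          tail_cutoff * 1e-3)
  }
  ## minimal truncation: keep the shortest prefix with tail < tail_cutoff
  cum <- cumsum(dist)
  j <- which(1 - cum < tail_cutoff)[1]
  dist <- dist[seq_len(j)]
  dist / sum(dist)
}

## distribution convolution with hard tail trim (keeps vectors short)
convolve_dist <- function(a, b, trim) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  cum <- cumsum(out)
  j <- which(1 - cum < trim)[1]
  if (is.na(j)) j <- n
  out[seq_len(j)]
}

## n-fold self-convolution by binary exponentiation
dist_power <- function(base, n, trim) {
  result <- 1.0
  sq <- base
  while (n > 0) {
    if (n %% 2 == 1) result <- convolve_dist(result, sq, trim)
    n <- n %/% 2
    if (n > 0) sq <- convolve_dist(sq, sq, trim)
  }
  result
}

#' m/z of an isotopologue peak
#'
#' Standard positive-mode relation: `(mass + k * proton + j * spacing) / k`.
#'
#' @param mass Monoisotopic mass, Da.
#' @param k Charge (1..5).
#' @param j Isotope index (0 = monoisotopic).
#' @return m/z in Th. Strictly decreasing in `k`.
#' @export
envelope_mz <- function(mass, k, j = 0) {
  if (any(k < 1)) stop("charge k must be >= 1")
  if (any(j < 0)) stop("isotope index j must be >= 0")
  if (any(mass <= 0)) stop("mass must be positive")
  (mass + k * PROTON_MASS + j * ISOTOPE_SPACING) / k
}
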