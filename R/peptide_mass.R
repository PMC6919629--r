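# Peptide mass arithmetic: residue tables, modification deltas, tryptic
# digestion and b/y fragment ions. Neutral monoisotopic masses are the
# internal currency; m/z appears only in fragment_series().

# Elemental composition (C, H, N, O, S) of the 20 canonical residues.
.residue_elements <- local({
  m <- rbind(
    G = c(2,  3, 1, 1, 0),
    A = c(3,  5, 1, 1, 0),
    S = c(3,  5, 1, 2, 0),
    P = c(5,  7, 1, 1, 0),
    V = c(5,  9, 1, 1, 0),
    T = c(4,  7, 1, 2, 0),
    C = c(3,  5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4,  6, 2, 2, 0),
    D = c(4,  5, 1, 3, 0),
    Q = c(5,  8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5,  7, 1, 3, 0),
    M = c(5,  9, 1, 1, 1),
    H = c(6,  7, 3, 1, 0),
    F = c(9,  9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9,  9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

# Monoisotopic atomic masses (Da) and IUPAC 2021 standard atomic weights.
.element_mono <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)
.element_avg  <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

.mass_constants <- list(
  water_mono  = sum(.element_mono[c("H", "H", "O")]),
  water_avg   = sum(.element_avg[c("H", "H", "O")]),
  proton      = 1.00727646688,
  # C-terminal amide: -OH replaced by -NH2
  amide_mono  = unname(.element_mono["N"] + .element_mono["H"] - .element_mono["O"]),
  amide_avg   = unname(.element_avg["N"] + .element_avg["H"] - .element_avg["O"])
)

.residue_mono <- drop(.residue_elements %*% .element_mono)
.residue_avg  <- drop(.residue_elements %*% .element_avg)

#' Residue mass table
#'
#' Monoisotopic and average residue (i.e. dehydrated amino-acid) masses used
#' throughout the package, together with the water and proton constants.
#'
#' @return A data.frame with one row per canonical residue and columns
#'   `residue`, `mono`, `average`, plus attributes `water_mono`,
#'   `water_average` and `proton`.
#' @examples
#' residue_mass_table()["G", "mono"]  # 57.02146
#' @export
residue_mass_table <- function() {
  out <- data.frame(residue = names(.residue_mono),
                    mono = unname(.residue_mono),
                    average = unname(.residue_avg))
  rownames(out) <- out$residue
  attr(out, "water_mono") <- .mass_constants$water_mono
  attr(out, "water_average") <- .mass_constants$water_avg
  attr(out, "proton") <- .mass_constants$proton
  out
}

.check_sequence_for_mass <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(.residue_mono))
  if (length(bad) > 0L)
    stop("mass undefined for residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  aa
}

.known_modifications <- c("C_TERM_AMIDE", "C_TERM_GLY_LOSS_AMIDE",
                          "CARBAMIDOMETHYL_C", "PROPIONAMIDE_C")

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water, with optional modifications. The
#' `C_TERM_GLY_LOSS_AMIDE` modification models the mass-spectrometric
#' "Gly-loss + amide" dynamic modification: it may only be applied to a
#' peptide whose database form ends in glycine, and yields the mass of the
#' des-Gly peptide with an amidated C terminus.
#'
#' @param sequence Peptide sequence (canonical residues only; `X` is
#'   rejected as mass-undefined).
#' @param modifications Character vector drawn from `"C_TERM_AMIDE"`,
#'   `"C_TERM_GLY_LOSS_AMIDE"`, `"CARBAMIDOMETHYL_C"`, `"PROPIONAMIDE_C"`,
#'   or `NULL` for the unmodified peptide. Cysteine modifications are
#'   fixed-per-Cys.
#' @param scale `"mono"` for monoisotopic or `"average"`. Average-scale
#'   results are reported to 2 decimals.
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("G")                                     # 75.03203
#' peptide_mass("VLYPNDPAAYAAYAPGTGGGATI",
#'              modifications = "C_TERM_AMIDE", scale = "average")
#' @export
peptide_mass <- function(sequence, modifications = NULL,
                         scale = c("mono", "average")) {
  scale <- match.arg(scale)
  aa <- .check_sequence_for_mass(sequence)
  if (!is.null(modifications)) {
    modifications <- as.character(modifications)
    bad <- setdiff(modifications, .known_modifications)
    if (length(bad) > 0L)
      stop("unknown modification(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if ("C_TERM_GLY_LOSS_AMIDE" %in% modifications &&
        aa[length(aa)] != "G")
      stop("C_TERM_GLY_LOSS_AMIDE applies only to peptides ending in G",
           call. = FALSE)
    if (all(c("C_TERM_AMIDE", "C_TERM_GLY_LOSS_AMIDE") %in% modifications))
      stop("C_TERM_AMIDE and C_TERM_GLY_LOSS_AMIDE are mutually exclusive",
           call. = FALSE)
  }
  res <- if (scale == "mono") .residue_mono else .residue_avg
  water <- if (scale == "mono") .mass_constants$water_mono else .mass_constants$water_avg
  mass <- sum(res[aa]) + water
  for (mod in modifications) {
    mass <- mass + switch(mod,
      C_TERM_AMIDE = if (scale == "mono") .mass_constants$amide_mono else .mass_constants$amide_avg,
      C_TERM_GLY_LOSS_AMIDE = gly_loss_amide_delta(scale),
      # iodoacetamide / acrylamide adducts on every cysteine
      CARBAMIDOMETHYL_C = sum(aa == "C") *
        (if (scale == "mono") 57.0214637 else 57.052),
      PROPIONAMIDE_C = sum(aa == "C") *
        (if (scale == "mono") 71.0371138 else 71.078)
    )
  }
  if (scale == "average") round(mass, 2) else mass
}

#' Mass delta of the Gly-loss + amide modification
#'
#' Loss of a C-terminal glycine residue combined with conversion of the
#' newly exposed C terminus to an amide:
#' delta = -(residue mass of G) + (NH2 - OH).
#'
#' @param scale `"mono"` or `"average"`.
#' @return Signed delta in Da (monoisotopic: -58.00548).
#' @export
gly_loss_amide_delta <- function(scale = c("mono", "average")) {
  scale <- match.arg(scale)
  if (scale == "mono")
    -(.residue_mono[["G"]]) + .mass_constants$amide_mono
  else
    -(.residue_avg[["G"]]) + .mass_constants$amide_avg
}

#' Relative mass match within a ppm tolerance
#'
#' @param observed,theoretical Positive neutral masses in Da (vectorized,
#'   recycled against each other).
#' @param tol_ppm Tolerance in parts per million (> 0).
#' @return A list with `match` (logical) and `error_ppm`
#'   (signed, observed - theoretical).
#' @export
ppm_match <- function(observed, theoretical, tol_ppm) {
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1L || tol_ppm <= 0)
    stop("tol_ppm must be a single positive number", call. = FALSE)
  if (any(observed <= 0) || any(theoretical <= 0))
    stop("masses must be positive", call. = FALSE)
  err <- (observed - theoretical) / theoretical * 1e6
  list(match = abs(err) <= tol_ppm, error_ppm = err)
}

#' Digestion configuration
#'
#' @param max_missed_cleavages Maximum number of internal (missed) cleavage
#'   sites per reported peptide (default 3, the Byonic search setting; the
#'   Mascot searches used 2).
#' @param suppress_KP Suppress cleavage when the residue following K/R is
#'   proline (standard trypsin rule; default `TRUE`).
#' @param min_length Minimum peptide length to report.
#' @export
digest_config <- function(max_missed_cleavages = 3L, suppress_KP = TRUE,
                          min_length = 1L) {
  stopifnot(max_missed_cleavages >= 0, min_length >= 1)
  list(max_missed_cleavages = as.integer(max_missed_cleavages),
       suppress_KP = isTRUE(suppress_KP),
       min_length = as.integer(min_length))
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R (optionally suppressed before proline) and
#' enumerates peptides carrying 0 .. `max_missed_cleavages` internal sites.
#' The 0-missed set partitions the sequence.
#'
#' @param sequence Protein or peptide sequence.
#' @param config A [digest_config()].
#' @return data.frame with 1-based closed `start`/`end`, `peptide` and
#'   `n_missed`, ordered by start then end.
#' @examples
#' tryptic_digest("PLVPAAAGRK", digest_config(max_missed_cleavages = 0))
#' @export
tryptic_digest <- function(sequence, config = digest_config()) {
  aa <- .check_valid_protein_sequence(sequence)
  n <- length(aa)
  # cleavage points: bond after position i
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (config$suppress_KP)
    cut_after <- cut_after[aa[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)   # peptide (i,j] between consecutive bounds
  nb <- length(bounds)
  out <- list()
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + config$max_missed_cleavages)
    for (j in (i + 1L):jmax) {
      s <- bounds[i] + 1L
      e <- bounds[j]
      if (e - s + 1L < config$min_length) next
      out[[length(out) + 1L]] <-
        data.frame(start = s, end = e,
                   peptide = paste(aa[s:e], collapse = ""),
                   n_missed = j - i - 1L)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(start = integer(), end = integer(),
                      peptide = character(), n_missed = integer())
  res[order(res$start, res$end), , drop = FALSE]
}

#' b/y fragment-ion m/z series
#'
#' b_i = (sum of first i residue masses) + proton; y_i = (sum of last i
#' residue masses) + water + proton, with the C-terminal amide delta added
#' to every y ion when `c_term_amidated`. Indices run 1 .. length-1.
#'
#' @param sequence Peptide sequence (length >= 2).
#' @param series `"b"` or `"y"`.
#' @param c_term_amidated Whether the peptide C terminus is an amide.
#' @param charge Positive integer charge state (default 1).
#' @return data.frame with `index`, `ion` (e.g. "y3") and `mz`.
#' @export
fragment_series <- function(sequence, series = c("b", "y"),
                            c_term_amidated = FALSE, charge = 1L) {
  series <- match.arg(series)
  aa <- .check_sequence_for_mass(sequence)
  n <- length(aa)
  if (n < 2L) stop("fragment series require a peptide of length >= 2",
                   call. = FALSE)
  if (!is.numeric(charge) || charge < 1) stop("charge must be >= 1",
                                              call. = FALSE)
  idx <- seq_len(n - 1L)
  if (series == "b") {
    neutral <- cumsum(.residue_mono[aa])[idx]
  } else {
    neutral <- cumsum(rev(.residue_mono[aa]))[idx] + .mass_constants$water_mono
    if (isTRUE(c_term_amidated)) neutral <- neutral + .mass_constants$amide_mono
  }
  mz <- (neutral + charge * .mass_constants$proton) / charge
  data.frame(index = idx, ion = paste0(series, idx), mz = unname(mz))
}
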