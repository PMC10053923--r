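# Accurate-mass arithmetic.
#
# Monoisotopic atomic masses (CODATA/AME reference values, >= 7 decimals).
# Carbon is exact by definition of the unified atomic mass unit.
MONOISOTOPIC_MASS <- c(
  C = 12,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# Mass of a proton (Da).  Adduct arithmetic uses the proton mass, not the
# hydrogen atom mass, and neglects the electron mass elsewhere: this is the
# convention that reproduces positive-mode [M+H]+ values to 4 decimals.
PROTON_MASS <- 1.00727646688

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas over C, H, N, O, S such as `"C21H20O10"`.
#'
#' @param formula Formula string.
#' @return Named integer vector of element counts (C, H, N, O, S).
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop_data("`formula` must be a single non-empty string.")
  }
  tokens <- stringr::str_match_all(formula, "([A-Z][a-z]?)(\\d*)")[[1L]]
  tokens <- tokens[nzchar(tokens[, 1L]), , drop = FALSE]
  if (paste0(tokens[, 1L], collapse = "") != formula) {
    stop_data("cannot parse formula '%s'.", formula)
  }
  counts <- setNames(rep(0L, length(MONOISOTOPIC_MASS)),
                     names(MONOISOTOPIC_MASS))
  for (i in seq_len(nrow(tokens))) {
    el <- tokens[i, 2L]
    if (!el %in% names(counts)) {
      stop_data("unknown element '%s' in formula '%s'.", el, formula)
    }
    k <- tokens[i, 3L]
    counts[el] <- counts[el] + if (nzchar(k)) as.integer(k) else 1L
  }
  counts
}

#' Monoisotopic mass of a neutral molecular formula
#'
#' @param formula Formula string (e.g. `"C28H24O14"`) or named count vector
#'   as returned by [parse_formula()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C21H20O10")  # 432.1056
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  bad <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(bad)) stop_data("unknown element symbol: %s", paste(bad, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_data("element counts must be non-negative integers.")
  }
  sum(MONOISOTOPIC_MASS[names(counts)] * counts)
}

#' Theoretical m/z of an electrospray adduct
#'
#' Supports the protonated and deprotonated molecules `[M+H]+` and `[M-H]-`,
#' the two adducts formed under the positive/negative ESI conditions this
#' pipeline targets.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), or a formula string.
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @return Theoretical m/z (Th).
#' @examples
#' adduct_mz("C21H20O10", "[M+H]+")  # 433.1129
#' @export
adduct_mz <- function(neutral_mass, adduct = c("[M+H]+", "[M-H]-")) {
  if (is.character(neutral_mass)) neutral_mass <- monoisotopic_mass(neutral_mass)
  neutral_mass <- check_number(neutral_mass, "neutral_mass", min = 0, strict = TRUE)
  adduct <- normalize_adduct(adduct[1L])
  switch(adduct,
    "[M+H]+" = neutral_mass + PROTON_MASS,
    "[M-H]-" = neutral_mass - PROTON_MASS
  )
}

normalize_adduct <- function(adduct) {
  a <- gsub("−|–", "-", adduct)  # unicode minus/dash
  if (!a %in% c("[M+H]+", "[M-H]-")) {
    stop_config("unsupported adduct label '%s' (use \"[M+H]+\" or \"[M-H]-\").",
                adduct)
  }
  a
}

default_adduct <- function(polarity) {
  switch(as.character(polarity),
         positive = , P = "[M+H]+",
         negative = , N = "[M-H]-",
         stop_config("polarity must be 'positive'/'P' or 'negative'/'N', got '%s'.",
                     polarity))
}

#' Relative mass error in parts per million
#'
#' @param observed,theoretical m/z values (Th); `theoretical` must be > 0.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop_data("theoretical m/z must be > 0.")
  1e6 * (observed - theoretical) / theoretical
}

#' Ring-and-double-bond equivalents of a CHNOS formula
#'
#' RDBE = C - H/2 + N/2 + 1 (oxygen and sulfur are divalent and do not
#' contribute).
#'
#' @param counts Named count vector or formula string.
#' @return RDBE (may be half-integral for odd H+N).
#' @export
rdbe <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  unname(counts["C"] - counts["H"] / 2 + counts["N"] / 2 + 1)
}

#' Predict molecular formulas for an accurate mass
#'
#' Exhaustively enumerates CHNOS formulas inside the elemental bounds, keeps
#' candidates whose theoretical adduct m/z falls within `tol_ppm` of the
#' query, and applies standard heuristic plausibility filters: H/C within
#' `hc_range`, O/C at most `oc_max`, and integral non-negative RDBE (required
#' for an even-electron `[M+H]+` / `[M-H]-` ion of a neutral molecule).
#' Candidates are ranked by absolute ppm error, ties broken by fewer total
#' atoms then alphabetical formula.
#'
#' @param mz Measured m/z (Th).
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @param tol_ppm Mass tolerance in ppm (default 3, the instrument gate).
#' @param bounds Named list of upper element bounds, e.g.
#'   `list(C = 50, H = 80, N = 5, O = 35, S = 2)`.  Lower bounds are 0.
#' @param hc_range Allowed H/C ratio interval (applied when C > 0).
#' @param oc_max Maximum O/C ratio (applied when C > 0).
#' @return Tibble of candidates: `formula`, element counts, `neutral_mass`,
#'   `theoretical_mz`, `ppm_error`, `rdbe`, sorted best-first.
#' @export
predict_formula <- function(mz, adduct = "[M+H]+", tol_ppm = 3,
                            bounds = list(C = 50, H = 80, N = 5, O = 35, S = 2),
                            hc_range = c(0.2, 3.1), oc_max = 1.2) {
  mz <- check_number(mz, "mz", min = 0, strict = TRUE)
  tol_ppm <- check_number(tol_ppm, "tol_ppm", min = 0, strict = TRUE)
  adduct <- normalize_adduct(adduct)
  b <- modifyList(list(C = 0, H = 0, N = 0, O = 0, S = 0), as.list(bounds))
  b <- vapply(b[names(MONOISOTOPIC_MASS)], function(x) as.integer(x), integer(1))
  if (all(b == 0L)) stop_config("empty constraint space: all element bounds are 0.")

  neutral <- if (adduct == "[M+H]+") mz - PROTON_MASS else mz + PROTON_MASS
  tol_da <- mz * tol_ppm * 1e-6

  # enumerate C/N/O/S and solve for the feasible H count(s) directly
  grid <- expand.grid(C = 0:b["C"], N = 0:b["N"], O = 0:b["O"], S = 0:b["S"])
  base_mass <- grid$C * MONOISOTOPIC_MASS["C"] + grid$N * MONOISOTOPIC_MASS["N"] +
    grid$O * MONOISOTOPIC_MASS["O"] + grid$S * MONOISOTOPIC_MASS["S"]
  rem <- neutral - base_mass
  h_lo <- pmax(0L, ceiling((rem - tol_da) / MONOISOTOPIC_MASS["H"]))
  h_hi <- pmin(b["H"], floor((rem + tol_da) / MONOISOTOPIC_MASS["H"]))
  ok <- which(h_hi >= h_lo)
  if (!length(ok)) return(empty_formula_tibble())

  rows <- lapply(ok, function(i) {
    h <- seq.int(h_lo[i], h_hi[i])
    data.frame(C = grid$C[i], H = h, N = grid$N[i], O = grid$O[i], S = grid$S[i])
  })
  cand <- do.call(rbind, rows)
  cand$neutral_mass <- cand$C * MONOISOTOPIC_MASS["C"] +
    cand$H * MONOISOTOPIC_MASS["H"] + cand$N * MONOISOTOPIC_MASS["N"] +
    cand$O * MONOISOTOPIC_MASS["O"] + cand$S * MONOISOTOPIC_MASS["S"]
  cand$theoretical_mz <- cand$neutral_mass +
    if (adduct == "[M+H]+") PROTON_MASS else -PROTON_MASS
  cand$ppm_error <- ppm_error(mz, cand$theoretical_mz)
  cand$rdbe <- cand$C - cand$H / 2 + cand$N / 2 + 1

  keep <- abs(cand$ppm_error) <= tol_ppm &
    cand$rdbe >= 0 & abs(cand$rdbe - round(cand$rdbe)) < 1e-9 &
    (cand$C > 0) &
    (cand$H / cand$C >= hc_range[1L] & cand$H / cand$C <= hc_range[2L]) &
    (cand$O / cand$C <= oc_max)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_formula_tibble())

  cand$formula <- format_formula(cand)
  cand$n_atoms <- cand$C + cand$H + cand$N + cand$O + cand$S
  ord <- order(abs(cand$ppm_error), cand$n_atoms, cand$formula)
  out <- as_tibble(cand[ord, c("formula", "C", "H", "N", "O", "S",
                               "neutral_mass", "theoretical_mz",
                               "ppm_error", "rdbe")])
  out
}

empty_formula_tibble <- function() {
  tibble(formula = character(), C = integer(), H = integer(), N = integer(),
         O = integer(), S = integer(), neutral_mass = numeric(),
         theoretical_mz = numeric(), ppm_error = numeric(), rdbe = numeric())
}

format_formula <- function(df) {
  apply(df[, c("C", "H", "N", "O", "S")], 1L, function(v) {
    paste0(mapply(function(el, k) {
      if (k == 0) "" else if (k == 1) el else paste0(el, k)
    }, c("C", "H", "N", "O", "S"), v), collapse = "")
  })
}
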