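# Elemental-composition arithmetic and accurate-mass formula prediction.
#
# Compositions are named integer vectors keyed by element symbol ("element
# counts"); molecular formulas are their Hill-notation string form. All masses
# are monoisotopic, in Da.

# Monoisotopic masses of the most abundant isotope (IUPAC/CODATA).
.element_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

# Electron rest mass in Da; added once per negative charge so that the
# deprotonated ion of C15H12O7 prints 303.0510 at 4 dp.
.electron_mass <- 0.00054857990907

#' Parse a Hill-notation molecular formula
#'
#' Converts a formula string such as `"C15H12O7"` into a named integer vector
#' of element counts. An omitted count means 1 (`"C20H19NO13S"` has one N and
#' one S). Only elements with a packaged monoisotopic mass (C, H, N, O, P, S)
#' are accepted.
#'
#' @param text A single formula string.
#' @return A named integer vector of element counts, in Hill order.
#' @examples
#' parse_formula("C15H12O7")
#' parse_formula("C20H19NO13S")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("`text` must be a single non-empty formula string", call. = FALSE)
  }
  text <- gsub("−", "-", trimws(text))
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(text)) {
    stop("malformed formula: ", text, call. = FALSE)
  }
  els <- sub("[0-9]*$", "", matched)
  ns <- sub("^[A-Za-z]+", "", matched)
  ns <- ifelse(nzchar(ns), suppressWarnings(as.integer(ns)), 1L)
  bad <- setdiff(els, names(.element_masses))
  if (length(bad) > 0) {
    stop("unknown element symbol: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- stats::setNames(integer(length(.element_masses)),
                            names(.element_masses))
  for (i in seq_along(els)) counts[els[i]] <- counts[els[i]] + ns[i]
  counts <- counts[counts != 0L]
  if (length(counts) == 0L) stop("empty formula: ", text, call. = FALSE)
  counts[hill_order(names(counts))]
}

# Hill ordering: C first, H second, remaining elements alphabetical.
hill_order <- function(els) {
  order(match(els, c("C", "H"), nomatch = 3L), els)
}

#' Write element counts as a Hill-notation formula
#'
#' Inverse of [parse_formula()]: zero counts are dropped, a count of one is
#' implicit, elements appear in Hill order (C, H, then alphabetical).
#'
#' @param counts Named numeric vector of element counts (all non-negative).
#' @return A single formula string.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0) return("")
  if (any(counts < 0)) stop("negative element count", call. = FALSE)
  counts <- counts[hill_order(names(counts))]
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

# Coerce a formula string or counts vector to counts.
as_counts <- function(x) {
  if (is.character(x)) parse_formula(x) else x
}

# Signed element-count arithmetic; subtraction failing on negative counts is
# enforced by callers that require a physical composition.
counts_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[out != 0]
}

counts_subtract <- function(a, b, allow_negative = FALSE) {
  out <- counts_add(a, -b)
  if (!allow_negative && any(out < 0)) {
    stop("subtraction would give a negative element count", call. = FALSE)
  }
  out
}

#' Monoisotopic mass of a composition
#'
#' Sum of most-abundant-isotope masses over a composition. Vectorised over a
#' character vector of formulas. Additive under composition addition.
#'
#' @param x A formula string (or character vector of them), or a named counts
#'   vector as returned by [parse_formula()]. Signed counts are allowed so
#'   that reaction deltas can be weighed.
#' @return Numeric mass(es) in Da; the empty composition weighs 0.
#' @examples
#' monoisotopic_mass("H2O")      # 18.0106
#' monoisotopic_mass("C6H8O6")   # 176.0321, the glucuronyl mass shift
#' @export
monoisotopic_mass <- function(x) {
  if (is.character(x)) {
    return(vapply(x, function(f) counts_mass(parse_formula(f)), numeric(1),
                  USE.NAMES = FALSE))
  }
  counts_mass(x)
}

counts_mass <- function(counts) {
  if (length(counts) == 0) return(0)
  bad <- setdiff(names(counts), names(.element_masses))
  if (length(bad) > 0) {
    stop("unknown element symbol: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sum(.element_masses[names(counts)] * counts)
}

#' Supported adducts
#'
#' The two negative-mode ion species used throughout: the deprotonated
#' molecule `[M-H]-` and the ammonia-adduct anion `[M+NH2]-` (equivalently
#' written \eqn{[M+NH_3-H]^-}). Unicode minus signs in labels are tolerated.
#'
#' @return A tibble with columns `adduct`, `delta` (list of signed element
#'   counts), `charge`.
#' @export
adduct_table <- function() {
  tibble::tibble(
    adduct = c("[M-H]-", "[M+NH2]-"),
    delta = list(c(H = -1), c(N = 1, H = 2)),
    charge = c(-1L, -1L)
  )
}

normalize_adduct <- function(adduct) {
  a <- gsub("−", "-", adduct)
  a <- gsub("\\s", "", a)
  a <- sub("\\[M\\+NH3-H\\]-", "[M+NH2]-", a)
  tab <- adduct_table()
  if (!all(a %in% tab$adduct)) {
    stop("unsupported adduct: ", paste(setdiff(a, tab$adduct), collapse = ", "),
         call. = FALSE)
  }
  a
}

#' Theoretical m/z of a negative-mode ion
#'
#' Computes the ion m/z for a neutral composition under a supported adduct:
#' the neutral mass plus the adduct composition delta, plus one electron mass
#' per unit negative charge.
#'
#' @param x Formula string(s) or a named counts vector for the neutral
#'   molecule.
#' @param adduct Adduct label, `"[M-H]-"` (default) or `"[M+NH2]-"`; recycled
#'   against `x`.
#' @return Numeric m/z value(s) in Da (full precision; round to 4 dp for
#'   display).
#' @examples
#' ion_mz("C15H12O7")               # 303.0510, deprotonated taxifolin
#' ion_mz("C21H18O12", "[M+NH2]-")  # 478.0991
#' @export
ion_mz <- function(x, adduct = "[M-H]-") {
  if (!is.character(x)) x <- format_formula(x)
  n <- max(length(x), length(adduct))
  x <- rep_len(x, n)
  adduct <- normalize_adduct(rep_len(adduct, n))
  tab <- adduct_table()
  vapply(seq_len(n), function(i) {
    row <- match(adduct[i], tab$adduct)
    counts <- counts_add(parse_formula(x[i]), tab$delta[[row]])
    if (any(counts < 0)) {
      stop("adduct delta gives a negative composition for ", x[i],
           call. = FALSE)
    }
    counts_mass(counts) + abs(tab$charge[row]) * .electron_mass
  }, numeric(1))
}

#' Signed mass error in parts per million
#'
#' @param measured,predicted m/z values in Da; vectorised.
#' @return `(measured - predicted) / predicted * 1e6`, full precision (round
#'   to 2 dp for display).
#' @examples
#' ppm_error(303.0521, 303.0510)  # 3.63
#' @export
ppm_error <- function(measured, predicted) {
  if (any(predicted <= 0)) stop("`predicted` must be positive", call. = FALSE)
  (measured - predicted) / predicted * 1e6
}

#' Ring-plus-double-bond equivalents
#'
#' DBE of the neutral molecule: `C - H/2 + N/2 + 1`; divalent O and S do not
#' contribute. Half-integer values indicate a radical/ionic composition.
#'
#' @param x Formula string(s) or a named counts vector.
#' @return Numeric DBE value(s).
#' @examples
#' rdbe("C15H12O7")  # 10
#' @export
rdbe <- function(x) {
  if (is.character(x)) {
    return(vapply(x, function(f) rdbe(parse_formula(f)), numeric(1),
                  USE.NAMES = FALSE))
  }
  n <- function(el) if (el %in% names(x)) unname(x[[el]]) else 0
  n("C") - n("H") / 2 + n("N") / 2 + n("P") / 2 + 1
}

#' Predict molecular formulas from an accurate ion m/z
#'
#' Exhaustively enumerates elemental compositions within per-element bounds
#' whose theoretical ion m/z under `adduct` lies within `tol_ppm` of the
#' measurement, keeping only chemically plausible candidates (DBE >= 0).
#' Candidates are ordered by absolute ppm error, ties broken by lower DBE and
#' then by Hill-sorted formula, so the ranking is fully deterministic.
#'
#' The default tolerance (6 ppm) and bounds (C40 H60 N2 O18 S2) cover the
#' full mass-accuracy spread and elemental space of the taxifolin metabolite
#' tables, including dimer sulphates.
#'
#' @param mz Measured ion m/z in Da (single value).
#' @param adduct Adduct label, see [adduct_table()].
#' @param tol_ppm Mass tolerance in ppm (> 0).
#' @param bounds Named integer vector of per-element maximum counts.
#' @return A tibble with columns `formula`, `predicted_mz`, `ppm`, `dbe`,
#'   ordered best-first; zero rows when nothing falls inside the window.
#' @examples
#' predict_formulas(383.0082)  # taxifolin sulphate, C15H12O10S top-ranked
#' @export
predict_formulas <- function(mz, adduct = "[M-H]-", tol_ppm = 6,
                             bounds = c(C = 40, H = 60, N = 2, O = 18, S = 2)) {
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0)
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) {
    stop("`tol_ppm` must be > 0", call. = FALSE)
  }
  if (is.null(names(bounds)) || any(!nzchar(names(bounds)))) {
    stop("`bounds` must be a named vector of element maxima", call. = FALSE)
  }
  adduct <- normalize_adduct(adduct)
  tab <- adduct_table()
  delta <- tab$delta[[match(adduct, tab$adduct)]]

  # neutral-mass window implied by the ppm window on the ion
  target <- mz - counts_mass(delta) - .electron_mass
  lo <- (mz * (1 - tol_ppm * 1e-6)) - counts_mass(delta) - .electron_mass
  hi <- (mz * (1 + tol_ppm * 1e-6)) - counts_mass(delta) - .electron_mass

  bounds <- bounds[names(bounds) %in% names(.element_masses)]
  others <- setdiff(names(bounds), "H")
  grid <- expand.grid(lapply(bounds[others], function(b) 0:b))
  base <- as.numeric(as.matrix(grid) %*% .element_masses[others])
  m_h <- .element_masses[["H"]]
  h_max <- if ("H" %in% names(bounds)) bounds[["H"]] else 0L
  h_lo <- pmax(ceiling((lo - base) / m_h - 1e-12), 0L)
  h_hi <- pmin(floor((hi - base) / m_h + 1e-12), h_max)
  keep <- which(h_lo <= h_hi)
  if (length(keep) == 0) return(empty_candidates())

  n_h <- h_hi[keep] - h_lo[keep] + 1L
  idx <- rep(keep, n_h)
  h <- unlist(lapply(seq_along(keep), function(i) h_lo[keep[i]] + 0:(n_h[i] - 1L)))
  cand <- grid[idx, , drop = FALSE]
  cand$H <- h
  mass <- base[idx] + h * m_h
  pred <- mass + counts_mass(delta) + .electron_mass
  ppm <- ppm_error(mz, pred)
  dbe <- cand$C - cand$H / 2 +
    (if ("N" %in% names(cand)) cand$N else 0) / 2 +
    (if ("P" %in% names(cand)) cand$P else 0) / 2 + 1

  ok <- abs(ppm) <= tol_ppm + 1e-12 & dbe >= 0 & rowSums(cand) > 0
  # the ion must correspond to a real neutral molecule under this adduct
  if (any(ok)) {
    neutral_ok <- vapply(which(ok), function(i) {
      counts <- unlist(cand[i, ])
      all(counts_add(counts[counts != 0], delta) >= 0)
    }, logical(1))
    ok[which(ok)] <- neutral_ok
  }
  if (!any(ok)) return(empty_candidates())

  cand <- cand[ok, , drop = FALSE]
  formula <- vapply(seq_len(nrow(cand)), function(i) {
    counts <- unlist(cand[i, ])
    format_formula(counts[counts != 0])
  }, character(1))
  out <- tibble::tibble(
    formula = formula,
    predicted_mz = pred[ok],
    ppm = ppm[ok],
    dbe = dbe[ok]
  )
  out[order(abs(out$ppm), out$dbe, out$formula), ]
}

empty_candidates <- function() {
  tibble::tibble(formula = character(), predicted_mz = numeric(),
                 ppm = numeric(), dbe = numeric())
}
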