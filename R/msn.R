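# MS2/MS3 annotation: characteristic neutral losses, aglycone identification,
# reference fragment matching and dimer coupling-bond classification.

#' Characteristic conjugate neutral losses
#'
#' The diagnostic neutral losses that identify phase II conjugations in
#' negative-mode MS2: SO3 (79.9568 Da, sulphation), the glucuronyl residue
#' C6H8O6 (176.0321 Da, glucuronidation), pyroglutamic acid C5H7NO3
#' (129.0426 Da) and the acetylamino moiety C2H5NO (59.0371 Da). Matching is
#' always done against the full-precision masses; the 2-dp values are display
#' forms.
#'
#' @return A tibble with columns `loss`, `formula`, `mass`, `meaning` (the
#'   reaction each loss evidences).
#' @export
neutral_loss_defs <- function() {
  defs <- tibble::tibble(
    loss = c("SO3", "glucuronyl", "pyroglutamyl", "acetylamino"),
    formula = c("SO3", "C6H8O6", "C5H7NO3", "C2H5NO"),
    meaning = c("sulphation", "glucuronidation", "pyroglutamate_conjugation",
                "acetylamination")
  )
  defs$mass <- monoisotopic_mass(defs$formula)
  defs[c("loss", "formula", "mass", "meaning")]
}

#' Normalise a fragment list to base peak = 100
#'
#' @param fragments A tibble with columns `mz`, `rel_ab`.
#' @return The same tibble with `rel_ab` rescaled so the most intense
#'   fragment is exactly 100; empty input is returned unchanged.
#' @export
normalize_spectrum <- function(fragments) {
  if (is.null(fragments) || nrow(fragments) == 0) {
    return(tibble::tibble(mz = numeric(), rel_ab = numeric()))
  }
  if (any(fragments$rel_ab <= 0)) {
    stop("relative abundances must be positive", call. = FALSE)
  }
  fragments$rel_ab <- fragments$rel_ab / max(fragments$rel_ab) * 100
  fragments
}

#' Match characteristic neutral losses in a spectrum
#'
#' A loss matches a fragment when `|precursor - fragment - loss_mass|` is
#' within `tol_da`; each fragment is assigned at most one loss (the closest).
#'
#' @param precursor_mz Precursor ion m/z in Da.
#' @param fragments Fragment tibble `(mz, rel_ab)`.
#' @param losses Loss definitions, see [neutral_loss_defs()].
#' @param tol_da Absolute matching tolerance in Da (default 0.02).
#' @return A tibble with one row per matched fragment: `fragment_mz`,
#'   `rel_ab`, `loss`, `loss_mass`, `meaning`, `delta_da`.
#' @examples
#' frags <- tibble::tibble(mz = 383.0083, rel_ab = 100)
#' match_losses(512.0509, frags)   # pyroglutamic acid loss
#' @export
match_losses <- function(precursor_mz, fragments, losses = neutral_loss_defs(),
                         tol_da = 0.02) {
  stopifnot(tol_da > 0)
  empty <- tibble::tibble(fragment_mz = numeric(), rel_ab = numeric(),
                          loss = character(), loss_mass = numeric(),
                          meaning = character(), delta_da = numeric())
  if (is.null(fragments) || nrow(fragments) == 0) return(empty)
  rows <- lapply(seq_len(nrow(fragments)), function(i) {
    obs <- precursor_mz - fragments$mz[i]
    dev <- abs(obs - losses$mass)
    j <- which.min(dev)
    if (dev[j] > tol_da) return(NULL)
    tibble::tibble(fragment_mz = fragments$mz[i], rel_ab = fragments$rel_ab[i],
                   loss = losses$loss[j], loss_mass = losses$mass[j],
                   meaning = losses$meaning[j], delta_da = obs - losses$mass[j])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}

#' Identify the aglycone behind a conjugate spectrum
#'
#' Scans the reference library for an aglycone whose deprotonated ion matches
#' either a fragment (conjugate spectra) or the precursor itself
#' (unconjugated peaks) within `tol_da`. Among matching references the one
#' with the most co-matching characteristic fragments wins; an unresolved tie
#' returns no call with a warning.
#'
#' @param precursor_mz Precursor ion m/z.
#' @param fragments Fragment tibble `(mz, rel_ab)`; may be empty.
#' @param refs Aglycone library, see [aglycone_library()].
#' @param tol_da Matching tolerance in Da.
#' @return One-row tibble `(name, formula, aglycone_mz, matched_by,
#'   n_char_matched)` or a zero-row tibble when no reference matches.
#' @export
identify_aglycone <- function(precursor_mz, fragments,
                              refs = aglycone_library(), tol_da = 0.02) {
  stopifnot(nrow(refs) > 0)
  if (is.null(fragments)) fragments <- tibble::tibble(mz = numeric(),
                                                      rel_ab = numeric())
  hits <- lapply(seq_len(nrow(refs)), function(i) {
    amz <- refs$aglycone_mz[i]
    frag_hit <- nrow(fragments) > 0 && any(abs(fragments$mz - amz) <= tol_da)
    prec_hit <- abs(precursor_mz - amz) <= tol_da
    if (!frag_hit && !prec_hit) return(NULL)
    nmatch <- 0L
    ref_frags <- refs$fragments[[i]]
    if (nrow(fragments) > 0 && nrow(ref_frags) > 0) {
      nmatch <- sum(vapply(ref_frags$mz, function(m) {
        any(abs(fragments$mz - m) <= tol_da)
      }, logical(1)))
    }
    tibble::tibble(name = refs$name[i], formula = refs$formula[i],
                   aglycone_mz = amz,
                   matched_by = if (frag_hit) "fragment" else "precursor",
                   n_char_matched = nmatch)
  })
  hits <- dplyr::bind_rows(hits[!vapply(hits, is.null, logical(1))])
  if (nrow(hits) == 0) return(hits)
  best <- hits[hits$n_char_matched == max(hits$n_char_matched), , drop = FALSE]
  if (nrow(best) > 1) {
    warning("ambiguous aglycone match (", paste(best$name, collapse = ", "),
            "); no call made", call. = FALSE)
    return(hits[0, , drop = FALSE])
  }
  best
}

#' Fraction of reference fragments observed
#'
#' @param fragments Observed fragment tibble `(mz, rel_ab)`.
#' @param ref One row of the aglycone library (with a `fragments`
#'   list-column), or a fragment tibble of reference m/z values.
#' @param tol_da Matching tolerance in Da.
#' @return Matched reference fragments / total reference fragments, in
#'   `[0, 1]`; 0 for an empty observed spectrum.
#' @export
fragment_match_score <- function(fragments, ref, tol_da = 0.02) {
  ref_frags <- if (is.data.frame(ref) && "fragments" %in% names(ref)) {
    ref$fragments[[1]]
  } else {
    ref
  }
  if (is.null(ref_frags) || nrow(ref_frags) == 0) {
    stop("reference has no characteristic fragments", call. = FALSE)
  }
  if (is.null(fragments) || nrow(fragments) == 0) return(0)
  matched <- vapply(ref_frags$mz, function(m) {
    any(abs(fragments$mz - m) <= tol_da)
  }, logical(1))
  mean(matched)
}

#' Classify a dimer's coupling bond from its MS2
#'
#' In the MS2 spectrum of a flavonoid dimer, a monomer fragment ion with
#' relative abundance below 5\% of the base peak indicates a bond that is
#' hard to cleave, i.e. C-C coupling; otherwise C-O coupling.
#'
#' @param monomer_rel_ab Relative abundance (\%) of the monomer fragment;
#'   vectorised, must lie in `[0, 100]`.
#' @return `"C-C"` where the abundance is strictly below 5, else `"C-O"`.
#' @examples
#' classify_coupling(c(4.08, 50, 5))  # "C-C" "C-O" "C-O"
#' @export
classify_coupling <- function(monomer_rel_ab) {
  if (any(is.na(monomer_rel_ab)) || any(monomer_rel_ab < 0) ||
      any(monomer_rel_ab > 100)) {
    stop("`monomer_rel_ab` must lie in [0, 100]", call. = FALSE)
  }
  ifelse(monomer_rel_ab < 5, "C-C", "C-O")
}
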