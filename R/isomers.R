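# Regioisomer assignment by the ClogP elution-order rule, with site-prior and
# peak-area tie-breaking.

#' Assign regioisomer candidates to peaks by the ClogP rule
#'
#' On reversed-phase chromatography, within a set of regioisomeric structures
#' the candidate with the smaller computed logP elutes earlier. Candidates
#' and peaks are therefore sorted (ClogP ascending; retention time ascending)
#' and matched by rank. Candidates with exactly equal ClogP values cannot be
#' ordered by the rule and form a tie group spanning the corresponding
#' retention-time ranks; resolve those with [break_tie()].
#'
#' The assignment is permutation-invariant: input row order never changes the
#' result.
#'
#' @param candidates Data frame with columns `label` and `clogp`
#'   (one candidate structure per row).
#' @param peaks Data frame with columns `peak_id` and `rt_min` (distinct
#'   retention times); must have as many rows as `candidates`.
#' @return A tibble, one row per peak in elution order: `peak_id`, `rt_min`,
#'   `label`, `clogp`, `tie_group` (`NA` for uniquely assigned peaks, an
#'   integer group index within ties).
#' @examples
#' assign_by_clogp(
#'   tibble::tibble(label = c("7", "3"), clogp = c(1.29372, 1.40805)),
#'   tibble::tibble(peak_id = c("a", "b"), rt_min = c(52.875, 53.592))
#' )
#' @export
assign_by_clogp <- function(candidates, peaks) {
  stopifnot(all(c("label", "clogp") %in% names(candidates)),
            all(c("peak_id", "rt_min") %in% names(peaks)))
  if (nrow(candidates) != nrow(peaks)) {
    stop("need exactly one candidate per peak (",
         nrow(candidates), " vs ", nrow(peaks), ")", call. = FALSE)
  }
  if (anyDuplicated(peaks$rt_min)) {
    stop("peak retention times must be distinct", call. = FALSE)
  }
  cand <- candidates[order(candidates$clogp, candidates$label), , drop = FALSE]
  pk <- peaks[order(peaks$rt_min), , drop = FALSE]
  # exact float equality defines ties: the values are table constants
  grp <- cumsum(!duplicated(cand$clogp))
  tie <- ave(grp, grp, FUN = length) > 1
  tibble::tibble(
    peak_id = pk$peak_id,
    rt_min = pk$rt_min,
    label = cand$label,
    clogp = cand$clogp,
    tie_group = ifelse(tie, grp, NA_integer_)
  )
}

#' Resolve ClogP tie groups with site priors and peak areas
#'
#' Within a tie group (candidates sharing one ClogP value), the elution rule
#' cannot order the sites, so metabolic knowledge steps in:
#'
#' * with peak areas, the peak with the largest area receives the most
#'   favoured site, remaining peaks matched by descending area against the
#'   prior order (the dominant regioisomer is the one formed at the favoured
#'   site);
#' * with priors but no areas, favoured sites are assigned in elution order;
#' * with neither, every peak in the group receives the composite
#'   `"3'/4'"`-style label and the tie is reported unresolved.
#'
#' @param assignment Result of [assign_by_clogp()].
#' @param priors Character vector of site labels, most favoured first
#'   (`NULL` for none). Sites absent from `priors` rank after all listed
#'   ones, in label order.
#' @param areas Named numeric vector of peak areas keyed by `peak_id`
#'   (`NULL` for none).
#' @return The assignment tibble with `label` resolved and an added
#'   `tie_resolution` column (`"unique"`, `"area"`, `"prior"`,
#'   `"unresolved"`).
#' @examples
#' a <- assign_by_clogp(
#'   tibble::tibble(label = c("3'", "4'"), clogp = c(0.0554161, 0.0554161)),
#'   tibble::tibble(peak_id = c("M73", "M74"), rt_min = c(56.3, 57.033))
#' )
#' break_tie(a, priors = c("3'", "7"), areas = c(M73 = 378222, M74 = 3335213))
#' @export
break_tie <- function(assignment, priors = NULL, areas = NULL) {
  out <- assignment
  out$tie_resolution <- ifelse(is.na(out$tie_group), "unique",
                               NA_character_)
  for (g in unique(stats::na.omit(out$tie_group))) {
    rows <- which(out$tie_group == g)
    if (length(rows) < 2) {
      out$tie_resolution[rows] <- "unique"
      next
    }
    sites <- out$label[rows]
    prior_rank <- match(sites, priors %||% character(0))
    site_order <- sites[order(is.na(prior_rank), prior_rank, sites)]
    have_areas <- !is.null(areas) && all(out$peak_id[rows] %in% names(areas))
    if (have_areas) {
      by_area <- rows[order(-areas[out$peak_id[rows]])]
      out$label[by_area] <- site_order
      out$tie_resolution[rows] <- "area"
    } else if (any(!is.na(prior_rank))) {
      out$label[rows] <- site_order  # rows are already in elution order
      out$tie_resolution[rows] <- "prior"
    } else {
      out$label[rows] <- paste(sort(sites), collapse = "/")
      out$tie_resolution[rows] <- "unresolved"
    }
  }
  out
}

#' Candidate conjugation sites of a flavonoid aglycone
#'
#' Free hydroxyl positions available to a conjugation, with the C-5 hydroxyl
#' excluded by default: chelation to the 4-keto group makes it metabolically
#' unreactive, so generated candidate sets omit it (user-supplied candidate
#' lists are never filtered).
#'
#' @param sites Character vector of hydroxyl site labels.
#' @param exclude_c5 Drop the `"5"` position (default `TRUE`).
#' @return The filtered site vector.
#' @export
candidate_sites <- function(sites = c("3", "5", "7", "3'", "4'"),
                            exclude_c5 = TRUE) {
  if (exclude_c5) sites[sites != "5"] else sites
}
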