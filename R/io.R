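# Readers/writers for the peak-list TSV dialect and packaged fixture tables.

#' Path to a packaged fixture file
#'
#' @param name File name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return A file path (or a character vector of fixture names).
#' @export
ms_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "metshift")
  if (is.null(name)) return(dir(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no packaged fixture: ", name, call. = FALSE)
  path
}

#' Packaged metabolite identification table (192 rows)
#'
#' Transcription of the published identification table for taxifolin and its
#' 191 rat metabolites: retention time, molecular formula, ion species,
#' measured/predicted m/z, ppm difference, DBE, urine/plasma/faeces detection
#' flags, identification level and name, plus the metabolite-class grouping
#' and provenance flags (bioactive, known metabolite, new compound, specific
#' structure, organ-only detection).
#'
#' @return A tibble with 192 rows (the parent compound plus M1-M191).
#' @export
tax_table1 <- function() {
  readr::read_csv(ms_fixture("table1.csv"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Packaged reaction assignments per metabolite (191 rows)
#'
#' The published metabolic-reaction bookkeeping table, transcribed as one
#' `";"`-separated reaction multiset per metabolite (repeats spelled out, so
#' a disulphate lists sulphation twice). Transcribed as printed: a handful of
#' rows are known to disagree with the formula-consistent decomposition (see
#' the methods vignette); [decompose_shift()] provides the formula-driven
#' alternative.
#'
#' @return A tibble with columns `id`, `reactions`.
#' @export
tax_table2 <- function() {
  readr::read_csv(ms_fixture("table2.csv"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Packaged organ-distribution matrix (47 rows)
#'
#' Detection of the parent compound and 46 metabolites across eight rat
#' organs (heart, liver, spleen, lung, kidney, brain, stomach, small
#' intestine), as a 0/1 matrix.
#'
#' @return A detection-matrix tibble (see [detection_matrix()]).
#' @export
tax_table3 <- function() {
  detection_matrix(readr::read_csv(ms_fixture("table3.csv"),
                                   show_col_types = FALSE, progress = FALSE))
}

#' Packaged ClogP lookup table
#'
#' Computed octanol-water partition coefficients for the regioisomeric
#' conjugate structures discussed in the source study, keyed by structure
#' label. ClogP values are injected data, not computed by this package.
#'
#' @return A tibble with columns `structure`, `aglycone`, `reaction`, `site`,
#'   `clogp`.
#' @export
clogp_table <- function() {
  readr::read_csv(ms_fixture("clogp.csv"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Packaged ClogP elution-order case studies
#'
#' The regioisomer groups with printed (ClogP, retention time, label)
#' pairings, used to validate [assign_by_clogp()] and [break_tie()]. Within a
#' case, candidate rows (site, clogp) and peak rows (peak_id, rt_min, area)
#' are aligned. `rule_consistent` marks whether the printed pairing follows
#' the elution-order rule (one published case does not; see vignette).
#'
#' @return A tibble of case-study rows.
#' @export
clogp_cases <- function() {
  readr::read_csv(ms_fixture("clogp_cases.csv"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Packaged aglycone reference library
#'
#' Reference aglycones with their characteristic negative-mode MS2 fragments
#' (m/z and published label), from the fragmentation behaviour of taxifolin,
#' quercetin, dihydrokaempferol and related scaffolds.
#'
#' @return A nested tibble with one row per aglycone: `name`, `formula`,
#'   `aglycone_mz` (deprotonated-ion m/z) and a `fragments` list-column of
#'   `(mz, label)` tibbles.
#' @export
aglycone_library <- function() {
  raw <- readr::read_csv(ms_fixture("aglycones.csv"), show_col_types = FALSE,
                         progress = FALSE)
  nested <- raw |>
    dplyr::group_by(.data$name, .data$formula) |>
    tidyr::nest(fragments = c("frag_mz", "frag_label")) |>
    dplyr::ungroup()
  nested$fragments <- lapply(nested$fragments, function(f) {
    f <- f[!is.na(f$frag_mz), , drop = FALSE]
    tibble::tibble(mz = f$frag_mz, label = f$frag_label)
  })
  nested$aglycone_mz <- ion_mz(nested$formula)
  nested[order(match(nested$name, unique(raw$name))), ]
}

#' Packaged metabolic site priors
#'
#' Literature-derived favoured conjugation sites per (aglycone, reaction),
#' most favoured first, used by [break_tie()].
#'
#' @return A tibble with columns `aglycone`, `reaction`, `sites` (list of
#'   ordered site labels).
#' @export
site_priors <- function() {
  pr <- readr::read_csv(ms_fixture("site_priors.csv"), show_col_types = FALSE,
                        progress = FALSE)
  pr$sites <- strsplit(pr$sites, ";", fixed = TRUE)
  pr
}

# ---------------------------------------------------------------------------
# Peak-list TSV dialect:
#   peak_id  compartment  rt_min  mz  area  ms2  ms3
# ms2 encodes fragments as "mz:relab;mz:relab"; ms3 is the same, prefixed by
# its precursor: "precursor>mz:relab;...". Missing spectra are empty cells.

format_fragments <- function(frags) {
  if (is.null(frags) || nrow(frags) == 0) return("")
  paste(sprintf("%.4f:%.2f", frags$mz, frags$rel_ab), collapse = ";")
}

parse_fragments <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) {
    return(tibble::tibble(mz = numeric(), rel_ab = numeric()))
  }
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop("malformed fragment list: ", txt, call. = FALSE)
  tibble::tibble(mz = as.numeric(vapply(parts, `[`, "", 1)),
                 rel_ab = as.numeric(vapply(parts, `[`, "", 2)))
}

#' Read a peak-list TSV
#'
#' Reads the tab-separated peak-list dialect written by [write_peaklist()]
#' and [simulate_peaklists()]: one chromatographic feature per row with
#' optional MS2/MS3 fragment lists. Fragment relative abundances are
#' normalised to base peak = 100 on ingestion.
#'
#' @param path File path.
#' @return A tibble with columns `peak_id`, `compartment`, `rt_min`, `mz`,
#'   `area`, and list-columns `ms2`, `ms3` of `(mz, rel_ab)` tibbles (`ms3`
#'   entries additionally carry a `precursor_mz` attribute-free column named
#'   in the tibble).
#' @export
read_peaklist <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_schema <- c("peak_id", "compartment", "rt_min", "mz", "area",
                       "ms2", "ms3")
  if (!all(validate_schema %in% names(raw))) {
    stop("peak list ", path, " lacks columns: ",
         paste(setdiff(validate_schema, names(raw)), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("rt_min", "mz", "area")) raw[[col]] <- as.numeric(raw[[col]])
  validate_peaklist_raw(raw, path)
  raw$ms2 <- lapply(raw$ms2, function(x) normalize_spectrum(parse_fragments(x)))
  raw$ms3 <- lapply(raw$ms3, function(x) {
    if (is.na(x) || !nzchar(x)) {
      return(tibble::tibble(precursor_mz = numeric(), mz = numeric(),
                            rel_ab = numeric()))
    }
    split <- strsplit(x, ">", fixed = TRUE)[[1]]
    if (length(split) != 2L) stop("malformed ms3 cell: ", x, call. = FALSE)
    frags <- normalize_spectrum(parse_fragments(split[2]))
    tibble::tibble(precursor_mz = as.numeric(split[1]), mz = frags$mz,
                   rel_ab = frags$rel_ab)
  })
  raw
}

validate_peaklist_raw <- function(raw, path) {
  need <- c("peak_id", "compartment", "rt_min", "mz", "area", "ms2", "ms3")
  if (!all(need %in% names(raw))) {
    stop("peak list ", path, " lacks columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(raw$mz > 0) | raw$rt_min < 0)
  if (length(bad) > 0) {
    stop("invalid mz/rt in ", path, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(raw)
}

#' Write a peak-list TSV
#'
#' Writes a peak-list tibble in the dialect read by [read_peaklist()], with
#' fixed display precision (m/z 4 dp, relative abundance 2 dp, retention time
#' 3 dp); the round trip is lossless at that precision.
#'
#' @param peaks Peak-list tibble (see [read_peaklist()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  out <- tibble::tibble(
    peak_id = peaks$peak_id,
    compartment = peaks$compartment,
    rt_min = sprintf("%.3f", peaks$rt_min),
    mz = sprintf("%.4f", peaks$mz),
    area = sprintf("%.0f", peaks$area),
    ms2 = vapply(peaks$ms2, format_fragments, character(1)),
    ms3 = vapply(peaks$ms3, function(f) {
      if (is.null(f) || nrow(f) == 0) return("")
      paste0(sprintf("%.4f", f$precursor_mz[1]), ">",
             format_fragments(f))
    }, character(1))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write an identification table as TSV
#'
#' Mirrors the published table layout: fixed precision for retention time
#' (3 dp), m/z (4 dp) and ppm (2 dp).
#'
#' @param identifications Identification tibble from [run_pipeline()] or
#'   [tidy()] on its result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(identifications, path) {
  out <- identifications
  out$reactions <- vapply(out$reactions, function(r) paste(r, collapse = ";"),
                          character(1))
  for (col in intersect(c("rt_min"), names(out))) {
    out[[col]] <- sprintf("%.3f", out[[col]])
  }
  for (col in intersect(c("meas_mz", "pred_mz"), names(out))) {
    out[[col]] <- sprintf("%.4f", out[[col]])
  }
  for (col in intersect(c("diff_ppm"), names(out))) {
    out[[col]] <- sprintf("%.2f", out[[col]])
  }
  drop <- intersect(c("ms2", "ms3"), names(out))
  out <- out[setdiff(names(out), drop)]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
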