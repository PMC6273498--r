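# Metabolite-by-compartment detection matrices and distribution summaries.

#' Build a detection matrix
#'
#' A detection matrix is a tibble with an `id` column (unique metabolite
#' identifiers) and one logical/0-1 column per compartment. Cells given as
#' `"▲"`/`"-"` (the published dialect) are converted to logical.
#'
#' @param x A data frame with an `id` column and compartment columns.
#' @return A tibble of class `metshift_detection` with logical compartment
#'   columns.
#' @export
detection_matrix <- function(x) {
  stopifnot("id" %in% names(x))
  if (anyDuplicated(x$id)) stop("metabolite ids must be unique", call. = FALSE)
  out <- tibble::as_tibble(x)
  for (col in setdiff(names(out), "id")) {
    v <- out[[col]]
    if (is.character(v)) {
      v <- trimws(v)
      out[[col]] <- v == "▲" | v == "1" | toupper(v) == "TRUE"
    } else {
      out[[col]] <- as.logical(v)
    }
    if (any(is.na(out[[col]]))) {
      stop("column ", col, " has cells that are not detections", call. = FALSE)
    }
  }
  class(out) <- c("metshift_detection", class(out))
  out
}

#' Read / write a detection matrix CSV
#'
#' Both the `▲`/`-` dialect and 1/0 cells are read; 1/0 is written.
#'
#' @param path File path.
#' @return [read_detection_matrix()]: a detection matrix;
#'   [write_detection_matrix()]: `path`, invisibly.
#' @export
read_detection_matrix <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  detection_matrix(raw)
}

#' @param m A detection matrix.
#' @rdname read_detection_matrix
#' @export
write_detection_matrix <- function(m, path) {
  out <- m
  for (col in setdiff(names(out), "id")) out[[col]] <- as.integer(out[[col]])
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Detections per compartment
#'
#' Column-wise counts of detected metabolites. The parent compound is stored
#' in the matrix but excluded from headline counts by default.
#'
#' @param m A detection matrix.
#' @param include_parent Count the parent row too (default `FALSE`).
#' @param parent_id Row id of the parent compound.
#' @return A tibble with columns `compartment`, `n`.
#' @examples
#' compartment_sums(tax_table3())
#' @export
compartment_sums <- function(m, include_parent = FALSE, parent_id = "TAX") {
  rows <- if (include_parent) m else m[m$id != parent_id, , drop = FALSE]
  comps <- setdiff(names(m), "id")
  tibble::tibble(
    compartment = comps,
    n = vapply(comps, function(cl) sum(rows[[cl]]), integer(1), USE.NAMES = FALSE)
  )
}

#' Widely distributed metabolites
#'
#' Metabolites detected in at least `min_organs` of the given organ columns,
#' sorted by organ count (descending) and then by id.
#'
#' @param m A detection matrix.
#' @param organs Organ column names (default: every non-id column).
#' @param min_organs Minimum number of organs (>= 1). "More than three
#'   organs" in the source study corresponds to `min_organs = 4`.
#' @param parent_id Parent row id, excluded from the listing.
#' @return A tibble with columns `id`, `n_organs`.
#' @examples
#' widely_distributed(tax_table3(), min_organs = 4)
#' @export
widely_distributed <- function(m, organs = setdiff(names(m), "id"),
                               min_organs = 4, parent_id = "TAX") {
  stopifnot(min_organs >= 1)
  rows <- m[m$id != parent_id, , drop = FALSE]
  counts <- rowSums(as.matrix(rows[organs]))
  keep <- counts >= min_organs
  out <- tibble::tibble(id = rows$id[keep], n_organs = as.integer(counts[keep]))
  out[order(-out$n_organs, natural_id_order(out$id)), ]
}

# Sort "M2" before "M11": numeric suffix where present, else alphabetical.
natural_id_order <- function(ids) {
  num <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", ids)))
  order(is.na(num), num, ids)
}

#' Heatmap of a detection matrix
#'
#' @param object A detection matrix.
#' @param ... Unused.
#' @return A ggplot object: metabolites by compartments, filled by detection.
#' @exportS3Method ggplot2::autoplot
autoplot.metshift_detection <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"id",
                              names_to = "compartment",
                              values_to = "detected")
  long$id <- factor(long$id, levels = rev(object$id[natural_id_order(object$id)]))
  long$compartment <- factor(long$compartment,
                             levels = setdiff(names(object), "id"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$compartment, y = .data$id,
                                     fill = .data$detected)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "grey25"),
                               name = "detected") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
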