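# Per-peak identification orchestration: formula prediction -> network lookup
# -> MSn corroboration -> class assignment -> identification level -> a
# published-table-shaped output.

#' Pipeline configuration
#'
#' @param tol_ppm MS1 mass tolerance in ppm. The default (6 ppm) covers the
#'   full accuracy spread of the reference identification table.
#' @param frag_tol_da MS2 fragment/loss tolerance in Da.
#' @param rt_window Retention-time window (min) for blank subtraction,
#'   reference-standard matching and compartment merging.
#' @param adducts Negative-mode adducts tried per peak.
#' @param max_depth Reaction multiset depth of the candidate network.
#' @param allow_dimers Include dimer nodes in the network.
#' @param use_ring_catalogue Seed ring-cleavage scaffolds into the network.
#' @param rules Reaction rule table.
#' @param reference_standards Optional tibble `(formula, rt_min)` of
#'   authentic standards; a formula + retention-time match gives
#'   identification level 1.
#' @param known_formulas Optional character vector of formulas known from
#'   literature/databases (level 2 evidence).
#' @return A named list of class `metshift_config`.
#' @export
pipeline_config <- function(tol_ppm = 6, frag_tol_da = 0.02, rt_window = 0.5,
                            adducts = c("[M-H]-", "[M+NH2]-"),
                            max_depth = 2, allow_dimers = FALSE,
                            use_ring_catalogue = TRUE,
                            rules = default_rules(),
                            reference_standards = NULL,
                            known_formulas = NULL) {
  stopifnot(tol_ppm > 0, frag_tol_da > 0, rt_window >= 0)
  structure(list(
    tol_ppm = tol_ppm, frag_tol_da = frag_tol_da, rt_window = rt_window,
    adducts = normalize_adduct(adducts), max_depth = max_depth,
    allow_dimers = allow_dimers, use_ring_catalogue = use_ring_catalogue,
    rules = rules, reference_standards = reference_standards,
    known_formulas = known_formulas
  ), class = "metshift_config")
}

#' Assign an identification level
#'
#' Level 1: matched to a reference standard (retention time and MSn
#' agreement). Level 2: consistent with literature or database knowledge.
#' Level 3: a new compound. Vectorised.
#'
#' @param matches_reference Logical; reference-standard match.
#' @param literature_known Logical; known from literature/databases.
#' @return Integer level(s) in `1:3`.
#' @examples
#' assign_level(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE))  # 1 2 3
#' @export
assign_level <- function(matches_reference, literature_known) {
  n <- max(length(matches_reference), length(literature_known))
  matches_reference <- rep_len(as.logical(matches_reference), n)
  literature_known <- rep_len(as.logical(literature_known), n)
  ifelse(matches_reference, 1L, ifelse(literature_known, 2L, 3L))
}

# Conjugation reaction names (those evidenced by neutral losses).
.conjugations <- c("sulphation", "glucuronidation",
                   "pyroglutamate_conjugation", "acetylamination")

#' Classify a metabolite into one of the eight categories
#'
#' Deterministic precedence on the reaction multiset and provenance: dimers
#' (two parent units) first, then ring-cleavage phenolic acids, the combined
#' dehydration + glucuronidation group, hydrogenated, dehydroxylated and
#' dehydrogenated (quercetin-type) aglycones, then methylated aglycones;
#' everything remaining keeps the parent (taxifolin) aglycone. A multiset
#' that fits no category is reported as `"unknown"`, never silently dropped.
#'
#' @param reactions Character vector (one multiset) or list of multisets.
#' @param n_parents Number of parent units (2 for dimers); recycled.
#' @return Character class label(s).
#' @examples
#' classify_metabolite(c("sulphation"))                      # "taxifolin"
#' classify_metabolite(c("dehydration", "glucuronidation"))
#' @export
classify_metabolite <- function(reactions, n_parents = 1) {
  if (!is.list(reactions)) reactions <- list(reactions)
  n_parents <- rep_len(n_parents, length(reactions))
  vapply(seq_along(reactions), function(i) {
    r <- reactions[[i]]
    if (!is.character(r) && !is.null(r)) return("unknown")
    if (n_parents[i] == 2 || "polymerization" %in% r) return("dimer")
    if ("ring_cleavage" %in% r) return("phenolic-acid")
    if ("dehydration" %in% r && "glucuronidation" %in% r) {
      return("dehydration-glucuronidation")
    }
    if ("hydrogenation" %in% r) return("hydrogenated-taxifolin")
    if ("dehydroxylation" %in% r) return("dehydroxylated-taxifolin")
    if ("dehydrogenation" %in% r) return("quercetin")
    if ("methylation" %in% r) return("methyl-taxifolin")
    known <- c(.conjugations, "isomerization", "hydroxylation", "hydration",
               "dehydration")
    if (length(r) == 0 || all(r %in% known)) return("taxifolin")
    "unknown"
  }, character(1))
}

# MS2 evidence for one network candidate: conjugations backed by matched
# losses, or the expected aglycone ion observed.
ms2_evidence <- function(node, ms2, precursor_mz, config, refs, losses) {
  conj <- intersect(unique(node$reactions[[1]]), .conjugations)
  if (is.null(ms2) || nrow(ms2) == 0) {
    return(list(has_ms2 = FALSE, consistent = TRUE, score = 0,
                aglycone = NA_character_))
  }
  matched <- match_losses(precursor_mz, ms2, losses, config$frag_tol_da)
  loss_frac <- if (length(conj) == 0) 1 else {
    mean(conj %in% matched$meaning)
  }
  # expected aglycone = candidate stripped of its conjugations
  agl_ok <- FALSE
  agl_name <- NA_character_
  conj_all <- node$reactions[[1]][node$reactions[[1]] %in% .conjugations]
  if (node$seed[1] != "dimer") {
    expected <- tryCatch({
      counts <- parse_formula(node$formula[1])
      for (r in conj_all) {
        i <- match(r, config$rules$reaction)
        counts <- counts_subtract(counts, config$rules$delta[[i]])
      }
      counts
    }, error = function(e) NULL)
    if (!is.null(expected)) {
      agl_mz <- counts_mass(expected) - .element_masses[["H"]] +
        .electron_mass
      agl_ok <- any(abs(ms2$mz - agl_mz) <= config$frag_tol_da) ||
        abs(precursor_mz - agl_mz) <= config$frag_tol_da
      hit <- refs[abs(refs$aglycone_mz - agl_mz) <= config$frag_tol_da, ,
                  drop = FALSE]
      if (agl_ok && nrow(hit) > 0) {
        scores <- vapply(seq_len(nrow(hit)), function(k) {
          fr <- hit$fragments[[k]]
          if (nrow(fr) == 0) 0 else {
            fragment_match_score(ms2, tibble::tibble(mz = fr$mz),
                                 config$frag_tol_da)
          }
        }, numeric(1))
        agl_name <- hit$name[which.max(scores)]
      }
    }
  }
  score <- loss_frac + as.numeric(agl_ok)
  consistent <- length(conj) == 0 || loss_frac > 0 || agl_ok
  list(has_ms2 = TRUE, consistent = consistent, score = score,
       aglycone = agl_name)
}

#' Identify a single peak against a candidate network
#'
#' Filters the enumerated network to compositions whose theoretical ion m/z
#' (over the configured adducts) lies within the ppm tolerance of the
#' measured value, corroborates each candidate against the MS2 spectrum
#' (a conjugate candidate whose diagnostic neutral loss or aglycone ion is
#' absent from an available spectrum is down-ranked), and returns the best
#' candidate with full provenance. Ranking is deterministic: MS2-consistent
#' first, then fewest reactions, higher MS2 evidence score, smaller absolute
#' ppm, and finally formula.
#'
#' @param mz Measured ion m/z.
#' @param ms2 Optional fragment tibble `(mz, rel_ab)`.
#' @param network Candidate network from [enumerate_candidates()].
#' @param config Pipeline configuration, see [pipeline_config()].
#' @param refs Aglycone library.
#' @param losses Neutral-loss definitions.
#' @return A one-row tibble (`formula`, `adduct`, `pred_mz`, `diff_ppm`,
#'   `dbe`, `reactions`, `n_parents`, `class`, `aglycone`, `ms1_only`,
#'   `coupling`, `depth`) or a zero-row tibble when no candidate is in
#'   tolerance.
#' @export
identify_peak <- function(mz, ms2 = NULL, network, config = pipeline_config(),
                          refs = aglycone_library(),
                          losses = neutral_loss_defs()) {
  if (!is.null(ms2) && nrow(ms2) > 0) ms2 <- normalize_spectrum(ms2)
  tab <- adduct_table()
  # adducts are an ordered preference: the deprotonated interpretation is
  # taken whenever it exists, and the ammonia-adduct reading is consulted
  # only when no [M-H]- candidate is in tolerance (an [M+NH2]- ion of Y is
  # exactly isobaric with the [M-H]- ion of Y + NH3, so trying both at once
  # would make every acetylamination conjugate ambiguous)
  cand <- NULL
  for (a in config$adducts) {
    row <- match(a, tab$adduct)
    pred <- network$mass + counts_mass(tab$delta[[row]]) + .electron_mass
    ppm <- ppm_error(mz, pred)
    keep <- which(abs(ppm) <= config$tol_ppm)
    if (length(keep) == 0) next
    cand <- network[keep, , drop = FALSE]
    cand$adduct <- a
    cand$pred_mz <- pred[keep]
    cand$ppm <- ppm[keep]
    break
  }
  if (is.null(cand)) return(empty_identification())

  ev <- lapply(seq_len(nrow(cand)), function(i) {
    ms2_evidence(cand[i, ], ms2, mz, config, refs, losses)
  })
  cand$consistent <- vapply(ev, `[[`, logical(1), "consistent")
  cand$ms2_score <- vapply(ev, `[[`, numeric(1), "score")
  cand$aglycone <- vapply(ev, `[[`, character(1), "aglycone")
  ord <- order(!cand$consistent, cand$depth, -cand$ms2_score, abs(cand$ppm),
               cand$formula)
  best <- cand[ord[1], , drop = FALSE]

  coupling <- NA_character_
  if (best$seed == "dimer" && !is.null(ms2) && nrow(ms2) > 0) {
    mono <- best$monomer_mz[[1]]
    hit <- which(vapply(ms2$mz, function(m) {
      any(abs(mono - m) <= config$frag_tol_da)
    }, logical(1)))
    if (length(hit) > 0) coupling <- classify_coupling(max(ms2$rel_ab[hit]))
  }

  n_parents <- if (best$seed == "dimer") 2L else 1L
  tibble::tibble(
    formula = best$formula,
    adduct = best$adduct,
    pred_mz = best$pred_mz,
    diff_ppm = ppm_error(mz, round(best$pred_mz, 4)),
    dbe = rdbe(best$formula),
    reactions = best$reactions,
    n_parents = n_parents,
    class = classify_metabolite(best$reactions, n_parents),
    aglycone = best$aglycone,
    ms1_only = is.null(ms2) || nrow(ms2) == 0,
    ms2_consistent = best$consistent,
    coupling = coupling,
    depth = best$depth,
    seed = best$seed
  )
}

empty_identification <- function() {
  tibble::tibble(
    formula = character(), adduct = character(), pred_mz = numeric(),
    diff_ppm = numeric(), dbe = numeric(), reactions = list(),
    n_parents = integer(), class = character(), aglycone = character(),
    ms1_only = logical(), ms2_consistent = logical(), coupling = character(),
    depth = integer(), seed = character()
  )
}

#' Run the identification pipeline on drug/blank peak lists
#'
#' For every compartment, drug-group peaks that also occur in the blank group
#' (same m/z within tolerance and retention time within the window) are
#' discarded as background; the remainder are identified against the
#' enumerated biotransformation network, merged across compartments (same
#' formula, retention times within the window), numbered in elution order,
#' and reported in the published-table shape with one detection-flag column
#' per compartment.
#'
#' @param drug Drug-group peak list (see [read_peaklist()] for columns).
#' @param blank Blank-group peak list, or `NULL` (a warning is issued and
#'   blank subtraction skipped).
#' @param parent Parent-compound formula.
#' @param config Pipeline configuration.
#' @param network Optional pre-built candidate network (rebuilt from `config`
#'   otherwise).
#' @return An object of class `metshift_annotation`: use [tidy()] for the
#'   identification tibble, [glance()] for one-row summary counts,
#'   [autoplot()] for a mass-error overview, and `$discarded` for the log of
#'   rejected peaks with reasons.
#' @export
run_pipeline <- function(drug, blank = NULL, parent = "C15H12O7",
                         config = pipeline_config(), network = NULL) {
  stopifnot(is.data.frame(drug))
  if (is.null(network)) {
    network <- enumerate_candidates(
      parent, config$rules, config$max_depth,
      ring_catalogue = if (config$use_ring_catalogue) ring_catalogue() else NULL,
      allow_dimers = config$allow_dimers
    )
  }
  refs <- aglycone_library()
  losses <- neutral_loss_defs()
  blank_subtracted <- !is.null(blank)
  if (!blank_subtracted) {
    warning("no blank peak list supplied; blank subtraction skipped",
            call. = FALSE)
  }
  if (!"ms2" %in% names(drug)) drug$ms2 <- rep(list(NULL), nrow(drug))
  if (!"area" %in% names(drug)) drug$area <- NA_real_

  discarded <- tibble::tibble(peak_id = character(), compartment = character(),
                              mz = numeric(), reason = character())
  keep <- rep(TRUE, nrow(drug))
  if (blank_subtracted && nrow(drug) > 0 && nrow(blank) > 0) {
    for (i in seq_len(nrow(drug))) {
      b <- blank[blank$compartment == drug$compartment[i], , drop = FALSE]
      if (nrow(b) == 0) next
      same <- abs(ppm_error(drug$mz[i], b$mz)) <= config$tol_ppm &
        abs(drug$rt_min[i] - b$rt_min) <= config$rt_window
      if (any(same)) keep[i] <- FALSE
    }
    if (any(!keep)) {
      discarded <- dplyr::bind_rows(discarded, tibble::tibble(
        peak_id = drug$peak_id[!keep], compartment = drug$compartment[!keep],
        mz = drug$mz[!keep], reason = "present in blank group"
      ))
    }
  }
  drug <- drug[keep, , drop = FALSE]

  hits <- vector("list", nrow(drug))
  for (i in seq_len(nrow(drug))) {
    hit <- identify_peak(drug$mz[i], drug$ms2[[i]], network, config, refs,
                         losses)
    if (nrow(hit) == 0) {
      discarded <- dplyr::bind_rows(discarded, tibble::tibble(
        peak_id = drug$peak_id[i], compartment = drug$compartment[i],
        mz = drug$mz[i], reason = "no network candidate within tolerance"
      ))
    } else {
      hit$peak_id <- drug$peak_id[i]
      hit$compartment <- drug$compartment[i]
      hit$rt_min <- drug$rt_min[i]
      hit$meas_mz <- drug$mz[i]
      hit$area <- drug$area[i]
      hits[[i]] <- hit
    }
  }
  hits <- dplyr::bind_rows(hits)

  out <- merge_compartments(hits, drug, config)
  out <- finalize_annotation(out, config)
  structure(list(
    identifications = out,
    discarded = discarded,
    config = config,
    network_size = nrow(network),
    blank_subtracted = blank_subtracted,
    compartments = unique(drug$compartment)
  ), class = "metshift_annotation")
}

# Merge per-compartment hits of the same metabolite (same formula, retention
# times within the window) into one row with compartment flags.
merge_compartments <- function(hits, drug, config) {
  comps <- unique(drug$compartment)
  if (nrow(hits) == 0) {
    out <- empty_identification()
    out$rt_min <- numeric()
    out$meas_mz <- numeric()
    for (cl in comps) out[[cl]] <- logical()
    return(out)
  }
  hits <- hits[order(hits$formula, hits$rt_min), , drop = FALSE]
  grp <- integer(nrow(hits))
  gid <- 0L
  for (i in seq_len(nrow(hits))) {
    if (i == 1 || hits$formula[i] != hits$formula[i - 1] ||
        hits$rt_min[i] - hits$rt_min[i - 1] > config$rt_window) {
      gid <- gid + 1L
    }
    grp[i] <- gid
  }
  hits$.group <- grp
  rows <- lapply(split(seq_len(nrow(hits)), grp), function(idx) {
    g <- hits[idx, , drop = FALSE]
    lead <- g[which.max(g$area), , drop = FALSE]  # most intense occurrence
    for (cl in comps) lead[[cl]] <- cl %in% g$compartment
    lead$rt_min <- stats::median(g$rt_min)
    lead$ms1_only <- all(g$ms1_only)
    lead
  })
  out <- dplyr::bind_rows(rows)
  out$.group <- NULL
  out$compartment <- NULL
  out[order(out$rt_min, out$formula), , drop = FALSE]
}

# Names, isomer numbering, levels and final column order.
finalize_annotation <- function(out, config) {
  if (nrow(out) == 0) return(out)
  out$identification <- vapply(seq_len(nrow(out)), function(i) {
    build_name(out$reactions[[i]], out$aglycone[i], out$seed[i],
               out$class[i], config$rules)
  }, character(1))
  # isomer numbering in elution order within identical base names + formula
  key <- paste(out$formula, out$identification)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 1) {
      ord <- idx[order(out$rt_min[idx])]
      out$identification[ord] <- paste(out$identification[ord],
                                       seq_along(ord))
    }
  }
  ref <- config$reference_standards
  ref_match <- rep(FALSE, nrow(out))
  if (!is.null(ref) && nrow(ref) > 0) {
    for (i in seq_len(nrow(out))) {
      ref_match[i] <- any(ref$formula == out$formula[i] &
                            abs(ref$rt_min - out$rt_min[i]) <=
                              config$rt_window)
    }
  }
  known <- rep(FALSE, nrow(out))
  if (!is.null(config$known_formulas)) {
    known <- out$formula %in% config$known_formulas
  }
  out$level <- assign_level(ref_match, known)
  out$id <- paste0("M", seq_len(nrow(out)))
  front <- c("id", "rt_min", "formula", "adduct", "meas_mz", "pred_mz",
             "diff_ppm", "dbe")
  rest <- setdiff(names(out), front)
  out[c(front, rest)]
}

# Mechanical identification string: phase-I modifiers prefix the aglycone
# stem, conjugations append.
build_name <- function(reactions, aglycone, seed, class, rules) {
  if (class == "dimer") {
    extra <- if ("sulphation" %in% reactions) " sulphate" else ""
    return(paste0("dimer", extra))
  }
  stem <- if (!is.na(aglycone)) {
    aglycone
  } else if (!seed %in% c("parent", "dimer")) {
    seed
  } else {
    mods <- c(hydrogenation = "hydrogenated", dehydrogenation = "dehydro",
              dehydroxylation = "dehydroxylated", hydroxylation = "hydroxylated",
              methylation = "methyl", dehydration = "dehydrated",
              hydration = "hydrated")
    pre <- unlist(lapply(names(mods), function(m) {
      k <- sum(reactions == m)
      if (k == 0) return(NULL)
      rep(mods[[m]], k)
    }))
    paste(c(pre, "taxifolin"), collapse = " ")
  }
  conj <- c(sulphation = "sulphate", glucuronidation = "glucuronide",
            pyroglutamate_conjugation = "pyroglutamate conjugate",
            acetylamination = "acetylamide")
  suff <- unlist(lapply(names(conj), function(cn) {
    k <- sum(reactions == cn)
    if (k == 0) return(NULL)
    if (k == 2) paste0("di", conj[[cn]]) else conj[[cn]]
  }))
  paste(c(stem, suff), collapse = " ")
}

#' @export
print.metshift_annotation <- function(x, ...) {
  cat("<metshift_annotation>\n")
  cat("  identifications:", nrow(x$identifications), "\n")
  cat("  discarded peaks:", nrow(x$discarded), "\n")
  cat("  network size:", x$network_size, "candidate nodes\n")
  cat("  blank subtracted:", x$blank_subtracted, "\n")
  invisible(x)
}

#' Tidy the identification table
#'
#' @param x A `metshift_annotation` object.
#' @param ... Unused.
#' @return The identification tibble (one row per metabolite, compartment
#'   flags as logical columns).
#' @exportS3Method generics::tidy
tidy.metshift_annotation <- function(x, ...) {
  x$identifications
}

#' One-row summary of a pipeline run
#'
#' @param x A `metshift_annotation` object.
#' @param ... Unused.
#' @return A one-row tibble: identification, discard and class counts.
#' @exportS3Method generics::glance
glance.metshift_annotation <- function(x, ...) {
  ids <- x$identifications
  tibble::tibble(
    n_identified = nrow(ids),
    n_discarded = nrow(x$discarded),
    n_level1 = sum(ids$level == 1),
    n_level2 = sum(ids$level == 2),
    n_level3 = sum(ids$level == 3),
    n_dimers = sum(ids$class == "dimer"),
    n_ms1_only = sum(ids$ms1_only),
    network_size = x$network_size
  )
}

#' Mass-error overview of an annotation run
#'
#' @param object A `metshift_annotation` object.
#' @param ... Unused.
#' @return A ggplot: ppm error against m/z, coloured by metabolite class.
#' @exportS3Method ggplot2::autoplot
autoplot.metshift_annotation <- function(object, ...) {
  ids <- object$identifications
  ggplot2::ggplot(ids, ggplot2::aes(x = .data$meas_mz, y = .data$diff_ppm,
                                    colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "measured m/z (Da)", y = "mass error (ppm)",
                  colour = "class") +
    ggplot2::theme_minimal()
}
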