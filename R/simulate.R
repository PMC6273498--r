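# Ground-truthed synthetic drug/blank peak-list generation for end-to-end
# recovery benchmarking. The generator emulates the statistical structure the
# pipeline assumes -- theoretical candidate masses plus Gaussian ppm noise,
# MS2 spectra built from conjugate neutral losses plus aglycone fragments --
# not chromatographic physics.

#' Simulation configuration
#'
#' @param parent Parent-compound formula.
#' @param n_metabolites Number of planted metabolites.
#' @param max_depth Reaction depth of the network sampled from.
#' @param dimer_fraction Fraction of planted metabolites that are dimers.
#' @param sigma_ppm Gaussian m/z noise, in ppm (2 ppm mirrors the accuracy
#'   spread of the reference instrument's identification table).
#' @param compartments Compartment names.
#' @param detect_prob Per-compartment Bernoulli detection probability.
#' @param n_blank Background peaks per compartment.
#' @param rules Reaction rule table.
#' @param use_ring_catalogue Seed ring-cleavage scaffolds.
#' @param seed Integer seed; fixes every random draw.
#' @return A named list of class `metshift_simconfig`.
#' @export
sim_config <- function(parent = "C15H12O7", n_metabolites = 40, max_depth = 2,
                       dimer_fraction = 0.1, sigma_ppm = 2,
                       compartments = c("urine", "plasma", "faeces"),
                       detect_prob = 0.7, n_blank = 50,
                       rules = default_rules(), use_ring_catalogue = TRUE,
                       seed = 1L) {
  stopifnot(n_metabolites >= 0, dimer_fraction >= 0, dimer_fraction <= 1,
            sigma_ppm >= 0, detect_prob >= 0, detect_prob <= 1, n_blank >= 0)
  structure(list(
    parent = parent, n_metabolites = n_metabolites, max_depth = max_depth,
    dimer_fraction = dimer_fraction, sigma_ppm = sigma_ppm,
    compartments = compartments, detect_prob = detect_prob,
    n_blank = n_blank, rules = rules,
    use_ring_catalogue = use_ring_catalogue, seed = as.integer(seed)
  ), class = "metshift_simconfig")
}

# Crude additive retention-time heuristic: conjugation makes a metabolite
# more polar (earlier), methylation less polar (later). Only the ordering
# structure matters to the pipeline; the model is deliberately non-physical.
.rt_offsets <- c(
  sulphation = -8, glucuronidation = -18, methylation = 10,
  pyroglutamate_conjugation = -20, acetylamination = -15,
  dehydroxylation = 5, hydroxylation = -6, dehydrogenation = 3,
  hydrogenation = 1, dehydration = 2, hydration = -3, isomerization = 1,
  ring_cleavage = -15, polymerization = 20
)

simulate_rt <- function(reactions, seed_name, index) {
  base <- if (identical(seed_name, "parent") || identical(seed_name, "dimer"))
    41 else 35
  off <- sum(.rt_offsets[reactions], na.rm = TRUE)
  max(1, base + off) + index * 1e-3
}

#' Sample a ground truth from the biotransformation network
#'
#' Enumerates the candidate network for the configured parent, deduplicates
#' it on composition, and samples `n_metabolites` distinct compositions
#' without replacement (a configured fraction of them dimers). Each truth
#' entry carries its reaction multiset, a heuristic retention time,
#' per-compartment Bernoulli memberships (at least one compartment each) and,
#' for dimers, a coupling-bond type.
#'
#' @param cfg Simulation configuration, see [sim_config()].
#' @return A tibble with columns `id`, `formula`, `mz` (deprotonated-ion),
#'   `rt_min`, `reactions` (list), `seed`, `n_parents`, `monomer_mz` (list),
#'   `coupling`, and one logical column per compartment.
#' @export
generate_truth <- function(cfg) {
  set.seed(cfg$seed)
  network <- enumerate_candidates(
    cfg$parent, cfg$rules, cfg$max_depth,
    ring_catalogue = if (cfg$use_ring_catalogue) ring_catalogue() else NULL,
    allow_dimers = cfg$dimer_fraction > 0
  )
  network <- network[!duplicated(network$formula), , drop = FALSE]
  # the unmodified parent is not a metabolite
  network <- network[network$depth > 0, , drop = FALSE]
  dimers <- network[network$seed == "dimer", , drop = FALSE]
  monomers <- network[network$seed != "dimer", , drop = FALSE]
  n_dim <- round(cfg$n_metabolites * cfg$dimer_fraction)
  n_mono <- cfg$n_metabolites - n_dim
  if (n_dim > nrow(dimers) || n_mono > nrow(monomers)) {
    stop("n_metabolites exceeds the size of the enumerated network",
         call. = FALSE)
  }
  pick <- dplyr::bind_rows(
    monomers[sample(nrow(monomers), n_mono), , drop = FALSE],
    dimers[sample(nrow(dimers), n_dim), , drop = FALSE]
  )
  n <- nrow(pick)
  if (n == 0) {
    out <- tibble::tibble(id = character(), formula = character(),
                          mz = numeric(), rt_min = numeric(),
                          reactions = list(), seed = character(),
                          n_parents = integer(), monomer_mz = list(),
                          coupling = character())
    for (cl in cfg$compartments) out[[cl]] <- logical()
    return(out)
  }
  member <- matrix(stats::runif(n * length(cfg$compartments)) <
                     cfg$detect_prob,
                   nrow = n)
  for (i in which(rowSums(member) == 0)) {
    member[i, sample(length(cfg$compartments), 1)] <- TRUE
  }
  out <- tibble::tibble(
    id = sprintf("T%03d", seq_len(n)),
    formula = pick$formula,
    mz = pick$mz_mh,
    rt_min = vapply(seq_len(n), function(i) {
      simulate_rt(pick$reactions[[i]], pick$seed[i], i)
    }, numeric(1)),
    reactions = pick$reactions,
    seed = pick$seed,
    n_parents = ifelse(pick$seed == "dimer", 2L, 1L),
    monomer_mz = pick$monomer_mz,
    coupling = ifelse(pick$seed == "dimer",
                      sample(c("C-C", "C-O"), n, replace = TRUE),
                      NA_character_)
  )
  for (k in seq_along(cfg$compartments)) out[[cfg$compartments[k]]] <- member[, k]
  out
}

# MS2 fragments for one truth entry; exact masses, base peak fixed at 100.
simulate_ms2 <- function(entry, cfg, refs, losses) {
  reactions <- entry$reactions[[1]]
  if (entry$seed == "dimer") {
    mono <- entry$monomer_mz[[1]][1]
    ab <- if (entry$coupling == "C-C") stats::runif(1, 0.5, 3.5) else
      stats::runif(1, 20, 80)
    return(tibble::tibble(
      mz = c(entry$mz - monoisotopic_mass("H2O"), mono),
      rel_ab = c(100, ab)
    ))
  }
  conj <- reactions[reactions %in% .conjugations]
  counts <- parse_formula(entry$formula)
  for (r in conj) {
    i <- match(r, cfg$rules$reaction)
    counts <- counts_subtract(counts, cfg$rules$delta[[i]])
  }
  agl_mz <- counts_mass(counts) - .element_masses[["H"]] + .electron_mass
  frags <- tibble::tibble(mz = numeric(), rel_ab = numeric())
  if (length(conj) > 0) {
    frags <- dplyr::bind_rows(frags, tibble::tibble(mz = agl_mz, rel_ab = 100))
    for (r in unique(conj)) {
      lm <- losses$mass[match(r, losses$meaning)]
      frags <- dplyr::bind_rows(frags, tibble::tibble(
        mz = entry$mz - lm, rel_ab = stats::runif(1, 30, 70)))
    }
  } else {
    frags <- tibble::tibble(mz = entry$mz - monoisotopic_mass("H2O"),
                            rel_ab = 100)
  }
  agl_formula <- format_formula(counts)
  hit <- refs[refs$formula == agl_formula, , drop = FALSE]
  if (nrow(hit) > 0 && nrow(hit$fragments[[1]]) > 0) {
    rf <- utils::head(hit$fragments[[1]], 3)
    frags <- dplyr::bind_rows(frags, tibble::tibble(
      mz = rf$mz, rel_ab = stats::runif(nrow(rf), 10, 50)))
  }
  frags <- frags[!duplicated(round(frags$mz, 4)), , drop = FALSE]
  frags$rel_ab[1] <- 100
  normalize_spectrum(frags)
}

#' Simulate drug and blank peak lists from a ground truth
#'
#' Each truth entry emits, in every compartment it belongs to, a peak at its
#' theoretical deprotonated-ion m/z perturbed by Gaussian ppm noise, with an
#' MS2 spectrum built from exact conjugate neutral losses plus aglycone
#' characteristic fragments (dimers: a monomer fragment whose relative
#' abundance encodes the coupling type, kept away from the 5\% decision
#' boundary). Blank lists contain only background peaks at random masses,
#' rejected within three times the instrument tolerance of any network
#' candidate so that false-positive counts are interpretable; the same
#' background peaks are injected into the drug lists as shared contaminants
#' for blank subtraction to remove.
#'
#' @param truth Ground truth from [generate_truth()].
#' @param cfg Simulation configuration.
#' @param tol_ppm Instrument tolerance used for the background rejection
#'   radius (3 x `tol_ppm`).
#' @return A list with elements `drug` and `blank`, both peak-list tibbles in
#'   the dialect of [read_peaklist()].
#' @export
simulate_peaklists <- function(truth, cfg, tol_ppm = 6) {
  set.seed(cfg$seed + 1L)
  refs <- aglycone_library()
  losses <- neutral_loss_defs()
  network <- enumerate_candidates(
    cfg$parent, cfg$rules, cfg$max_depth,
    ring_catalogue = if (cfg$use_ring_catalogue) ring_catalogue() else NULL,
    allow_dimers = TRUE
  )
  candidate_mz <- sort(unique(c(network$mz_mh,
                                network$mass + monoisotopic_mass("NH2") -
                                  0 + .electron_mass)))

  drug <- list()
  for (i in seq_len(nrow(truth))) {
    entry <- truth[i, , drop = FALSE]
    ms2 <- simulate_ms2(entry, cfg, refs, losses)
    for (cl in cfg$compartments) {
      if (!isTRUE(entry[[cl]][1])) next
      mz <- entry$mz * (1 + stats::rnorm(1, 0, cfg$sigma_ppm) * 1e-6)
      drug[[length(drug) + 1L]] <- tibble::tibble(
        peak_id = paste0(entry$id, "_", cl),
        compartment = cl,
        rt_min = entry$rt_min,
        mz = mz,
        area = round(stats::rlnorm(1, 13, 1)),
        ms2 = list(ms2),
        ms3 = list(tibble::tibble(precursor_mz = numeric(), mz = numeric(),
                                  rel_ab = numeric()))
      )
    }
  }
  drug <- if (length(drug) > 0) dplyr::bind_rows(drug) else empty_peaklist()

  mz_range <- c(150, 750)
  blank <- list()
  for (cl in cfg$compartments) {
    kept <- numeric(0)
    guard <- 0L
    while (length(kept) < cfg$n_blank && guard < 50L) {
      guard <- guard + 1L
      draw <- stats::runif(cfg$n_blank * 2, mz_range[1], mz_range[2])
      ok <- vapply(draw, function(m) {
        all(abs(ppm_error(m, candidate_mz)) > 3 * tol_ppm)
      }, logical(1))
      kept <- c(kept, draw[ok])
    }
    kept <- kept[seq_len(cfg$n_blank)]
    blank[[length(blank) + 1L]] <- tibble::tibble(
      peak_id = sprintf("B%s_%03d", cl, seq_along(kept)),
      compartment = cl,
      rt_min = round(stats::runif(length(kept), 1, 90), 3),
      mz = kept,
      area = round(stats::rlnorm(length(kept), 12, 1)),
      ms2 = rep(list(tibble::tibble(mz = numeric(), rel_ab = numeric())),
                length(kept)),
      ms3 = rep(list(tibble::tibble(precursor_mz = numeric(), mz = numeric(),
                                    rel_ab = numeric())), length(kept))
    )
  }
  blank <- if (length(blank) > 0) dplyr::bind_rows(blank) else empty_peaklist()
  # shared contaminants: background peaks appear in the drug group too
  list(drug = dplyr::bind_rows(drug, blank), blank = blank)
}

empty_peaklist <- function() {
  tibble::tibble(peak_id = character(), compartment = character(),
                 rt_min = numeric(), mz = numeric(), area = numeric(),
                 ms2 = list(), ms3 = list())
}

#' Score a pipeline run against its ground truth
#'
#' @param annotation A `metshift_annotation` from [run_pipeline()].
#' @param truth Ground truth from [generate_truth()].
#' @param cfg Simulation configuration used.
#' @param blank Optional blank peak list; when given, identifications whose
#'   underlying peak is a blank-group background peak are counted as
#'   `n_background_ids`.
#' @param rt_window Retention-time window for matching.
#' @return A one-row tibble: `n_truth`, `n_identified`, `formula_recovery`
#'   (fraction of planted metabolites whose formula was recovered),
#'   `n_background_ids` (identifications arising from blank-only background
#'   peaks; without `blank`, identifications matching no truth entry),
#'   `coupling_accuracy` (over planted dimers; `NA` if none),
#'   `detection_agreement` (fraction of truth compartment flags reproduced).
#' @export
evaluate_recovery <- function(annotation, truth, cfg, blank = NULL,
                              rt_window = 0.5) {
  ids <- annotation$identifications
  matched_truth <- logical(nrow(truth))
  matched_id <- logical(nrow(ids))
  coupling_ok <- logical(0)
  flags_ok <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    hit <- which(ids$formula == truth$formula[i] &
                   abs(ids$rt_min - truth$rt_min[i]) <= rt_window)
    if (length(hit) == 0) next
    matched_truth[i] <- TRUE
    matched_id[hit] <- TRUE
    j <- hit[1]
    if (!is.na(truth$coupling[i])) {
      coupling_ok <- c(coupling_ok,
                       isTRUE(ids$coupling[j] == truth$coupling[i]))
    }
    comps <- intersect(cfg$compartments, names(ids))
    if (length(comps) > 0) {
      flags_ok <- c(flags_ok, mean(vapply(comps, function(cl) {
        isTRUE(ids[[cl]][j] == truth[[cl]][i])
      }, logical(1))))
    }
  }
  n_background <- if (!is.null(blank)) {
    sum(ids$peak_id %in% blank$peak_id)
  } else {
    sum(!matched_id)
  }
  tibble::tibble(
    n_truth = nrow(truth),
    n_identified = nrow(ids),
    formula_recovery = if (nrow(truth) == 0) NA_real_ else mean(matched_truth),
    n_background_ids = n_background,
    coupling_accuracy = if (length(coupling_ok) == 0) NA_real_ else
      mean(coupling_ok),
    detection_agreement = if (length(flags_ok) == 0) NA_real_ else
      mean(flags_ok)
  )
}
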