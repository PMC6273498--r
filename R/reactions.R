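# Biotransformation reaction vocabulary and candidate-metabolite enumeration.
#
# A reaction is a signed composition delta; a candidate metabolite is a node
# of the network spanned by applying reaction multisets to the parent (or to a
# ring-cleavage scaffold), with dimerization joining two monomer nodes.

#' Default biotransformation rules
#'
#' The twelve metabolic reactions observed for taxifolin in vivo: six phase I
#' redox/hydration reactions, isomerization, and five phase II conjugations,
#' including the two newly reported ones (pyroglutamic acid conjugation and
#' acetylamination). Each rule carries a signed element-count delta; the
#' hydroxylation/dehydroxylation pair is modelled as +O/-O so that H parity
#' is preserved. `max_repeats` caps how often a rule may be applied on one
#' monomer (disulphates, dimethyl and dihydroxy metabolites all occur).
#'
#' @return A tibble with columns `reaction`, `phase`, `delta` (list of signed
#'   counts), `delta_mass`, `max_repeats`, `novel`.
#' @examples
#' default_rules()
#' @export
default_rules <- function() {
  rules <- tibble::tibble(
    reaction = c("dehydration", "dehydroxylation", "hydroxylation",
                 "dehydrogenation", "hydrogenation", "hydration",
                 "isomerization", "methylation", "sulphation",
                 "glucuronidation", "pyroglutamate_conjugation",
                 "acetylamination"),
    phase = c("I", "I", "I", "I", "I", "I", "I", "II", "II", "II", "II", "II"),
    delta = list(
      c(H = -2, O = -1), c(O = -1), c(O = 1), c(H = -2), c(H = 2),
      c(H = 2, O = 1), numeric(0), c(C = 1, H = 2),
      c(S = 1, O = 3), c(C = 6, H = 8, O = 6), c(C = 5, H = 7, N = 1, O = 3),
      c(C = 2, H = 5, N = 1, O = 1)
    ),
    max_repeats = c(1L, 1L, 2L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L),
    novel = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
              FALSE, TRUE, TRUE)
  )
  rules$delta_mass <- vapply(rules$delta, counts_mass, numeric(1))
  rules
}

# Fixed priority used to order equally-sized decompositions: conjugations
# before redox before (de)hydration/isomerization.
.reaction_priority <- c(
  "sulphation", "glucuronidation", "methylation",
  "pyroglutamate_conjugation", "acetylamination",
  "dehydroxylation", "hydroxylation", "dehydrogenation", "hydrogenation",
  "dehydration", "hydration", "isomerization",
  "ring_cleavage", "polymerization"
)

#' Ring-cleavage product catalogue
#'
#' Phenolic-acid scaffolds formed by C-ring cleavage of the flavonoid core
#' (largely microbial metabolism), onto which the conjugation rules apply.
#' The catalogue is packaged as CSV and user-replaceable.
#'
#' @param path Optional path to a CSV with columns `name`, `formula`.
#' @return A tibble with columns `name`, `formula`, `mass`.
#' @export
ring_catalogue <- function(path = ms_fixture("ring_catalogue.csv")) {
  cat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("name", "formula") %in% names(cat)))
  cat$mass <- monoisotopic_mass(cat$formula)
  tibble::as_tibble(cat)
}

# Multiset helpers: reaction multisets are sorted character vectors.
multiset_key <- function(reactions) paste(sort(reactions), collapse = ";")

multiset_rank_key <- function(reactions) {
  r <- sort(match(reactions, .reaction_priority))
  paste(sprintf("%02d", r), collapse = ";")
}

#' Apply a reaction multiset to a composition
#'
#' @param x Formula string or counts vector of the starting composition.
#' @param reactions Character vector (multiset) of reaction names.
#' @param rules Rule table, see [default_rules()].
#' @return Named counts vector of the product composition.
#' @examples
#' format_formula(apply_reactions("C15H12O7", c("methylation", "sulphation")))
#' @export
apply_reactions <- function(x, reactions, rules = default_rules()) {
  counts <- as_counts(x)
  for (r in reactions) {
    i <- match(r, rules$reaction)
    if (is.na(i)) stop("unknown reaction: ", r, call. = FALSE)
    counts <- counts_add(counts, rules$delta[[i]])
  }
  if (any(counts < 0)) {
    stop("reaction multiset gives a negative composition", call. = FALSE)
  }
  counts
}

#' Enumerate candidate metabolite compositions
#'
#' Breadth-first enumeration of the biotransformation network: reaction
#' multisets of size up to `max_depth` applied to the parent and (when a ring
#' catalogue is given) to each ring-cleavage scaffold, deduplicated on
#' composition plus reaction multiset. With `allow_dimers`, all pairs of
#' parent-derived monomer nodes whose multisets use only non-conjugative
#' reactions (redox, hydration, methylation) and whose depth is at most
#' `dimer_depth` are joined as `A + B - H2` — the oxidative coupling of two
#' flavonoid units — optionally followed by one sulphation.
#'
#' @param parent Formula string or counts vector of the parent compound.
#' @param rules Rule table, see [default_rules()].
#' @param max_depth Maximum reaction multiset size per monomer (>= 0).
#' @param ring_catalogue Optional tibble of ring-cleavage scaffolds
#'   (columns `name`, `formula`); `NULL` to disable.
#' @param allow_dimers Add dimer nodes.
#' @param dimer_depth Maximum monomer depth entering dimerization.
#' @return A tibble with columns `formula`, `mass`, `mz_mh` (deprotonated-ion
#'   m/z), `reactions` (list), `depth`, `seed` (`"parent"` or scaffold name),
#'   `parents` (list; two entries for dimers).
#' @examples
#' net <- enumerate_candidates("C15H12O7", max_depth = 1)
#' @export
enumerate_candidates <- function(parent, rules = default_rules(),
                                 max_depth = 2, ring_catalogue = NULL,
                                 allow_dimers = FALSE, dimer_depth = 3) {
  stopifnot(max_depth >= 0)
  parent_counts <- as_counts(parent)
  expand <- rules[lengths(rules$delta) > 0, , drop = FALSE]

  seeds <- list(list(counts = parent_counts, reactions = character(0),
                     seed = "parent"))
  if (!is.null(ring_catalogue) && nrow(ring_catalogue) > 0) {
    for (i in seq_len(nrow(ring_catalogue))) {
      seeds[[length(seeds) + 1L]] <- list(
        counts = parse_formula(ring_catalogue$formula[i]),
        reactions = "ring_cleavage",
        seed = ring_catalogue$name[i]
      )
    }
  }

  nodes <- new.env(parent = emptyenv())
  add_node <- function(counts, reactions, seed, parents,
                       monomer_mz = numeric(0)) {
    key <- paste(format_formula(counts), multiset_key(reactions), sep = "|")
    if (!is.null(nodes[[key]])) return(FALSE)
    nodes[[key]] <- list(counts = counts, reactions = reactions, seed = seed,
                         parents = parents, monomer_mz = monomer_mz)
    TRUE
  }

  frontier <- list()
  for (s in seeds) {
    if (add_node(s$counts, s$reactions, s$seed, s$seed)) {
      frontier[[length(frontier) + 1L]] <- s
    }
  }
  depth_used <- function(reactions) sum(reactions != "ring_cleavage")
  while (length(frontier) > 0) {
    nxt <- list()
    for (node in frontier) {
      if (depth_used(node$reactions) >= max_depth) next
      for (i in seq_len(nrow(expand))) {
        rn <- expand$reaction[i]
        if (sum(node$reactions == rn) >= expand$max_repeats[i]) next
        counts <- counts_add(node$counts, expand$delta[[i]])
        if (any(counts < 0) || sum(counts) == 0) next
        reactions <- c(node$reactions, rn)
        if (add_node(counts, reactions, node$seed, node$seed)) {
          nxt[[length(nxt) + 1L]] <- list(counts = counts,
                                          reactions = reactions,
                                          seed = node$seed)
        }
      }
    }
    frontier <- nxt
  }

  all_nodes <- as.list(nodes)
  if (allow_dimers) {
    nonconj <- c("dehydroxylation", "hydroxylation", "dehydrogenation",
                 "hydrogenation", "dehydration", "hydration", "methylation")
    mono <- Filter(function(n) {
      identical(n$seed, "parent") &&
        length(n$reactions) <= dimer_depth &&
        all(n$reactions %in% nonconj)
    }, all_nodes)
    mono <- mono[order(vapply(mono, function(n) length(n$reactions),
                              integer(1)))]
    if (length(mono) > 0) {
      for (i in seq_along(mono)) {
        for (j in i:length(mono)) {
          a <- mono[[i]]; b <- mono[[j]]
          counts <- counts_subtract(counts_add(a$counts, b$counts), c(H = 2),
                                    allow_negative = TRUE)
          if (any(counts < 0)) next
          reactions <- c(a$reactions, b$reactions, "polymerization")
          parents <- c(monomer_name(parent_counts, a$reactions, rules),
                       monomer_name(parent_counts, b$reactions, rules))
          mono_mz <- c(counts_mass(a$counts), counts_mass(b$counts)) -
            .element_masses[["H"]] + .electron_mass
          add_node(counts, reactions, "dimer", parents, mono_mz)
          counts_s <- counts_add(counts, c(S = 1, O = 3))
          add_node(counts_s, c(reactions, "sulphation"), "dimer", parents,
                   mono_mz)
        }
      }
      all_nodes <- as.list(nodes)
    }
  }

  all_nodes <- unname(all_nodes)
  out <- tibble::tibble(
    formula = vapply(all_nodes, function(n) format_formula(n$counts),
                     character(1)),
    mass = vapply(all_nodes, function(n) counts_mass(n$counts), numeric(1)),
    reactions = lapply(all_nodes, function(n) sort(n$reactions)),
    depth = vapply(all_nodes, function(n) length(n$reactions), integer(1)),
    seed = vapply(all_nodes, function(n) n$seed, character(1)),
    parents = lapply(all_nodes, function(n) n$parents),
    monomer_mz = lapply(all_nodes, function(n) n$monomer_mz)
  )
  out$mz_mh <- out$mass - .element_masses[["H"]] + .electron_mass
  out <- out[order(out$depth, out$formula,
                   vapply(out$reactions, multiset_key, character(1))), ]
  out
}

# Human-readable monomer tag used in dimer provenance.
monomer_name <- function(parent_counts, reactions, rules) {
  if (length(reactions) == 0) return("parent")
  paste0("parent+", multiset_key(reactions))
}

#' Decompose a composition difference into reaction multisets
#'
#' Finds every multiset of reactions (each used at most its `max_repeats`
#' times, total size at most `max_depth`) whose summed deltas equal the
#' element-count difference between a candidate and the parent. Results are
#' ordered smallest multiset first, then by the fixed reaction-priority list
#' (conjugations before redox before hydration), then lexicographically, so
#' the first entry is the preferred interpretation. Zero-delta rules
#' (isomerization) are never used to pad a decomposition; an identical
#' composition decomposes to the empty multiset.
#'
#' @param candidate,parent Formula strings or counts vectors.
#' @param rules Rule table, see [default_rules()].
#' @param max_depth Maximum multiset size searched.
#' @return A list of character vectors (possibly empty when no decomposition
#'   exists); `list(character(0))` when the compositions are identical.
#' @examples
#' decompose_shift("C21H20O13", "C15H12O7")  # glucuronidation
#' @export
decompose_shift <- function(candidate, parent, rules = default_rules(),
                            max_depth = 4) {
  diff <- counts_subtract(as_counts(candidate), as_counts(parent),
                          allow_negative = TRUE)
  diff <- diff[diff != 0]
  expand <- rules[lengths(rules$delta) > 0, , drop = FALSE]
  els <- Reduce(union, c(list(names(diff)), lapply(expand$delta, names)))
  target <- stats::setNames(numeric(length(els)), els)
  target[names(diff)] <- diff
  deltas <- lapply(expand$delta, function(d) {
    v <- stats::setNames(numeric(length(els)), els)
    v[names(d)] <- d
    v
  })

  results <- list()
  n <- nrow(expand)
  recurse <- function(i, remaining, used) {
    if (i > n) {
      # a decomposition is any multiset whose deltas sum exactly to the
      # difference -- non-minimal ones (with cancelling pairs) included
      if (all(abs(remaining) < 1e-9)) {
        results[[length(results) + 1L]] <<- used
      }
      return(invisible())
    }
    max_k <- min(expand$max_repeats[i], max_depth - length(used))
    for (k in 0:max_k) {
      recurse(i + 1L,
              remaining - if (k > 0) k * deltas[[i]] else 0,
              c(used, rep(expand$reaction[i], k)))
    }
  }
  recurse(1L, target, character(0))
  if (length(results) == 0) return(list())
  ord <- order(lengths(results),
               vapply(results, multiset_rank_key, character(1)),
               vapply(results, multiset_key, character(1)))
  lapply(results[ord], sort)
}

#' Tally reactions across a set of identifications
#'
#' Counts, for each reaction, how many identifications invoke it at least
#' once — the bookkeeping behind a "Sum" row of a metabolic-reaction table.
#'
#' @param identifications A data frame with a `reactions` column: either a
#'   list of character vectors or `";"`-separated strings.
#' @param rules Rule table supplying the reaction order of the output; counts
#'   also cover `ring_cleavage` and `polymerization`.
#' @return A tibble with columns `reaction`, `n`.
#' @export
tally_reactions <- function(identifications, rules = default_rules()) {
  all_names <- c(rules$reaction, "ring_cleavage", "polymerization")
  rxn <- identifications$reactions
  if (is.character(rxn)) rxn <- strsplit(rxn, ";", fixed = TRUE)
  counts <- vapply(all_names, function(rn) {
    sum(vapply(rxn, function(r) rn %in% r, logical(1)))
  }, numeric(1))
  tibble::tibble(reaction = all_names, n = as.integer(counts))
}
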