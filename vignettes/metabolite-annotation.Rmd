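---
title: "Rule-based metabolite identification from accurate-mass LC-MS(n) peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based metabolite identification from accurate-mass LC-MS(n) peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metshift)
```

## The identification problem

When a single drug or food constituent is dosed in vivo, high-resolution
LC-ESI-MS^n^ of urine, plasma, faeces and organ extracts shows hundreds of
drug-derived chromatographic features. None of them comes with a structure
attached. What *is* known is (i) the parent compound's molecular formula,
(ii) a small vocabulary of biotransformation reactions, each of which shifts
the elemental composition by a fixed signed amount, and (iii) reproducible
fragmentation behaviour in negative-ion MS^2^/MS^3^. metshift implements the
rule-based strategy that turns these three pieces of knowledge into
metabolite identifications, using the in vivo metabolism of taxifolin
(dihydroquercetin, C~15~H~12~O~7~) — a flavanonol that rats transform into
191 detectable metabolites — as its worked reference system.

The pipeline has five stages, each exposed as ordinary functions on data
frames so that any stage can be used alone:

1. **Mass arithmetic and formula prediction** (`monoisotopic_mass()`,
   `ion_mz()`, `predict_formulas()`). The theoretical m/z of a deprotonated
   molecule is $m/z = M - m_\mathrm{H} + m_e$, with $M$ the monoisotopic
   neutral mass, $m_\mathrm{H}$ the hydrogen-atom mass and $m_e = 0.000549$
   Da the electron mass. Including $m_e$ matters: it shifts every value by
   half a milli-dalton and is required to hit the reference values at four
   decimal places (taxifolin's [M−H]^−^ at m/z 303.0510). Formula
   prediction enumerates all compositions within per-element bounds and a
   ppm window; it is exhaustive by construction and is tested against an
   independent brute-force oracle for exact set-and-order agreement.
2. **Biotransformation network enumeration** (`default_rules()`,
   `enumerate_candidates()`). Twelve reactions (hydroxylation ±O,
   dehydrogenation/hydrogenation ∓H~2~, (de)hydration ±H~2~O, methylation
   +CH~2~, sulphation +SO~3~, glucuronidation +C~6~H~8~O~6~, the two novel
   conjugations pyroglutamate +C~5~H~7~NO~3~ and acetylamination
   +C~2~H~5~NO, isomerization Δ=∅) are applied breadth-first to the parent
   up to a configurable multiset depth. Ring-cleavage phenolic acids enter
   as catalogue scaffolds, and dimers as A + B − H~2~ over pairs of
   monomer-layer nodes.
3. **MS^2^ corroboration** (`match_losses()`, `identify_aglycone()`).
   Conjugations betray themselves as characteristic neutral losses
   (79.9568, 176.0321, 129.0426, 59.0371 Da); the residual aglycone ion and
   its characteristic fragments pin the core scaffold.
4. **Regiochemistry** (`assign_by_clogp()`, `break_tie()`). Within a set of
   regioisomeric candidate structures, the one with the smaller computed
   logP elutes earlier on reversed phase; candidates and peaks are rank
   matched. Exactly equal ClogP values form tie groups resolved by site
   priors and relative peak areas, or emitted as composite "3′/4′" labels.
5. **Bookkeeping** (`classify_metabolite()`, `assign_level()`,
   `run_pipeline()`, `compartment_sums()`). Every identification receives
   one of eight aglycone-based classes, an identification level (1 =
   reference standard, 2 = literature/database, 3 = new compound), and
   per-compartment detection flags derived from drug-versus-blank
   comparison.

## Tunable parameters

| parameter | default | unit | why this value |
|---|---|---|---|
| `tol_ppm` | 6 | ppm | the reference identification table contains mass errors up to \|5.61\| ppm; 6 ppm covers them with no headroom to spare |
| element bounds | C≤40 H≤60 N≤2 O≤18 S≤2 | counts | spans every composition in the reference tables, including C~33~ dimer sulphates |
| `frag_tol_da` | 0.02 | Da | absolute tolerance matching the 2-dp loss arithmetic used in practice; fragment ions are lower-resolution than precursors |
| `rt_window` | 0.5 | min | blank subtraction / compartment merging / standard matching window; the source study states none, this is a conventional width for 100-min gradients |
| `max_depth` | 2 (pipeline), 4 (full reachability) | reactions | two reactions cover the bulk of phase II chemistry; all 191 reference metabolites need at most four |
| coupling threshold | 5 | % relative abundance | a monomer fragment below 5% of the base peak marks a coupling bond too strong to cleave, i.e. C-C; the decision is strict `<` |

## Design choices where the design was open

* **Adducts are an ordered preference, not a set.** The [M+NH~2~]^−^
  (equivalently [M+NH~3~−H]^−^) reading of a peak is exactly isobaric with
  the [M−H]^−^ reading of the acetylaminated composition, so trying both
  adducts symmetrically makes every acetylamination conjugate ambiguous.
  `identify_peak()` therefore accepts the deprotonated interpretation
  whenever one exists and consults the ammonia adduct only otherwise —
  mirroring how the adduct is invoked in practice (only the luteolin
  glucuronides require it).
* **Candidate ranking.** When several network nodes fit one mass the order
  is: MS^2^-consistent candidates first (a sulphate candidate without an
  SO~3~ loss or aglycone match is down-ranked), then fewest reactions, then
  MS^2^ evidence score, then smallest absolute ppm error. The ordering is
  deterministic and pinned by tests.
* **Hydroxylation is ±O, not ±OH.** Modelling the ±15.99 Da shifts as
  oxygen-only deltas preserves hydrogen parity; radical arithmetic would
  not.
* **Dimer coupling loses H~2~** regardless of C-C versus C-O type (verified
  against the printed dimer formulas); the coupling type is decided from
  MS^2^ monomer-fragment abundance, never from composition. Dimerization
  pairs monomer-layer nodes carrying only redox/hydration/methylation
  modifications (conjugation happens after coupling, as one optional
  sulphation).
* **Ring cleavage is catalogue-based.** The phenolic-acid scaffolds are
  enumerated as an explicit, user-replaceable catalogue onto which the
  conjugation rules apply, rather than by graph-based bond breaking: the
  identifiable products are specific known acids, not arbitrary fragments.
* **Decomposition ambiguity** (+O versus −H~2~ then +H~2~O, and the like)
  is resolved by smallest multiset first, then a fixed priority list —
  conjugations before redox before hydration — then lexicographic order.
  `decompose_shift()` nevertheless returns *all* multisets within depth, so
  non-minimal interpretations remain inspectable.
* **The C-5 hydroxyl** is excluded from *generated* candidate site sets
  (chelation to the 4-keto group makes it metabolically unreactive), but
  user-supplied candidate lists are never filtered — a 5-O-sulphate can
  still be assigned when the user supplies it, as the reference data in
  fact require.
* **Display conventions.** m/z is displayed at 4 dp, ppm at 2 dp, retention
  times at 3 dp, with round-half-even rounding; internal matching always
  uses full-precision masses (the 2-dp printed loss values, e.g. "129.05
  Da", are display forms of 129.0426). The ppm column of the output table
  is computed against the 4-dp-rounded predicted m/z because that is
  demonstrably how the reference table's instrument software computed it:
  with this convention 187 of 192 reference rows agree to 0.05 ppm, and
  with full-precision predictions only about half do.

## What the packaged reference tables do and do not encode

The transcribed identification table (192 rows), reaction bookkeeping table
(191 multisets) and organ-distribution matrix (47 × 8) are *inputs*, pinned
by checksum. Two transcription caveats are deliberately preserved rather
than repaired:

* The printed reaction bookkeeping contains a handful of rows whose marks
  disagree with the formula difference (e.g. glucuronide sulphates marked
  with an extra hydroxylation, unconjugated phenolic acids carrying a
  sulphation mark). The fixture reproduces the *printed* marks — its column
  sums are the published ones — while `decompose_shift()` supplies the
  formula-consistent reading; a unit test documents the divergence.
* In the luteolin glucuronide case study the published ClogP values and the
  published assignment contradict the elution-order rule itself (the
  earliest-eluting peak is assigned the *largest* ClogP). `clogp_cases()`
  flags this case `rule_consistent = FALSE`; the assigner implements the
  stated rule and consequently reproduces every case study except this
  internally inconsistent one. (If the two printed ClogP values were
  swapped, rule and assignment would agree exactly.)

## The synthetic-data generator

`sim_config()` / `generate_truth()` / `simulate_peaklists()` emulate the
statistical structure the pipeline assumes: planted metabolites are sampled
without replacement from the enumerated network; each emits, per member
compartment, a peak at its theoretical [M−H]^−^ m/z times
$(1 + \varepsilon)$, $\varepsilon \sim \mathcal{N}(0, \sigma_\mathrm{ppm})$
with $\sigma = 2$ ppm by default (matching the error spread of the
reference table); MS^2^ spectra are built from exact conjugate neutral
losses plus aglycone characteristic fragments; dimer spectra carry a
monomer fragment whose relative abundance encodes the coupling type, drawn
away from the 5% boundary (0.5–3.5% for C-C, 20–80% for C-O). Background
peaks are uniform over m/z 150–750 but rejected within three times the
instrument tolerance of any candidate mass, so a false positive count is
attributable to the pipeline, not to unlucky background. Retention times
come from a crude additive heuristic (conjugation earlier, methylation
later) — deliberately non-physical, since only ordering within isomer
groups matters downstream.

What passing recovery tests therefore *does* show: the identification
logic, blank subtraction, compartment flags and coupling calls are
internally consistent and robust at realistic mass accuracy. What it does
*not* show: robustness to chromatographic drift, co-elution, in-source
fragmentation, isotopologue interference or abundance-dependent fragment
quality — none of which the generator models.

## Problem sizes used by the test suite

The packaged checks run the full 192-row reference table through the mass
engine, re-identify all 192 measured m/z values against a depth-4 network
(about ten thousand candidate nodes), verify formula prediction against a
brute-force oracle on 50 random masses, verify decomposition against 200
random reaction multisets, and run one synthetic study with 200 planted
metabolites at 2 ppm noise. These sizes were chosen to exercise every rule
and class at full scale while keeping the whole suite comfortably fast on a
single core.

## Known limitations

* Stereoisomers are indistinguishable by construction: isomerization nodes
  share one composition, and no chiral information exists in the inputs.
* ClogP values are injected from a lookup table; the package does not
  compute logP, so the regiochemistry module is only as good as the
  supplied table.
* Only negative-ion chemistry is implemented ([M−H]^−^, [M+NH~2~]^−^,
  charge −1); positive-ion adducts and multiply charged species are out of
  scope.
* Isotope patterns are not scored; a formula candidate is judged on mass,
  DBE and MS^2^ evidence alone.
* The identification-string builder is mechanical ("methyl taxifolin
  sulphate 2"); it does not attempt trivial-name resolution.
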