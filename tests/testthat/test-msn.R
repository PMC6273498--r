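# Neutral-loss matching, aglycone identification and coupling classification.

frag <- function(mz, rel_ab = 100) tibble::tibble(mz = mz, rel_ab = rel_ab)

test_that("characteristic losses are matched at full mass precision", {
  # pyroglutamic acid loss off the sulphate-pyroglutamate conjugate
  hit <- match_losses(512.0509, frag(383.0083))
  expect_identical(hit$meaning, "pyroglutamate_conjugation")
  expect_lt(abs(hit$delta_da), 0.02)
  # SO3 loss from taxifolin sulphate down to the aglycone ion
  hit2 <- match_losses(383.0078, frag(303.0510))
  expect_identical(hit2$loss, "SO3")
  # empty fragment list matches nothing
  expect_identical(nrow(match_losses(383.0078, frag(numeric(0),
                                                    numeric(0)))), 0L)
  # each fragment matches at most one loss (the closest)
  both <- match_losses(512.0509, frag(c(383.0083, 432.0941), c(100, 40)))
  expect_identical(nrow(both), 2L)
  expect_false(anyDuplicated(both$fragment_mz) > 0)
})

test_that("loss matching has full recall on exactly constructed spectra", {
  defs <- neutral_loss_defs()
  precursor <- 559.0399
  spectrum <- frag(precursor - defs$mass, rep(100, nrow(defs)))
  spectrum <- normalize_spectrum(spectrum)
  hits <- match_losses(precursor, spectrum, defs, tol_da = 0.02)
  expect_setequal(hits$loss, defs$loss)
})

test_that("aglycone identification uses fragments then the precursor", {
  refs <- aglycone_library()
  # conjugate spectrum: aglycone ion + two characteristic fragments
  s <- frag(c(303.0510, 285.0407, 241.0524), c(100, 45, 30))
  got <- identify_aglycone(383.0078, s, refs)
  expect_identical(got$name, "taxifolin")
  expect_gte(got$n_char_matched, 2)
  # the methylated aglycone at its published [aglycone - H]- value
  got2 <- identify_aglycone(397.0235, frag(317.0667), refs)
  expect_identical(got2$name, "methyl taxifolin")
  # unconjugated peak: the precursor itself is the aglycone ion
  got3 <- identify_aglycone(303.0510, frag(285.0407, 100), refs)
  expect_identical(got3$name, "taxifolin")
  # nothing near any reference
  expect_identical(nrow(identify_aglycone(1000, frag(999.0))), 0L)
})

test_that("an unresolvable aglycone tie yields no call with a warning", {
  refs <- aglycone_library()
  # eriodictyol and dihydrokaempferol share C15H12O6: a bare aglycone ion
  # cannot distinguish them
  expect_warning(
    none <- identify_aglycone(367.0129, frag(287.0561)),
    "ambiguous"
  )
  expect_identical(nrow(none), 0L)
  # a diagnostic characteristic fragment resolves the tie
  got <- identify_aglycone(367.0129, frag(c(287.0561, 269.0431), c(100, 40)))
  expect_identical(got$name, "dihydrokaempferol")
})

test_that("fragment match score is the matched fraction of the reference", {
  refs <- aglycone_library()
  tax <- refs[refs$name == "taxifolin", ]
  full <- frag(c(285.0407, 241.0524, 177.0253, 175.0424, 125.0290),
               c(100, 50, 40, 30, 20))
  expect_identical(fragment_match_score(full, tax), 1)
  quer <- refs[refs$name == "quercetin", ]
  qfull <- frag(c(229.0526, 211.0386, 179.0015, 151.0061, 107.0230),
                c(100, 50, 40, 30, 20))
  expect_identical(fragment_match_score(qfull, quer), 1)
  expect_identical(fragment_match_score(frag(numeric(0), numeric(0)), tax), 0)
  expect_identical(fragment_match_score(full[1:2, ], tax), 2 / 5)
  expect_error(fragment_match_score(full, frag(numeric(0), numeric(0))),
               "no characteristic fragments")
})

test_that("coupling classification is a strict-threshold step function", {
  expect_identical(classify_coupling(4.08), "C-C")
  expect_identical(classify_coupling(50), "C-O")
  expect_identical(classify_coupling(5), "C-O")  # boundary is strict "<"
  expect_identical(classify_coupling(c(0, 4.99, 5.01, 100)),
                   c("C-C", "C-C", "C-O", "C-O"))
  # monotone: increasing abundance never flips C-O back to C-C
  x <- sort(runif(50, 0, 100))
  cls <- classify_coupling(x)
  expect_true(all(diff(cls == "C-O") >= 0))
  expect_error(classify_coupling(-1), "0, 100")
  expect_error(classify_coupling(101), "0, 100")
})

test_that("spectrum normalisation pins the base peak at 100", {
  s <- normalize_spectrum(frag(c(100, 200), c(20, 80)))
  expect_identical(max(s$rel_ab), 100)
  expect_identical(s$rel_ab[1], 25)
  expect_identical(nrow(normalize_spectrum(NULL)), 0L)
  expect_error(normalize_spectrum(frag(100, 0)), "positive")
})
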