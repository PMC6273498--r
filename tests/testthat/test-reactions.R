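# Reaction vocabulary, candidate enumeration and mass-shift decomposition.

test_that("default rules carry the published mass shifts", {
  rules <- default_rules()
  expect_identical(nrow(rules), 12L)
  expect_false(anyDuplicated(rules$reaction) > 0)
  delta <- function(r) rules$delta_mass[rules$reaction == r]
  expect_equal(round(delta("methylation"), 4), 14.0157)
  expect_equal(round(delta("sulphation"), 4), 79.9568)
  expect_equal(round(delta("glucuronidation"), 2), 176.03)
  expect_equal(round(delta("dehydroxylation"), 2), -15.99)
  expect_equal(round(delta("dehydrogenation"), 2), -2.02)
  expect_equal(round(delta("pyroglutamate_conjugation"), 2), 129.04)
  expect_equal(round(delta("acetylamination"), 2), 59.04)
  expect_identical(delta("isomerization"), 0)
  expect_true(all(rules$novel == (rules$reaction %in%
                                    c("pyroglutamate_conjugation",
                                      "acetylamination"))))
})

test_that("enumeration reaches the published candidate compositions", {
  sulph <- default_rules()[default_rules()$reaction == "sulphation", ]
  net1 <- enumerate_candidates("C15H12O7", rules = sulph, max_depth = 1)
  expect_true("C15H12O10S" %in% net1$formula)

  net2 <- enumerate_candidates("C15H12O7", max_depth = 2)
  expect_true("C22H22O13" %in% net2$formula)  # methyl + glucuronyl

  net0 <- enumerate_candidates("C15H12O7", max_depth = 0)
  expect_identical(net0$formula, "C15H12O7")
  expect_identical(net0$reactions[[1]], character(0))

  # empty rule set: just the parent
  net_empty <- enumerate_candidates("C15H12O7",
                                    rules = default_rules()[0, ],
                                    max_depth = 3)
  expect_identical(net_empty$formula, "C15H12O7")
})

test_that("dimer nodes combine two monomers with loss of H2", {
  net <- enumerate_candidates("C15H12O7", max_depth = 2, allow_dimers = TRUE)
  # taxifolin + dehydroxylated methyl taxifolin -> C31H24O13
  expect_true("C31H24O13" %in% net$formula[net$seed == "dimer"])
  dim_rows <- net[net$seed == "dimer", ]
  expect_true(all(lengths(dim_rows$parents) == 2))
  expect_true(all(lengths(dim_rows$monomer_mz) == 2))
  # composition identity: dimer = A + B - H2 (+ optional SO3)
  h2 <- monoisotopic_mass("H2")
  for (i in seq_len(nrow(dim_rows))) {
    mono_mass <- sum(dim_rows$monomer_mz[[i]]) +
      2 * (monoisotopic_mass("H") - 0.00054857990907)
    expected <- mono_mass - h2 +
      if ("sulphation" %in% dim_rows$reactions[[i]])
        monoisotopic_mass("SO3") else 0
    expect_equal(dim_rows$mass[i], expected, tolerance = 1e-9)
  }
})

test_that("enumeration is deduplicated and idempotent at depth zero", {
  net <- enumerate_candidates("C15H12O7", max_depth = 2,
                              ring_catalogue = ring_catalogue())
  keys <- paste(net$formula,
                vapply(net$reactions, function(r) paste(sort(r), collapse = ";"),
                       character(1)))
  expect_false(anyDuplicated(keys) > 0)
  # re-enumerating any node at depth 0 returns exactly that node
  for (i in sample(nrow(net), 5)) {
    again <- enumerate_candidates(net$formula[i], max_depth = 0)
    expect_identical(again$formula, net$formula[i])
  }
})

test_that("every published metabolite formula is reachable at depth four", {
  net <- full_network()
  t1 <- tax_table1()
  metabolites <- t1$formula[t1$id != "TAX"]
  expect_true(all(metabolites %in% net$formula))
})

test_that("decomposition recovers published reaction multisets", {
  expect_identical(decompose_shift("C21H20O13", "C15H12O7")[[1]],
                   "glucuronidation")
  ident <- decompose_shift("C15H12O7", "C15H12O7")
  expect_identical(ident[[1]], character(0))  # the empty multiset leads
  expect_identical(
    decompose_shift("C22H22O16S", "C15H12O7")[[1]],
    c("glucuronidation", "methylation", "sulphation")
  )
  # no decomposition within depth -> empty list
  expect_identical(decompose_shift("C15H12O7", "CH4", max_depth = 2), list())
  # smallest multiset first: +O beats -H2 + H2O
  first <- decompose_shift("C15H12O8", "C15H12O7")[[1]]
  expect_identical(first, "hydroxylation")
})

test_that("decompose is a left inverse of apply on random multisets", {
  set.seed(7)
  rules <- default_rules()
  usable <- rules$reaction[lengths(rules$delta) > 0]
  parent <- "C15H12O7"
  n_checked <- 0
  while (n_checked < 200) {
    size <- sample(1:3, 1)
    ms <- character(0)
    for (k in seq_len(size)) {
      pool <- usable[vapply(usable, function(r) {
        sum(ms == r) < rules$max_repeats[rules$reaction == r]
      }, logical(1))]
      ms <- c(ms, sample(pool, 1))
    }
    product <- tryCatch(apply_reactions(parent, ms), error = function(e) NULL)
    if (is.null(product)) next
    n_checked <- n_checked + 1
    res <- decompose_shift(product, parent, max_depth = 3)
    keys <- vapply(res, function(r) paste(sort(r), collapse = ";"),
                   character(1))
    expect_true(paste(sort(ms), collapse = ";") %in% keys)
    # when the applied multiset is the unique minimal one, it comes first
    min_size <- min(lengths(res))
    if (length(ms) == min_size && sum(lengths(res) == min_size) == 1) {
      expect_identical(sort(res[[1]]), sort(ms))
    }
  }
})

test_that("reaction tallies count identifications containing each reaction", {
  ids <- tibble::tibble(reactions = list(
    c("sulphation", "sulphation"),
    c("methylation", "sulphation"),
    character(0)
  ))
  tal <- tally_reactions(ids)
  expect_identical(tal$n[tal$reaction == "sulphation"], 2L)
  expect_identical(tal$n[tal$reaction == "methylation"], 1L)
  expect_identical(tal$n[tal$reaction == "glucuronidation"], 0L)
  empty <- tally_reactions(tibble::tibble(reactions = list()))
  expect_true(all(empty$n == 0L))
  # ";"-separated strings are accepted too
  tal2 <- tally_reactions(tibble::tibble(reactions = "sulphation;methylation"))
  expect_identical(tal2$n[tal2$reaction == "sulphation"], 1L)
})

test_that("formula-inconsistent printed bookkeeping rows are documented", {
  # the published reaction table marks hydroxylation for the glucuronide
  # sulphates M26-M32, but their formula difference is exactly glucuronyl +
  # SO3; the mass-shift decomposition records the formula-consistent version
  t2 <- tax_table2()
  stated <- strsplit(t2$reactions[t2$id == "M26"], ";")[[1]]
  expect_true("hydroxylation" %in% stated)
  minimal <- decompose_shift("C21H20O16S", "C15H12O7")[[1]]
  expect_identical(minimal, c("glucuronidation", "sulphation"))
})
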