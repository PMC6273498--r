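# Ground-truth generation and synthetic peak-list structure.

test_that("truth sampling honours size, dimer fraction and reachability", {
  cfg <- sim_config(n_metabolites = 40, max_depth = 2, dimer_fraction = 0.15,
                    seed = 1)
  truth <- generate_truth(cfg)
  expect_identical(nrow(truth), 40L)
  expect_false(anyDuplicated(truth$formula) > 0)
  expect_identical(sum(truth$n_parents == 2), 6L)  # round(40 * 0.15)
  # every monomer entry decomposes back to its seed within the rule set
  cat <- ring_catalogue()
  for (i in which(truth$n_parents == 1)) {
    seed_formula <- if (truth$seed[i] == "parent") cfg$parent else
      cat$formula[cat$name == truth$seed[i]]
    res <- decompose_shift(truth$formula[i], seed_formula, max_depth = 2)
    expect_gt(length(res), 0)
  }
  # reproducibility under the same seed
  expect_identical(generate_truth(cfg), truth)
  # every entry belongs to at least one compartment
  member <- as.matrix(tibble::as_tibble(truth)[cfg$compartments])
  expect_true(all(rowSums(member) >= 1))
})

test_that("degenerate truth configurations behave", {
  expect_identical(nrow(generate_truth(sim_config(n_metabolites = 0))), 0L)
  expect_error(generate_truth(sim_config(n_metabolites = 100000)),
               "exceeds")
  all_dim <- generate_truth(sim_config(n_metabolites = 5, dimer_fraction = 1,
                                       seed = 2))
  expect_true(all(all_dim$n_parents == 2))
  # dimer composition identity A + B - H2 at the mass level
  for (i in seq_len(nrow(all_dim))) {
    mono_neutral <- sum(all_dim$monomer_mz[[i]]) +
      2 * (monoisotopic_mass("H") - 0.00054857990907)
    base <- mono_neutral - monoisotopic_mass("H2")
    neutral <- monoisotopic_mass(all_dim$formula[i])
    extra <- neutral - base
    expect_true(abs(extra) < 1e-9 ||
                  abs(extra - monoisotopic_mass("SO3")) < 1e-9)
  }
})

test_that("noiseless simulation emits exact theoretical masses", {
  cfg <- sim_config(n_metabolites = 10, sigma_ppm = 0, seed = 3, n_blank = 5)
  truth <- generate_truth(cfg)
  pl <- simulate_peaklists(truth, cfg)
  planted <- pl$drug[pl$drug$peak_id %in%
                       paste0(rep(truth$id, each = 3), "_",
                              rep(cfg$compartments, nrow(truth))), ]
  for (i in seq_len(nrow(planted))) {
    tid <- sub("_.*$", "", planted$peak_id[i])
    expect_lt(abs(planted$mz[i] - truth$mz[truth$id == tid]), 1e-9)
  }
  # absence from a compartment means no drug peak there
  for (i in seq_len(nrow(truth))) {
    for (cl in cfg$compartments) {
      present <- paste0(truth$id[i], "_", cl) %in% pl$drug$peak_id
      expect_identical(present, truth[[cl]][i])
    }
  }
})

test_that("mass noise has the configured ppm spread", {
  cfg <- sim_config(n_metabolites = 80, sigma_ppm = 2, seed = 7,
                    detect_prob = 1, n_blank = 0)
  truth <- generate_truth(cfg)
  pl <- simulate_peaklists(truth, cfg)
  drug <- pl$drug[grepl("^T", pl$drug$peak_id), ]
  tid <- sub("_.*$", "", drug$peak_id)
  ppm <- ppm_error(drug$mz, truth$mz[match(tid, truth$id)])
  expect_gt(length(ppm), 200)
  expect_lte(stats::quantile(abs(ppm), 0.95), 4.5)  # ~1.96 sigma = 3.9
})

test_that("simulated spectra have a base peak and encode coupling", {
  cfg <- sim_config(n_metabolites = 12, dimer_fraction = 0.5, seed = 5)
  truth <- generate_truth(cfg)
  pl <- simulate_peaklists(truth, cfg)
  planted <- pl$drug[grepl("^T", pl$drug$peak_id), ]
  for (i in seq_len(nrow(planted))) {
    s <- planted$ms2[[i]]
    expect_identical(sum(s$rel_ab == 100), 1L)
    expect_true(all(s$rel_ab > 0 & s$rel_ab <= 100))
  }
  # dimer spectra put the monomer fragment on the right side of 5%
  for (i in which(truth$n_parents == 2)) {
    row <- planted[sub("_.*$", "", planted$peak_id) == truth$id[i], ][1, ]
    s <- row$ms2[[1]]
    mono <- truth$monomer_mz[[i]][1]
    ab <- s$rel_ab[which.min(abs(s$mz - mono))]
    expect_identical(classify_coupling(ab), truth$coupling[i])
  }
})

test_that("background peaks stay clear of candidate masses", {
  cfg <- sim_config(n_metabolites = 10, seed = 11, n_blank = 30)
  truth <- generate_truth(cfg)
  pl <- simulate_peaklists(truth, cfg, tol_ppm = 6)
  net <- enumerate_candidates(cfg$parent, cfg$rules, cfg$max_depth,
                              ring_catalogue = ring_catalogue(),
                              allow_dimers = TRUE)
  for (mz in pl$blank$mz) {
    expect_gt(min(abs(ppm_error(mz, net$mz_mh))), 18)  # 3 x 6 ppm
  }
})

test_that("a small round trip recovers the planted truth", {
  cfg <- sim_config(n_metabolites = 30, seed = 13, dimer_fraction = 0.1)
  truth <- generate_truth(cfg)
  pl <- simulate_peaklists(truth, cfg)
  ann <- run_pipeline(pl$drug, pl$blank,
                      config = pipeline_config(max_depth = 2,
                                               allow_dimers = TRUE))
  rec <- evaluate_recovery(ann, truth, cfg, blank = pl$blank)
  expect_gte(rec$formula_recovery, 0.95)
  expect_identical(rec$n_background_ids, 0L)
  expect_identical(rec$coupling_accuracy, 1)
})
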