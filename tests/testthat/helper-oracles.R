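# Independent oracles and shared (cached) fixtures for the test suite.

# Monoisotopic masses restated independently of the package internals.
oracle_masses <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100)
oracle_electron <- 0.00054857990907

# Brute-force formula prediction for the deprotonated ion: a full nested grid
# over element counts, filtered and ordered exactly as the contract states.
oracle_predict <- function(mz, tol_ppm, bounds) {
  grid <- expand.grid(C = 0:bounds[["C"]], H = 0:bounds[["H"]],
                      N = 0:bounds[["N"]], O = 0:bounds[["O"]],
                      S = 0:bounds[["S"]])
  mass <- as.matrix(grid) %*% oracle_masses[c("C", "H", "N", "O", "S")]
  pred <- as.numeric(mass) - oracle_masses[["H"]] + oracle_electron
  ppm <- (mz - pred) / pred * 1e6
  dbe <- grid$C - grid$H / 2 + grid$N / 2 + 1
  # the deprotonated ion needs at least one H on the neutral molecule
  ok <- abs(ppm) <= tol_ppm + 1e-12 & dbe >= 0 & rowSums(grid) > 0 &
    grid$H >= 1
  grid <- grid[ok, , drop = FALSE]
  # Hill notation: with carbon present C, H first then alphabetical; without
  # carbon all elements alphabetical
  hill <- function(i) {
    parts <- c(C = grid$C[i], H = grid$H[i], N = grid$N[i], O = grid$O[i],
               S = grid$S[i])
    parts <- parts[parts > 0]
    if (!"C" %in% names(parts)) parts <- parts[order(names(parts))]
    paste0(names(parts), ifelse(parts == 1, "", parts), collapse = "")
  }
  out <- data.frame(
    formula = vapply(seq_len(nrow(grid)), hill, character(1)),
    predicted_mz = pred[ok],
    ppm = ppm[ok],
    dbe = dbe[ok],
    stringsAsFactors = FALSE
  )
  out[order(abs(out$ppm), out$dbe, out$formula), , drop = FALSE]
}

# A full-depth candidate network is expensive to build; cache it per session.
.test_cache <- new.env(parent = emptyenv())

full_network <- function() {
  if (is.null(.test_cache$net)) {
    .test_cache$net <- enumerate_candidates(
      "C15H12O7", max_depth = 4, ring_catalogue = ring_catalogue(),
      allow_dimers = TRUE
    )
  }
  .test_cache$net
}

# Random physical composition for additivity checks.
random_counts <- function() {
  n <- c(C = sample(0:30, 1), H = sample(0:40, 1), N = sample(0:3, 1),
         O = sample(0:15, 1), S = sample(0:2, 1))
  n[n > 0]
}
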