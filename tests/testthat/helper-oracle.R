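# Brute-force linear-programming oracle for the engineered scenario:
# maximise ethanol = 2 f + 2 r over the balance polytope by enumerating its
# basic feasible vertices (the system has one degree of freedom, so every
# vertex pins one sign-constrained variable at zero). Independent of the
# solver implementation, which works branch-wise on the allocation rule.
lp_max_ethanol <- function(params) {
  p <- params
  ac <- p$atp_coeffs
  b <- p$n_co2_biomass
  # variable order: f, g, x, o, n, r   (n is sign-free)
  Aeq <- rbind(
    c(1, 1 / 2, (1 + b) / 6, 1, 5 / 6, 0),                       # carbon
    c(0, -1, p$n_nadh, 0, 0, -2),                                # NADH
    c(0, 0, -p$n_nadph, 2, 0, 0),                                # NADPH
    c(0, 0, 0, 1, 1, -1),                                        # Ru5P
    if (p$y_atp > 0)
      c(p$y_atp * ac$ferment, p$y_atp * ac$glycerol, -1,
        p$y_atp * ac$oxppp_hexose, p$y_atp * ac$nonoxppp_ru5p,
        p$y_atp * ac$rubisco)                                    # ATP coupling
    else c(0, 0, 1, 0, 0, 0))                                    # x = 0
  beq <- c(100, 0, 0, 0, 0)
  pins <- list(c(1, 0, 0, 0, 0, 0),   # f = 0
               c(0, 1, 0, 0, 0, 0),   # g = 0
               c(0, 0, 1, 0, 0, 0),   # x = 0
               c(0, 0, 0, 0, 0, 1))   # r = 0
  best <- -Inf
  for (pin in pins) {
    z <- tryCatch(solve(rbind(Aeq, pin), c(beq, 0)), error = function(e) NULL)
    if (is.null(z)) next
    if (all(z[c(1, 2, 3, 4, 6)] >= -1e-7))
      best <- max(best, 2 * z[1] + 2 * z[6])
  }
  best
}

# Random but physiologically shaped parameter sets: biosynthetic NADH excess
# over NADPH demand (the premise of the glycerol problem), moderate ATP
# yields; biosynthetic CO2 release electron-consistent by construction.
random_stoich_params <- function() {
  n_nadh <- stats::runif(1, 0.15, 0.32)
  stoich_params(n_nadh = n_nadh,
                n_nadph = stats::runif(1, 0.06, n_nadh - 0.03),
                y_atp = stats::runif(1, 0.30, 0.55))
}

table1_duplicates <- function(mean, mdev) c(mean - mdev, mean + mdev)

ymeans <- function(y) {
  vapply(y[c("Y_biomass", "Y_ethanol", "Y_glycerol")], mean, numeric(1))
}
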