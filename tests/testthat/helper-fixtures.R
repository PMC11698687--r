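# Shared fixtures. Test signals are synthesized with the closed-form
# mono/multi-exponential expressions directly (independent of
# predict_signal, which is itself under test).

# isotropic mixture signal: fractions f at ADCs D (um^2/ms), b in s/mm^2
iso_mixture_signal <- function(bvals, adcs, fracs) {
  stopifnot(length(adcs) == length(fracs))
  drop(exp(-outer(bvals * 1e-3, adcs)) %*% fracs)
}

# single axially symmetric tensor signal along unit direction u
tensor_signal <- function(scheme, lambda_par, lambda_perp, u) {
  be <- scheme$bvals * 1e-3
  c2 <- drop(crossprod(scheme$bvecs, u))^2
  exp(-be * lambda_perp) * exp(-be * (lambda_par - lambda_perp) * c2)
}

fixture_scheme <- function(seed = 1L) scheme_ex_vivo(seed)

fixture_dictionary <- function() build_dictionary()

# exhaustive two-atom oracle: best pair of dictionary columns and mixing
# fraction on a 0.01 grid, by residual
two_atom_oracle <- function(A, y, f_grid = seq(0, 1, by = 0.01)) {
  best <- list(res = Inf)
  n <- ncol(A)
  for (j1 in 1:(n - 1)) for (j2 in (j1 + 1):n) {
    for (f in f_grid) {
      r <- sqrt(sum((f * A[, j1] + (1 - f) * A[, j2] - y)^2))
      if (r < best$res) best <- list(res = r, j1 = j1, j2 = j2, f = f)
    }
  }
  best
}

# mass of an iso spectrum within +/- one grid step of a target ADC
mass_near <- function(spectrum, dictionary, target, steps = 1L) {
  D <- dictionary$iso_adcs
  i <- which.min(abs(D - target))
  lo <- D[max(1L, i - steps)]; hi <- D[min(length(D), i + steps)]
  sum(spectrum$iso_fractions[D >= lo & D <= hi])
}
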