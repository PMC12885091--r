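# Shared fixtures: default tissue optics and slow independent oracles.

default_optics <- optical_properties()

# Independent evaluation of the semi-infinite field autocorrelation,
# written out from the closed form (not calling the package's g1).
oracle_g1 <- function(tau, bfi, op = default_optics) {
  a <- 3 * op$mu_a * op$mu_s_prime
  b <- 6 * op$mu_s_prime^2 * (2 * pi * op$n_tissue / op$wavelength)^2 * bfi
  gp <- function(k) exp(-k * op$r1) / op$r1 - exp(-k * op$rb) / op$rb
  gp(sqrt(a + b * tau)) / gp(sqrt(a))
}

# Brute-force trapezoidal Riemann evaluation of the visibility integral
# K^2 = (2 beta / T) int_0^T (1 - tau/T) g1^2 dtau on a uniform grid.
oracle_k2_riemann <- function(T, bfi, beta, op = default_optics,
                              n_sub = 1e6) {
  tau <- seq(0, T, length.out = n_sub + 1)
  f <- (1 - tau / T) * oracle_g1(tau, bfi, op)^2
  beta * 2 / T * (sum(f) - (f[1] + f[length(f)]) / 2) * (T / n_sub)
}

# Root-solve the forward model for BFI at one exposure (bisection oracle
# for the look-up-table inversion).
oracle_invert_bisect <- function(T, k2_obs, beta, op = default_optics,
                                 lower = 0.1e-8, upper = 8e-8) {
  stats::uniroot(function(f) k2_model(T, f, beta, op) - k2_obs,
                 c(lower, upper), tol = 1e-14)$root
}
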