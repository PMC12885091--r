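#' Tissue and measurement optical properties
#'
#' Bundles the optical parameters of a semi-infinite diffuse speckle
#' measurement and precomputes the derived boundary quantities used by the
#' correlation diffusion model: the wavenumber in tissue `k0`, the effective
#' source depth `z0 = 1/mu_s_prime`, the effective reflection coefficient
#' `R_eff` at the tissue/medium interface, the extrapolated-boundary distance
#' `zb`, and the source/image distances `r1` and `rb` to the detector.
#'
#' All lengths are in centimetres; the blood flow index is in cm^2/s
#' throughout the package.
#'
#' @param mu_a absorption coefficient, 1/cm.
#' @param mu_s_prime reduced scattering coefficient, 1/cm.
#' @param wavelength vacuum wavelength of the source, cm (785 nm = 785e-7).
#' @param n_tissue refractive index of tissue.
#' @param n_medium refractive index of the outside medium.
#' @param rho source-detector separation, cm.
#'
#' @return An object of class `optical_properties`: a list with the input
#'   fields plus derived `k0`, `z0`, `R_eff`, `zb`, `r1`, `rb`.
#' @examples
#' op <- optical_properties()
#' op$R_eff  # about 0.53 for n_tissue/n_medium = 1.4
#' @export
optical_properties <- function(mu_a = 0.1, mu_s_prime = 10,
                               wavelength = 785e-7,
                               n_tissue = 1.4, n_medium = 1.0,
                               rho = 3) {
  vals <- c(mu_a = mu_a, mu_s_prime = mu_s_prime, wavelength = wavelength,
            n_tissue = n_tissue, n_medium = n_medium, rho = rho)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all optical properties must be finite and strictly positive")
  if (n_tissue < n_medium || n_medium < 1)
    stop("refractive indices must satisfy n_tissue >= n_medium >= 1")

  R_eff <- effective_reflection(n_tissue / n_medium)
  z0 <- 1 / mu_s_prime
  zb <- 2 * (1 + R_eff) / (3 * mu_s_prime * (1 - R_eff))
  op <- list(
    mu_a = mu_a, mu_s_prime = mu_s_prime, wavelength = wavelength,
    n_tissue = n_tissue, n_medium = n_medium, rho = rho,
    k0 = 2 * pi * n_tissue / wavelength,
    z0 = z0,
    R_eff = R_eff,
    zb = zb,
    r1 = sqrt(rho^2 + z0^2),
    rb = sqrt(rho^2 + (z0 + 2 * zb)^2)
  )
  class(op) <- "optical_properties"
  op
}

#' Effective reflection coefficient at a refractive-index mismatch
#'
#' Polynomial approximation of the internal reflection coefficient for the
#' extrapolated-boundary condition of the photon diffusion equation,
#' `R_eff = -1.440 n^-2 + 0.710 n^-1 + 0.668 + 0.0636 n`, where
#' `n = n_tissue / n_medium >= 1`.
#'
#' @param n_rel refractive-index ratio tissue/medium, must be >= 1.
#' @return The effective reflection coefficient, a number in `[0, 1)`.
#' @examples
#' effective_reflection(1.4)  # ~0.5295
#' @export
effective_reflection <- function(n_rel) {
  if (!is.numeric(n_rel) || length(n_rel) != 1L || !is.finite(n_rel))
    stop("'n_rel' must be a single finite number")
  if (n_rel < 1)
    stop("'n_rel' must be >= 1 (tissue index at least the medium index)")
  -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("Optical properties (semi-infinite geometry)\n")
  cat(sprintf("  mu_a = %g 1/cm, mu_s' = %g 1/cm, lambda = %g nm\n",
              x$mu_a, x$mu_s_prime, x$wavelength * 1e7))
  cat(sprintf("  n_tissue = %g, n_medium = %g, rho = %g cm\n",
              x$n_tissue, x$n_medium, x$rho))
  cat(sprintf("  derived: k0 = %.4g 1/cm, z0 = %.4g cm, R_eff = %.4f,\n",
              x$k0, x$z0, x$R_eff))
  cat(sprintf("           zb = %.4g cm, r1 = %.6g cm, rb = %.6g cm\n",
              x$zb, x$r1, x$rb))
  invisible(x)
}

#' Read optical and flow parameters from a configuration file
#'
#' Reads a YAML or JSON file with any of the fields accepted by
#' [optical_properties()]; missing fields take the package defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `optical_properties` object.
#' @export
read_optics_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("mu_a", "mu_s_prime", "wavelength", "n_tissue", "n_medium", "rho")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(optical_properties, cfg[intersect(names(cfg), known)])
}

is_optics <- function(x) inherits(x, "optical_properties")
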