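#' Analytic spherical-conductor lead field
#'
#' Forward model mapping unit current dipoles to radial magnetometers on a
#' sphere. The field of a dipole inside a spherically symmetric conductor is
#' evaluated with the closed-form expression for the external magnetic field
#' (volume currents accounted for analytically); each sensor measures the
#' radially oriented component at its position. Radially oriented dipoles
#' are magnetically silent in this geometry, so each source contributes two
#' effective (tangential) degrees of freedom even though three orthogonal
#' gain columns are returned.
#'
#' Units are arbitrary but consistent (the vacuum-permeability prefactor is
#' dropped); positions are in meters.
#'
#' @param channel_positions Numeric matrix, channels x 3.
#' @param source_positions Numeric matrix, sources x 3, strictly inside the
#'   sensor shell.
#' @param center Sphere center; defaults to the centroid of the channel
#'   positions, which makes the gains invariant to a common translation of
#'   sensors and sources.
#' @param channel_names Optional channel labels.
#' @param source_labels Optional source labels.
#' @return An object of class `leadfield`: `gains` is a list (one element
#'   per source) of channels x 3 matrices whose columns are the gains of
#'   unit dipoles along x, y, z.
#' @export
build_spherical_leadfield <- function(channel_positions, source_positions,
                                      center = NULL,
                                      channel_names = NULL,
                                      source_labels = NULL) {
  channel_positions <- as.matrix(channel_positions)
  source_positions <- as.matrix(source_positions)
  if (!all(is.finite(channel_positions)) || !all(is.finite(source_positions))) {
    stop_invalid("positions must be finite")
  }
  if (is.null(center)) center <- colMeans(channel_positions)
  ch <- sweep(channel_positions, 2, center)
  src <- sweep(source_positions, 2, center)
  ch_r <- sqrt(rowSums(ch^2))
  src_r <- sqrt(rowSums(src^2))
  if (any(src_r < 1e-9)) {
    stop_invalid("degenerate geometry: source at the sphere center")
  }
  if (any(src_r >= min(ch_r))) {
    stop_invalid("sources must lie strictly inside the sensor shell")
  }
  n_src <- nrow(src)
  if (is.null(channel_names)) {
    channel_names <- sprintf("MEG%03d", seq_len(nrow(ch)))
  }
  if (is.null(source_labels)) source_labels <- sprintf("src%02d", seq_len(n_src))
  gains <- lapply(seq_len(n_src), function(s) {
    g <- sapply(1:3, function(k) {
      q <- c(0, 0, 0); q[k] <- 1
      sarvas_radial(ch, src[s, ], q)
    })
    dimnames(g) <- list(channel_names, c("qx", "qy", "qz"))
    g
  })
  names(gains) <- source_labels
  structure(list(
    gains = gains,
    channel_positions = channel_positions,
    source_positions = source_positions,
    center = center,
    channel_names = channel_names,
    source_labels = source_labels
  ), class = "leadfield")
}

# Radial component of the external field of a current dipole q at position
# r0 inside a spherical conductor, evaluated at sensor positions R (rows).
# All positions are relative to the sphere center. For the radial component
# the volume-current contribution vanishes, so this reduces to the radial
# projection of the primary-dipole field; the full closed-form field is used
# here, the reduction serving as an independent oracle in the tests.
sarvas_radial <- function(R, r0, q) {
  qxr0 <- cross3(q, r0)
  vapply(seq_len(nrow(R)), function(i) {
    r <- R[i, ]
    rn <- sqrt(sum(r^2))
    a_vec <- r - r0
    a <- sqrt(sum(a_vec^2))
    ar <- sum(a_vec * r)
    f <- a * (rn * a + rn^2 - sum(r0 * r))
    grad_f <- (a^2 / rn + ar / a + 2 * a + 2 * rn) * r -
      (a + 2 * rn + ar / a) * r0
    b <- (f * qxr0 - sum(qxr0 * r) * grad_f) / f^2
    sum(b * r) / rn
  }, numeric(1))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d channels, %d sources (spherical model)\n",
              nrow(x$channel_positions), length(x$gains)))
  invisible(x)
}

#' Quasi-uniform sensor/source geometry for simulations
#'
#' Places `n_channels` radial magnetometers on the upper half of a sphere
#' (Fibonacci lattice) and `n_sources` sources well inside the shell,
#' spread over the upper hemisphere. Purely synthetic: no head realism is
#' attempted.
#'
#' @param n_channels Number of sensors (default 30).
#' @param n_sources Number of sources (default 3).
#' @param radius Sensor shell radius in meters (default 0.12).
#' @param source_depth Fraction of the radius at which sources sit
#'   (default 0.6).
#' @param source_labels Optional labels.
#' @return A list with `channel_positions`, `source_positions`,
#'   `channel_names`, `source_labels`.
#' @export
meg_geometry <- function(n_channels = 30L, n_sources = 3L, radius = 0.12,
                         source_depth = 0.6, source_labels = NULL) {
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_channels)
  z <- -0.35 + 1.3 * (k - 0.5) / n_channels  # wide band keeps centroid central
  theta <- golden * k
  rho <- sqrt(pmax(1 - z^2, 0))
  ch <- radius * cbind(rho * cos(theta), rho * sin(theta), z)
  k2 <- seq_len(n_sources)
  z2 <- rep(0.5, n_sources)
  th2 <- 0.5 + 2 * pi * (k2 - 1L) / n_sources # spread, offset from lattice
  rho2 <- sqrt(pmax(1 - z2^2, 0))
  src <- source_depth * radius * cbind(rho2 * cos(th2), rho2 * sin(th2), z2)
  if (is.null(source_labels)) source_labels <- sprintf("src%02d", k2)
  list(
    channel_positions = ch,
    source_positions = src,
    channel_names = sprintf("MEG%03d", k),
    source_labels = source_labels
  )
}
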