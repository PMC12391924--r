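#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Build a helmet-like array of radial magnetometers
#'
#' Places \code{nSensors} points quasi-uniformly (Fibonacci spiral) on the
#' upper spherical cap covering \code{capFraction} of the sphere surface, at
#' the given radius, each sensing the radial field component (orientation =
#' position / radius). A single sensor is placed at the cap apex
#' \code{(0, 0, radius)}.
#'
#' @param nSensors number of magnetometers (positive integer).
#' @param radius helmet radius in meters (must exceed the source sphere).
#' @param capFraction fraction of the sphere surface covered by the helmet
#'   cap, in (0, 1]. The default 0.6 approximates a whole-head helmet.
#' @return a \linkS4class{SensorArray}
#' @examples
#' helmet <- buildSensorHelmet(127, radius = 0.12)
#' nSensors(helmet)
#' @export
buildSensorHelmet <- function(nSensors, radius = 0.12, capFraction = 0.6) {
  if (length(nSensors) != 1L || is.na(nSensors) || nSensors < 1)
    .stopInvalidGeometry("nSensors must be a positive integer")
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    .stopInvalidGeometry("radius must be positive")
  if (capFraction <= 0 || capFraction > 1)
    .stopInvalidGeometry("capFraction must be in (0, 1]")
  n <- as.integer(nSensors)
  if (n == 1L) {
    z <- radius
    xy <- matrix(0, 1, 2)
  } else {
    # cap z-range [R(1-2f), R]; mid-cell offsets give good uniformity
    i <- seq_len(n)
    z <- radius * (1 - 2 * capFraction * (i - 0.5) / n)
    golden <- pi * (3 - sqrt(5))
    az <- (i - 1) * golden
    rho <- sqrt(pmax(radius^2 - z^2, 0))
    xy <- cbind(rho * cos(az), rho * sin(az))
  }
  pos <- cbind(xy, z)
  colnames(pos) <- c("x", "y", "z")
  new("SensorArray", positions = pos, orientations = pos / radius)
}

#' Build a cubic dipole lattice inside a spherical source volume
#'
#' Generates the regular cubic lattice of step \code{spacing} centered at the
#' origin and keeps the points with norm strictly less than \code{radius}.
#' Each dipole is assigned a fixed unit tangential orientation drawn
#' deterministically from \code{orientationSeed} (radial dipoles are silent
#' in the spherically symmetric conductor, so tangential moments carry all
#' the measurable signal). If the origin lattice point is retained its
#' orientation is the fixed +x axis and its index is flagged in
#' \code{originIndex}.
#'
#' @param radius source sphere radius, meters.
#' @param spacing lattice step, meters (default 5 mm).
#' @param orientationSeed integer seed for the tangential orientations.
#' @return a \linkS4class{SourceSpace}
#' @examples
#' grid <- buildSourceGrid(radius = 0.08, spacing = 0.02)
#' voxelVolume(grid)  # cm^3
#' @export
buildSourceGrid <- function(radius, spacing = 0.005, orientationSeed = 7L) {
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    .stopInvalidGeometry("spacing must be positive")
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    .stopInvalidGeometry("radius must be positive")
  kmax <- floor(radius / spacing)
  ax <- (-kmax:kmax) * spacing
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  keep <- sqrt(rowSums(g^2)) < radius
  pos <- g[keep, , drop = FALSE]
  # stable ordering: z, then y, then x
  ord <- order(pos[, 3], pos[, 2], pos[, 1])
  pos <- pos[ord, , drop = FALSE]
  D <- nrow(pos)
  rad <- sqrt(rowSums(pos^2))
  originIndex <- if (any(rad == 0)) which(rad == 0) else 0L
  ori <- .withSeed(orientationSeed, {
    o <- matrix(0, D, 3)
    for (d in seq_len(D)) {
      if (d == originIndex) { o[d, ] <- c(1, 0, 0); next }
      p <- pos[d, ] / rad[d]
      repeat {
        v <- stats::rnorm(3)
        tang <- v - sum(v * p) * p
        nt <- sqrt(sum(tang^2))
        if (nt > 1e-6) { o[d, ] <- tang / nt; break }
      }
    }
    o
  })
  rownames(pos) <- NULL
  new("SourceSpace", positions = pos, orientations = ori,
      spacing = spacing, radius = radius, originIndex = as.integer(originIndex))
}

#' Radial magnetometer reading of a single current dipole
#'
#' Closed-form spherical-conductor solution: for a sensor at \code{r} reading
#' the radial field component and a dipole of unit moment along \code{theta}
#' at \code{rq},
#' \deqn{L = \frac{\mu_0}{4\pi}\,
#'   \frac{(\mathbf{r} \times \mathbf{r}_q)\cdot\Theta}
#'        {\|\mathbf{r}\|\,\|\mathbf{r}-\mathbf{r}_q\|^3}.}
#' Volume currents contribute nothing to the radial component in a
#' spherically symmetric conductor, so this equals the radial part of the
#' primary (free-space dipole) field. It is linear in \code{theta} and
#' vanishes for radial dipoles and for a dipole at the origin.
#'
#' @param sensorPosition 3-vector, meters (nonzero).
#' @param dipolePosition 3-vector, meters.
#' @param dipoleOrientation unit 3-vector.
#' @return scalar gain in tesla per (A*m)
#' @export
leadfieldEntry <- function(sensorPosition, dipolePosition, dipoleOrientation) {
  r <- as.numeric(sensorPosition); rq <- as.numeric(dipolePosition)
  th <- as.numeric(dipoleOrientation)
  rn <- sqrt(sum(r^2))
  if (rn == 0) .stopInvalidGeometry("sensor at the origin")
  dn <- sqrt(sum((r - rq)^2))
  if (dn == 0) stop("singular-geometry: sensor and dipole positions coincide", call. = FALSE)
  (MU0 / (4 * pi)) * sum(.cross3(r, rq) * th) / (rn * dn^3)
}

#' Assemble the full leadfield matrix
#'
#' Evaluates \code{\link{leadfieldEntry}} for every sensor/dipole pair of the
#' given geometries (vectorized over dipoles), with each dipole's fixed
#' orientation folded in, yielding the S x D forward operator of
#' \code{M = L Q + N}.
#'
#' @param sensors a \linkS4class{SensorArray}.
#' @param sources a \linkS4class{SourceSpace}; every dipole must lie strictly
#'   inside the sensor shell.
#' @return a \linkS4class{Leadfield}
#' @examples
#' lf <- assembleLeadfield(buildSensorHelmet(32), buildSourceGrid(0.07, 0.025))
#' dim(gain(lf))
#' @export
assembleLeadfield <- function(sensors, sources) {
  stopifnot(is(sensors, "SensorArray"), is(sources, "SourceSpace"))
  sensR <- sqrt(rowSums(sensors@positions^2))
  srcR <- sqrt(rowSums(sources@positions^2))
  if (min(sensR) <= max(srcR))
    .stopInvalidGeometry("all sensors must lie strictly outside the source volume")
  S <- nSensors(sensors); D <- nSources(sources)
  P <- sources@positions; O <- sources@orientations
  G <- matrix(0, S, D)
  for (s in seq_len(S)) {
    r <- sensors@positions[s, ]
    # (r x rq) . theta for all dipoles at once
    cx <- cbind(r[2] * P[, 3] - r[3] * P[, 2],
                r[3] * P[, 1] - r[1] * P[, 3],
                r[1] * P[, 2] - r[2] * P[, 1])
    num <- rowSums(cx * O)
    diff <- sweep(P, 2, r, "-")
    dn <- sqrt(rowSums(diff^2))
    G[s, ] <- (MU0 / (4 * pi)) * num / (sensR[s] * dn^3)
  }
  new("Leadfield", gain = G, sensors = sensors, sources = sources)
}
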