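# Shared fixtures: small geometries and independent oracles.

tinyGeometry <- function(nSensors = 24, sensorRadius = 0.12,
                         sourceRadius = 0.06, spacing = 0.03,
                         capFraction = 0.6) {
  sensors <- buildSensorHelmet(nSensors, sensorRadius, capFraction)
  grid <- buildSourceGrid(sourceRadius, spacing)
  list(sensors = sensors, grid = grid,
       lf = assembleLeadfield(sensors, grid))
}

# independent oracle: radial component of the primary (Biot-Savart) field of
# a current dipole, evaluated numerically from the vector cross product
biotSavartRadial <- function(sensorPos, dipolePos, theta) {
  mu0 <- 4 * pi * 1e-7
  d <- sensorPos - dipolePos
  B0 <- (mu0 / (4 * pi)) *
    c(theta[2] * d[3] - theta[3] * d[2],
      theta[3] * d[1] - theta[1] * d[3],
      theta[1] * d[2] - theta[2] * d[1]) / sum(d^2)^1.5
  sum(B0 * sensorPos) / sqrt(sum(sensorPos^2))
}

# random unit vector tangential to p
randomTangent <- function(p) {
  repeat {
    v <- stats::rnorm(3)
    t <- v - sum(v * p) * p / sum(p^2)
    if (sqrt(sum(t^2)) > 1e-6) return(t / sqrt(sum(t^2)))
  }
}

# breadth-first search over the 6-neighborhood lattice: is the index set
# connected?
bfsConnected <- function(indices, sourceSpace) {
  if (length(indices) <= 1L) return(TRUE)
  k <- round(sourceSpace@positions[indices, , drop = FALSE] / sourceSpace@spacing)
  key <- apply(k, 1, paste, collapse = ",")
  seen <- rep(FALSE, length(indices))
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      nb <- paste(k[cur, ] + o, collapse = ",")
      hit <- which(!seen & key == nb)
      if (length(hit)) { seen[hit] <- TRUE; queue <- c(queue, hit) }
    }
  }
  all(seen)
}

# source space from hand-picked lattice coordinates (integer triples),
# avoiding the silent origin; useful for exact-size toy leadfields
customSourceSpace <- function(coords, spacing = 0.02, radius = 0.08,
                              seed = 5L) {
  pos <- coords * spacing
  set.seed(seed)
  ori <- t(apply(pos, 1, randomTangent))
  new("SourceSpace", positions = pos, orientations = ori,
      spacing = spacing, radius = radius, originIndex = 0L)
}

# build a Scenario activating a chosen set of dipoles with given params
focalScenario <- function(indices, sourceSpace, params = NULL,
                          times = makeTimeAxis()) {
  if (is.null(params)) params <- sampleSignalParams()
  if (!is.list(params)) params <- rep(list(params), length(indices))
  new("Scenario",
      kind = if (length(indices) == 1L) "single_focal" else "multi_focal",
      groups = mapply(function(i, p) list(indices = as.integer(i), params = p),
                      indices, params, SIMPLIFY = FALSE),
      nSources = nSources(sourceSpace), times = times, fs = 1000)
}
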