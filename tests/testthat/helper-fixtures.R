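# shared fixtures and independent oracles, built in code at test time

# brute-force nearest-site rasterization of periodic Voronoi areas
raster_areas <- function(x, y, box, res = 0.01) {
  gx <- seq(res / 2, box[1] - res / 2, by = res)
  gy <- seq(res / 2, box[2] - res / 2, by = res)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  n <- length(x)
  best <- NULL
  near <- integer(length(px))
  for (i in seq_len(n)) {
    dx <- px - x[i]; dx <- dx - box[1] * round(dx / box[1])
    dy <- py - y[i]; dy <- dy - box[2] * round(dy / box[2])
    d2 <- dx^2 + dy^2
    if (is.null(best)) {
      best <- d2; near[] <- 1L
    } else {
      sel <- d2 < best
      best[sel] <- d2[sel]
      near[sel] <- i
    }
  }
  tabulate(near, n) * res^2
}

# brute-force flood fill of connected components on a neighbour list
flood_components <- function(flags, neighbors) {
  comp <- integer(length(flags))
  cur <- 0L
  for (s in which(flags)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in neighbors[[i]]) {
        if (flags[j] && comp[j] == 0) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# two-leaflet frame with uniformly random positions, one species
random_frame <- function(n, box, seed = 1, species = "sat") {
  set.seed(seed)
  mk <- function() data.frame(id = seq_len(n), species = species,
                              x = runif(n, 0, box[1]),
                              y = runif(n, 0, box[2]))
  bilayer_frame(mk(), mk(), box = box)
}

# a small GRO file with two leaflets of 4 lipids each (one bead per lipid)
write_gro_fixture <- function(path, residues = NULL) {
  res <- residues %||% c(rep("DPPC", 4), rep("DUPC", 4))
  z <- c(rep(3.0, 4), rep(1.0, 4))
  x <- rep(c(1, 3, 1, 3), 2)
  y <- rep(c(1, 1, 3, 3), 2)
  lines <- c("toy bilayer", sprintf("%5d", 8L))
  for (i in 1:8) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              i, res[i], "PO4", i, x[i], y[i], z[i]))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", 4.0, 4.0, 10.0))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
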