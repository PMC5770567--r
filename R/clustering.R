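#' Local concentration of ordered species around each site
#'
#' For every site, the fraction of ordered species among the site itself and
#' its first surrounding shell of nearest neighbours (the Voronoi/Delaunay
#' adjacency). In ternary mixtures the "ordered" species set is typically the
#' saturated lipid plus cholesterol, and the fraction is their summed share
#' of the shell.
#'
#' @param tess a [periodic_voronoi()] tessellation, or a plain list of
#'   1-based neighbour index vectors.
#' @param labels species label per site.
#' @param ordered_species character vector of labels counted as ordered.
#' @return numeric vector of local concentrations in `[0, 1]`.
#' @export
local_composition <- function(tess, labels, ordered_species) {
  if (!length(ordered_species)) stopf("ordered_species must be non-empty")
  nbrs <- if (inherits(tess, "voronoi_tess")) tess$neighbors else tess
  if (length(labels) != length(nbrs))
    stopf("labels do not align with sites")
  is_ord <- labels %in% ordered_species
  vapply(seq_along(nbrs), function(i) {
    shell <- c(i, nbrs[[i]])
    mean(is_ord[shell])
  }, numeric(1))
}

#' Flag ordered sites by comparison with the global mean concentration
#'
#' A site belongs to an ordered cluster when its local concentration of the
#' ordered species strictly exceeds their average concentration in the whole
#' leaflet. The strict inequality means a perfectly homogeneous leaflet has
#' no ordered sites.
#'
#' @param local_conc per-site local concentrations from [local_composition()].
#' @param global_mean global mean concentration of the ordered species in the
#'   leaflet, in `(0, 1)` (use the species fraction among all sites).
#' @return logical vector of ordered flags.
#' @export
assign_ordered_sites <- function(local_conc, global_mean) {
  if (global_mean <= 0 || global_mean >= 1)
    stopf("global_mean must be in (0, 1)")
  local_conc > global_mean
}

#' Detect ordered sites in one leaflet
#'
#' Convenience wrapper: local composition, global mean, strict-threshold
#' flags in one call.
#'
#' @inheritParams local_composition
#' @return logical vector of ordered flags.
#' @export
detect_ordered_sites <- function(tess, labels, ordered_species) {
  lc <- local_composition(tess, labels, ordered_species)
  f <- mean(labels %in% ordered_species)
  if (f <= 0 || f >= 1) return(rep(FALSE, length(labels)))
  assign_ordered_sites(lc, f)
}

#' Group ordered sites into clusters and measure them
#'
#' Connected components of the ordered-site subgraph of the periodic Delaunay
#' adjacency. Clusters may wrap around the box. For each cluster the area
#' (sum of member Voronoi areas), equivalent-circle radius, normalized
#' boundary length, composition and per-species mean area are reported.
#'
#' @param flags logical ordered flag per site (from
#'   [detect_ordered_sites()] or [assign_ordered_sites()]).
#' @param tess a [periodic_voronoi()] tessellation.
#' @param labels species label per site (defaults to the tessellation's).
#' @param time frame time in ns, carried through to the output.
#' @return object of class `cluster_set`: list with `clusters` (data frame:
#'   cluster, n_sites, area, radius, boundary, boundary_norm, one
#'   composition column per species), `members` (list of site index
#'   vectors), `ordered_area_fraction`, `flags`, `time`.
#' @export
group_clusters <- function(flags, tess, labels = NULL, time = NA_real_) {
  stopifnot(inherits(tess, "voronoi_tess"), length(flags) == tess$n)
  labels <- labels %||% tess$labels
  ord_idx <- which(flags)
  species <- if (!is.null(labels)) sort(unique(labels)) else character()

  members <- list()
  if (length(ord_idx)) {
    # edges of the ordered-site subgraph (periodic adjacency)
    ed <- do.call(rbind, lapply(ord_idx, function(i) {
      nb <- tess$neighbors[[i]]
      nb <- nb[flags[nb] & nb > i]
      if (!length(nb)) return(NULL)
      cbind(i, nb)
    }))
    g <- igraph::graph_from_data_frame(
      d = if (is.null(ed)) data.frame(from = integer(), to = integer())
          else data.frame(from = ed[, 1], to = ed[, 2]),
      directed = FALSE,
      vertices = data.frame(name = ord_idx))
    comp <- igraph::components(g)
    vnames <- as.integer(igraph::V(g)$name)
    members <- split(vnames, comp$membership)
  }

  rows <- lapply(seq_along(members), function(k) {
    m <- members[[k]]
    area <- sum(tess$area[m])
    b <- boundary_length(m, tess)
    row <- data.frame(cluster = k, n_sites = length(m), area = area,
                      radius = cluster_radius(area),
                      boundary = b$perimeter, boundary_norm = b$normalized)
    for (s in species) row[[paste0("C_", s)]] <- mean(labels[m] == s)
    row
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), n_sites = integer(), area = numeric(),
               radius = numeric(), boundary = numeric(),
               boundary_norm = numeric())

  structure(list(clusters = clusters, members = members,
                 ordered_area_fraction =
                   sum(tess$area[flags]) / prod(tess$box),
                 flags = flags, time = time, box = tess$box),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters, ordered area fraction %.3f\n",
              nrow(x$clusters), x$ordered_area_fraction))
  if (nrow(x$clusters)) {
    cat(sprintf("  largest: %d sites, R = %.2f nm, L = %.3f\n",
                max(x$clusters$n_sites),
                x$clusters$radius[which.max(x$clusters$n_sites)],
                x$clusters$boundary_norm[which.max(x$clusters$n_sites)]))
  }
  invisible(x)
}

#' Normalized boundary length of a cluster
#'
#' The raw perimeter is the sum of Voronoi edge lengths between member and
#' non-member sites; it is normalized by the perimeter of the circle with
#' the cluster's area, `2*sqrt(pi*A)`. A perfect disc gives 1 (isoperimetric
#' lower bound); rough, dendritic clusters give values well above 1. A
#' cluster covering the whole leaflet has zero boundary and the normalized
#' value is undefined (`NA`).
#'
#' @param members integer site indices of the cluster.
#' @param tess a [periodic_voronoi()] tessellation.
#' @return list with `perimeter` (nm) and `normalized` (dimensionless).
#' @export
boundary_length <- function(members, tess) {
  stopifnot(inherits(tess, "voronoi_tess"), length(members) >= 1)
  inset <- logical(tess$n)
  inset[members] <- TRUE
  per <- 0
  for (i in members) {
    nb <- tess$neighbors[[i]]
    # an edge to the site's own periodic image is interior when the site is
    # a member, so plain membership lookup is correct even for wrapping
    # clusters
    out <- !inset[nb]
    if (any(out)) per <- per + sum(tess$edge_lengths[[i]][out])
  }
  area <- sum(tess$area[members])
  norm <- if (per == 0) NA_real_ else per / (2 * sqrt(pi * area))
  list(perimeter = per, normalized = norm)
}

#' Equivalent-circle radius of a cluster
#'
#' `R = sqrt(A / pi)`, the radius of the disc with the cluster's area.
#'
#' @param area cluster area(s) in nm^2.
#' @return radius in nm.
#' @export
cluster_radius <- function(area) sqrt(area / pi)

#' Area-weighted mean cluster radius
#'
#' @param cluster_set a [group_clusters()] result, or a data frame with
#'   `area` and `radius` columns.
#' @return area-weighted mean radius (nm), `NA` if there are no clusters.
#' @export
mean_cluster_radius <- function(cluster_set) {
  cl <- if (inherits(cluster_set, "cluster_set")) cluster_set$clusters
        else cluster_set
  if (!nrow(cl)) return(NA_real_)
  sum(cl$area * cl$radius) / sum(cl$area)
}

#' Ordered-area fraction over a frame sequence
#'
#' Per frame: tessellate the leaflet, detect ordered sites, report the
#' ordered Voronoi area divided by the leaflet area. A plateau detector fits
#' the slope of the final-third rolling mean; a demixing run rises then
#' plateaus (slope indistinguishable from zero at the end), a mixed run
#' fluctuates with no drift.
#'
#' @param frames list of [bilayer_frame()] objects.
#' @param ordered_species labels counted as ordered.
#' @param leaflet which leaflet to analyse.
#' @return data frame `time`, `fraction`, with attributes
#'   `plateau_slope` (slope of fraction vs time in the final third),
#'   `plateau_ci` (95% confidence interval of that slope).
#' @export
area_fraction_timeseries <- function(frames, ordered_species,
                                     leaflet = "upper") {
  stopifnot(length(frames) >= 1)
  vals <- vapply(frames, function(fr) {
    tess <- periodic_voronoi(fr, leaflet = leaflet)
    flags <- detect_ordered_sites(tess, tess$labels, ordered_species)
    sum(tess$area[flags]) / prod(tess$box)
  }, numeric(1))
  times <- vapply(frames, function(fr) fr$time, numeric(1))
  out <- data.frame(time = times, fraction = vals)
  tail_n <- max(3L, ceiling(length(vals) / 3))
  idx <- seq(length(vals) - tail_n + 1, length(vals))
  if (length(idx) >= 3 && sd(vals[idx]) > 0 && sd(times[idx]) > 0) {
    fit <- lm(vals[idx] ~ times[idx])
    sl <- summary(fit)$coefficients
    attr(out, "plateau_slope") <- sl[2, 1]
    attr(out, "plateau_ci") <- sl[2, 1] + c(-1, 1) * 1.96 * sl[2, 2]
  } else {
    attr(out, "plateau_slope") <- 0
    attr(out, "plateau_ci") <- c(0, 0)
  }
  out
}

#' Write a per-frame cluster table
#'
#' @param cluster_sets list of [group_clusters()] results.
#' @param path CSV output path.
#' @return the combined data frame, invisibly.
#' @export
export_clusters <- function(cluster_sets, path) {
  tab <- do.call(rbind, lapply(cluster_sets, function(cs) {
    if (!nrow(cs$clusters)) return(NULL)
    cbind(frame_time = cs$time, cs$clusters)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
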