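#' Periodic 2D Voronoi tessellation of a leaflet
#'
#' Tessellates the in-plane positions of one leaflet on the torus defined by
#' the periodic box. Every site gets a closed finite cell; cell areas tile
#' the box exactly, and the shared Voronoi edges define the first
#' nearest-neighbour shell (the Delaunay adjacency of the periodic point
#' set). The per-site areas are the areas per lipid; shared-edge lengths feed
#' the cluster boundary measurements.
#'
#' Exactly cocircular site quadruples (e.g. a perfect square lattice) make
#' the tessellation ambiguous; a deterministic, id-derived jitter of 1e-9 nm
#' is applied before tessellating to break such ties (far below any physical
#' length scale in the data).
#'
#' @param sites data frame with columns `x`, `y` (nm) and optionally `id`, or
#'   a [bilayer_frame()] together with `leaflet`.
#' @param box periodic box `(Lx, Ly)` in nm (taken from the frame when a
#'   frame is supplied).
#' @param leaflet which leaflet to tessellate when `sites` is a frame.
#' @return object of class `voronoi_tess`: list with `area` (nm^2 per site),
#'   `neighbors` (list of 1-based site ids), `edge_lengths` (list, nm,
#'   aligned with `neighbors`), `vertices` (list of polygon vertex matrices),
#'   `labels` (species labels when available), `box`, `n`.
#' @export
periodic_voronoi <- function(sites, box = NULL, leaflet = "upper") {
  labels <- NULL
  if (inherits(sites, "bilayer_frame")) {
    box <- sites$box
    df <- sites$leaflets[[leaflet]]
    labels <- df$species
    sites <- df
  }
  stopifnot(!is.null(box), length(box) == 2)
  x <- wrap_box(sites$x, box[1])
  y <- wrap_box(sites$y, box[2])
  n <- length(x)
  if (n < 3) stopf("need at least 3 sites to tessellate")

  dup <- duplicated(cbind(round(x, 9), round(y, 9)))
  if (any(dup)) {
    ids <- if (!is.null(sites$id)) sites$id[dup] else which(dup)
    stopf("coincident sites: %s", paste(ids, collapse = ", "))
  }

  # deterministic tie-breaking jitter (1e-9 nm), hash of the site index
  h <- (seq_len(n) * 2654435761) %% 65536
  x <- wrap_box(x + (h / 65536 - 0.5) * 2e-9, box[1])
  h2 <- (seq_len(n) * 40503) %% 65536
  y <- wrap_box(y + (h2 / 65536 - 0.5) * 2e-9, box[2])

  cells <- .voronoi_cells(x, y, box[1], box[2])
  total <- sum(cells$area)
  if (abs(total - box[1] * box[2]) > 1e-6 * box[1] * box[2])
    stop("internal error: Voronoi areas do not tile the box")

  structure(list(area = cells$area, neighbors = cells$neighbors,
                 edge_lengths = cells$edge_lengths,
                 vertices = cells$vertices,
                 labels = labels, box = as.numeric(box), n = n,
                 x = x, y = y),
            class = "voronoi_tess")
}

#' @export
print.voronoi_tess <- function(x, ...) {
  cat(sprintf("<voronoi_tess> %d sites, box %.2f x %.2f nm\n",
              x$n, x$box[1], x$box[2]))
  cat(sprintf("  area per site: mean %.4f nm^2 (range %.4f-%.4f)\n",
              mean(x$area), min(x$area), max(x$area)))
  cat(sprintf("  neighbours per site: mean %.2f\n",
              mean(lengths(x$neighbors))))
  invisible(x)
}

#' Mean Voronoi area per species
#'
#' Computes, for each species, the mean and standard error of the Voronoi
#' cell area over its sites — the per-component area per lipid. A `subset`
#' restricts the average to a set of site indices (e.g. the members of one
#' cluster).
#'
#' @param tess a [periodic_voronoi()] tessellation.
#' @param labels species label per site (defaults to the labels stored in
#'   the tessellation).
#' @param subset optional integer site indices to restrict to.
#' @return data frame with columns `species`, `mean_area`, `se`, `n_sites`.
#'   A species with no sites in the subset gets `NA` (flagged absent, not
#'   zero).
#' @export
area_per_species <- function(tess, labels = NULL, subset = NULL) {
  stopifnot(inherits(tess, "voronoi_tess"))
  labels <- labels %||% tess$labels
  if (is.null(labels)) stopf("no species labels available")
  if (length(labels) != tess$n) stopf("labels do not align with sites")
  idx <- subset %||% seq_len(tess$n)
  species <- sort(unique(labels))
  out <- do.call(rbind, lapply(species, function(s) {
    i <- idx[labels[idx] == s]
    if (!length(i))
      return(data.frame(species = s, mean_area = NA_real_, se = NA_real_,
                        n_sites = 0L))
    a <- tess$area[i]
    data.frame(species = s, mean_area = mean(a),
               se = if (length(a) > 1) sd(a) / sqrt(length(a)) else NA_real_,
               n_sites = length(a))
  }))
  rownames(out) <- NULL
  out
}

#' Export a tessellation to CSV
#'
#' Writes a per-site table (id, area, n_neighbors) and an edge list
#' (i, j, edge_length) with each undirected edge listed once.
#'
#' @param tess a [periodic_voronoi()] tessellation.
#' @param sites_csv,edges_csv output paths.
#' @return invisibly, a list with the two data frames.
#' @export
export_tessellation <- function(tess, sites_csv, edges_csv) {
  stopifnot(inherits(tess, "voronoi_tess"))
  sites <- data.frame(id = seq_len(tess$n), area = tess$area,
                      n_neighbors = lengths(tess$neighbors))
  ed <- do.call(rbind, lapply(seq_len(tess$n), function(i) {
    nb <- tess$neighbors[[i]]
    keep <- nb > i
    if (!any(keep)) return(NULL)
    data.frame(i = i, j = nb[keep], edge_length = tess$edge_lengths[[i]][keep])
  }))
  write.csv(sites, sites_csv, row.names = FALSE)
  write.csv(ed, edges_csv, row.names = FALSE)
  invisible(list(sites = sites, edges = ed))
}
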