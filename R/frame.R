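#' Construct a bilayer frame
#'
#' A `bilayer_frame` holds one time point of a two-leaflet bilayer: per-lipid
#' reference sites with species labels for each leaflet, the periodic in-plane
#' box, and optionally per-lipid hydrocarbon chain sites and a height
#' coordinate per site.
#'
#' @param upper,lower data frames with columns `id`, `species`, `x`, `y` and
#'   optionally `z` (all lengths in nm). Coordinates are wrapped into the box.
#' @param box numeric length-2, the periodic in-plane box `(Lx, Ly)` in nm.
#' @param time frame time in ns.
#' @param chains optional list with elements `upper` and `lower`; each is a
#'   list (one entry per lipid, in row order of the leaflet data frame) of
#'   chains, each chain an `n x 3` matrix of ordered chain-site coordinates
#'   in nm. Chains need at least 3 sites to contribute to the orientational
#'   order parameter.
#' @return an object of class `bilayer_frame`.
#' @export
bilayer_frame <- function(upper, lower, box, time = 0, chains = NULL) {
  stopifnot(is.numeric(box), length(box) == 2, all(box > 0))
  fix <- function(df, leaflet) {
    df <- as.data.frame(df)
    need <- c("id", "species", "x", "y")
    if (!all(need %in% names(df)))
      stopf("leaflet '%s' must have columns id, species, x, y", leaflet)
    df$x <- wrap_box(df$x, box[1])
    df$y <- wrap_box(df$y, box[2])
    df$species <- as.character(df$species)
    df
  }
  out <- structure(
    list(leaflets = list(upper = fix(upper, "upper"),
                         lower = fix(lower, "lower")),
         box = as.numeric(box), time = as.numeric(time), chains = chains),
    class = "bilayer_frame")
  out
}

#' @export
print.bilayer_frame <- function(x, ...) {
  cat(sprintf("<bilayer_frame> t = %g ns, box %.2f x %.2f nm\n",
              x$time, x$box[1], x$box[2]))
  for (lf in c("upper", "lower")) {
    df <- x$leaflets[[lf]]
    tab <- table(df$species)
    cat(sprintf("  %s: %d sites (%s)\n", lf, nrow(df),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' Write bilayer frames to a flat CSV + JSON bundle
#'
#' Each frame is stored as one CSV per leaflet (columns id, species, x, y, z)
#' plus a JSON sidecar carrying the box, frame times and any generator
#' metadata. The layout round-trips through [read_frames()].
#'
#' @param frames a `bilayer_frame` or list of them.
#' @param dir output directory (created if missing).
#' @param meta optional named list stored verbatim in the sidecar.
#' @return the directory, invisibly.
#' @export
write_frames <- function(frames, dir, meta = list()) {
  if (inherits(frames, "bilayer_frame")) frames <- list(frames)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  times <- vapply(frames, function(f) f$time, numeric(1))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    for (lf in c("upper", "lower")) {
      df <- fr$leaflets[[lf]]
      if (is.null(df$z)) df$z <- NA_real_
      write.csv(df[, c("id", "species", "x", "y", "z")],
                file.path(dir, sprintf("frame%05d_%s.csv", i, lf)),
                row.names = FALSE)
    }
  }
  side <- list(n_frames = length(frames), times = times,
               box = frames[[1]]$box, meta = meta)
  jsonlite::write_json(side, file.path(dir, "frames.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame bundle written by [write_frames()]
#'
#' @param dir directory containing `frames.json` and the per-leaflet CSVs.
#' @return list of `bilayer_frame` objects.
#' @export
read_frames <- function(dir) {
  sidef <- file.path(dir, "frames.json")
  if (!file.exists(sidef)) stopf("no frames.json in '%s'", dir)
  side <- jsonlite::read_json(sidef, simplifyVector = TRUE)
  lapply(seq_len(side$n_frames), function(i) {
    up <- read.csv(file.path(dir, sprintf("frame%05d_upper.csv", i)),
                   stringsAsFactors = FALSE)
    lo <- read.csv(file.path(dir, sprintf("frame%05d_lower.csv", i)),
                   stringsAsFactors = FALSE)
    bilayer_frame(up, lo, box = side$box, time = side$times[i])
  })
}

#' Read bilayer frames from coordinate files
#'
#' Adapts GRO or PDB coordinate files (one frame per file) to
#' [bilayer_frame()] objects. Each lipid is reduced to one reference site via
#' `topology_map`, which assigns a species label and a reference atom name to
#' every residue name. Leaflets are assigned by the sign of the reference-site
#' z relative to the per-frame median, unless `leaflet` overrides it.
#'
#' @param paths character vector of GRO/PDB files, one frame each.
#' @param topology_map data frame with columns `resname`, `species`,
#'   `ref_atom`; optionally `chain_atoms` (comma-separated ordered atom names
#'   forming the hydrocarbon chains, `|` between chains).
#' @param times frame times in ns (default `seq_along(paths) - 1`).
#' @return list of `bilayer_frame` objects.
#' @export
read_trajectory <- function(paths, topology_map,
                            times = seq_along(paths) - 1) {
  stopifnot(all(file.exists(paths)))
  tm <- as.data.frame(topology_map)
  if (!all(c("resname", "species", "ref_atom") %in% names(tm)))
    stopf("topology_map needs columns resname, species, ref_atom")
  lapply(seq_along(paths), function(i) {
    at <- read_coords(paths[i])
    unknown <- setdiff(unique(at$resname), tm$resname)
    if (length(unknown))
      stopf("unmapped residue names: %s", paste(unknown, collapse = ", "))
    m <- match(at$resname, tm$resname)
    ref <- at[at$atom == tm$ref_atom[m], , drop = FALSE]
    if (!nrow(ref)) stopf("no reference atoms found in '%s'", paths[i])
    zmed <- stats::median(ref$z)
    upper_sel <- ref$z >= zmed
    mk <- function(sel) {
      r <- ref[sel, , drop = FALSE]
      data.frame(id = r$resid,
                 species = tm$species[match(r$resname, tm$resname)],
                 x = r$x, y = r$y, z = r$z, stringsAsFactors = FALSE)
    }
    chains <- NULL
    if ("chain_atoms" %in% names(tm)) {
      chains <- list(
        upper = extract_chains(at, ref$resid[upper_sel], tm),
        lower = extract_chains(at, ref$resid[!upper_sel], tm))
    }
    fr <- bilayer_frame(mk(upper_sel), mk(!upper_sel),
                        box = at_box(at), time = times[i], chains = chains)
    fr
  })
}

# parse one GRO or PDB file into data.frame(resid, resname, atom, x, y, z)
# with a "box" attribute (nm)
read_coords <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\\.gro$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    n <- as.integer(trimws(ln[2]))
    body <- ln[3:(2 + n)]
    out <- data.frame(
      resid = as.integer(substr(body, 1, 5)),
      resname = trimws(substr(body, 6, 10)),
      atom = trimws(substr(body, 11, 15)),
      x = as.numeric(substr(body, 21, 28)),
      y = as.numeric(substr(body, 29, 36)),
      z = as.numeric(substr(body, 37, 44)),
      stringsAsFactors = FALSE)
    boxv <- as.numeric(strsplit(trimws(ln[3 + n]), "\\s+")[[1]])
    attr(out, "box") <- boxv[1:2]
    out
  } else if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    cry <- ln[startsWith(ln, "CRYST1")]
    at <- ln[startsWith(ln, "ATOM") | startsWith(ln, "HETATM")]
    out <- data.frame(
      resid = as.integer(substr(at, 23, 26)),
      resname = trimws(substr(at, 18, 21)),
      atom = trimws(substr(at, 13, 16)),
      x = as.numeric(substr(at, 31, 38)) / 10, # Angstrom -> nm
      y = as.numeric(substr(at, 39, 46)) / 10,
      z = as.numeric(substr(at, 47, 54)) / 10,
      stringsAsFactors = FALSE)
    if (length(cry)) {
      b <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24))) / 10
      attr(out, "box") <- b
    } else stopf("PDB file '%s' lacks a CRYST1 record (box unknown)", path)
    out
  } else stopf("unsupported coordinate format: '%s' (use .gro or .pdb)",
               basename(path))
}

at_box <- function(at) attr(at, "box")

extract_chains <- function(at, resids, tm) {
  lapply(resids, function(rid) {
    rows <- at[at$resid == rid, , drop = FALSE]
    spec <- tm[match(rows$resname[1], tm$resname), ]
    if (is.na(spec$chain_atoms) || !nzchar(spec$chain_atoms)) return(list())
    lapply(strsplit(spec$chain_atoms, "\\|")[[1]], function(ch) {
      atoms <- trimws(strsplit(ch, ",")[[1]])
      m <- match(atoms, rows$atom)
      as.matrix(rows[m[!is.na(m)], c("x", "y", "z")])
    })
  })
}
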