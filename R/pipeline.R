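#' Classifier configuration
#'
#' Thresholds combining the structural and dynamic evidence into a phase
#' verdict. The defaults make explicit the qualitative combination used for
#' bilayer phase calls: long-range (linear) density decay together with
#' substantial interleaflet overlap (> 0.7 is the signature of strong
#' interleaflet correlation) and persistent density maps indicates two
#' coexisting phases; short-range (exponential) decay with a correlation
#' length several times the inter-lipid spacing indicates near-critical
#' fluctuations in a single phase.
#'
#' @param overlap_threshold minimum interleaflet overlap for a two-phase
#'   call (default 0.7).
#' @param persistence_threshold minimum persistence score (density-map
#'   contrast ratio, longest vs shortest window) for a two-phase call
#'   (default 0.8).
#' @param xi_multiple multiple of the mean inter-lipid spacing that `xi`
#'   must exceed for a near-critical call (default 3).
#' @param exp_fit_range range in nm for the correlation-length fit (`NULL`:
#'   the [fit_correlation_length()] default).
#' @param linear_fit_range lower bound in nm where the decay-shape
#'   comparison starts (default 0.8, past the first-neighbour bin); the
#'   comparison runs to the profile's running minimum.
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(overlap_threshold = 0.7,
                              persistence_threshold = 0.8,
                              xi_multiple = 3,
                              exp_fit_range = NULL,
                              linear_fit_range = NULL) {
  structure(list(overlap_threshold = overlap_threshold,
                 persistence_threshold = persistence_threshold,
                 xi_multiple = xi_multiple,
                 exp_fit_range = exp_fit_range,
                 linear_fit_range = linear_fit_range),
            class = "classifier_config")
}

#' Classify the bilayer phase state
#'
#' Compares linear and exponential decay models of the radial distribution
#' function by small-sample-corrected AIC on the monotone decay segment
#' (the exponential is pinned to the profile's tail level, so both models
#' have equal complexity: a one-phase profile relaxes exponentially to the
#' uncorrelated level, while a phase-separated profile crosses below it on
#' the way to the inter-domain undulation, which only the line can follow).
#' The preferred decay is then combined with the interleaflet overlap, the
#' persistence score and the fitted correlation length: `two_phase` requires
#' linear decay preferred AND overlap above threshold AND persistence above
#' threshold; `near_critical` requires exponential decay preferred with `xi`
#' exceeding a multiple of the mean inter-lipid spacing; everything else is
#' `one_phase`.
#'
#' @param rdf_profile a `radial_profile` from [rdf2d()].
#' @param overlap interleaflet overlap in `[0, 1]` (from
#'   [interleaflet_overlap()]).
#' @param persistence persistence score (density-map contrast ratio between
#'   the longest and shortest windows), or `NA` when unavailable.
#' @param xi_fit a [fit_correlation_length()] result (computed from the
#'   profile when `NULL`).
#' @param mean_spacing mean inter-lipid spacing in nm,
#'   `sqrt(box_area / n)`; taken from the profile attributes when `NULL`.
#' @param config a [classifier_config()].
#' @return object of class `phase_verdict`: list with `label` (one of
#'   `"one_phase"`, `"two_phase"`, `"near_critical"`, or `NA` when evidence
#'   is missing), and `evidence` (all statistics that entered the call).
#' @export
classify_phase_state <- function(rdf_profile, overlap, persistence = NA,
                                 xi_fit = NULL, mean_spacing = NULL,
                                 config = classifier_config()) {
  stopifnot(inherits(rdf_profile, "radial_profile"))
  if (is.null(xi_fit))
    xi_fit <- fit_correlation_length(rdf_profile, config$exp_fit_range)
  if (is.null(mean_spacing)) {
    box <- attr(rdf_profile, "box")
    n <- attr(rdf_profile, "n_sites")[1]
    mean_spacing <- sqrt(box[1] * box[2] / n)
  }
  dec <- compare_decay_models(rdf_profile,
                              r_min = (config$linear_fit_range %||% 0.8)[1])
  linear_preferred <- dec$decided && dec$linear_preferred

  evidence <- list(aicc_linear = dec$aicc_linear,
                   aicc_exponential = dec$aicc_exponential,
                   linear_preferred = linear_preferred,
                   decay_segment = dec$segment,
                   tail_level = dec$tail_level,
                   overlap = overlap, persistence = persistence,
                   xi = xi_fit$xi, xi_refused = xi_fit$refused,
                   mean_spacing = mean_spacing, config = config)

  if (is.null(overlap) || is.na(overlap)) {
    return(structure(list(label = NA_character_, evidence = evidence,
                          reason = "overlap evidence missing"),
                     class = "phase_verdict"))
  }
  label <- if (linear_preferred &&
               overlap > config$overlap_threshold &&
               (is.na(persistence) ||
                persistence >= config$persistence_threshold)) {
    if (is.na(persistence)) {
      return(structure(list(label = NA_character_, evidence = evidence,
                            reason = "persistence evidence missing"),
                       class = "phase_verdict"))
    }
    "two_phase"
  } else if (!linear_preferred && !xi_fit$refused &&
             is.finite(xi_fit$xi) &&
             xi_fit$xi > config$xi_multiple * mean_spacing) {
    "near_critical"
  } else "one_phase"
  structure(list(label = label, evidence = evidence, reason = NULL),
            class = "phase_verdict")
}

#' @export
print.phase_verdict <- function(x, ...) {
  if (is.na(x$label)) {
    cat(sprintf("<phase_verdict> withheld: %s\n", x$reason))
  } else {
    e <- x$evidence
    cat(sprintf("<phase_verdict> %s\n", x$label))
    cat(sprintf("  decay: %s preferred (AICc lin %.1f vs exp %.1f)\n",
                if (e$linear_preferred) "linear" else "exponential",
                e$aicc_linear, e$aicc_exponential))
    cat(sprintf("  overlap %.3f, persistence %s, xi %s nm (spacing %.2f)\n",
                e$overlap, format(e$persistence, digits = 3),
                format(e$xi, digits = 3), e$mean_spacing))
  }
  invisible(x)
}

#' Run the full lateral-heterogeneity analysis
#'
#' Orchestrates tessellation, ordered-cluster detection, interleaflet
#' registration, radial distribution function and correlation-length fit,
#' windowed density maps, chain order (when chains are present) and the
#' phase-state classifier over a trajectory, aggregating over the analysis
#' window (by default the final 10% of frames, mirroring the convention of
#' analysing the equilibrated tail of a trajectory).
#'
#' @param config either a named list or a path to a YAML file. Recognised
#'   fields: `synthetic` (arguments for [lattice_gas_params()] plus
#'   `n_frames`), or `frames_dir` (a [write_frames()] bundle);
#'   `ordered_species` (default: every species except `"unsat"`);
#'   `rdf_species` (default `"unsat"`); `rdf_normalize` (default
#'   `"all_sites"`, which cancels lattice packing structure; see [rdf2d()]);
#'   `window_fraction` (default 0.1);
#'   `cell_size` (default 0.5 nm); `bin_width` (default 0.1 nm);
#'   `classifier` (arguments for [classifier_config()]); `out` (optional
#'   output directory); `seed` (overrides the synthetic seed).
#' @return object of class `bilayer_analysis`: list with `summary` (one-row
#'   data frame with A_L, A_L_ordered, A_L_disord, per-species A_i and C_i,
#'   S_z when available, overlap, xi, phase), `verdict`, `clusters`,
#'   `overlap_series`, `rdf`, `xi_fit`, `persistence`, `frames_analyzed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))

  frames <- if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    nfr <- syn$n_frames %||% 10
    syn$n_frames <- NULL
    if (!is.null(config$seed)) syn$seed <- config$seed
    pars <- do.call(lattice_gas_params, syn)
    fr <- generate_lattice_gas(pars, n_frames = nfr)
    if (inherits(fr, "bilayer_frame")) list(fr) else fr
  } else if (!is.null(config$frames_dir)) {
    read_frames(config$frames_dir)
  } else stopf("config must name an input: synthetic or frames_dir")
  if (!length(frames)) stopf("empty trajectory")

  all_species <- sort(unique(frames[[1]]$leaflets$upper$species))
  ordered_species <- config$ordered_species %||% setdiff(all_species, "unsat")
  rdf_species <- config$rdf_species %||%
    (if ("unsat" %in% all_species) "unsat" else all_species[1])
  wfrac <- config$window_fraction %||% 0.1
  n_an <- max(1L, ceiling(length(frames) * wfrac))
  an_frames <- tail(frames, n_an)

  cl_cfg <- do.call(classifier_config, config$classifier %||% list())

  per_frame <- lapply(an_frames, function(fr) {
    tu <- periodic_voronoi(fr, leaflet = "upper")
    tl <- periodic_voronoi(fr, leaflet = "lower")
    fu <- detect_ordered_sites(tu, tu$labels, ordered_species)
    fl <- detect_ordered_sites(tl, tl$labels, ordered_species)
    cs <- group_clusters(fu, tu, time = fr$time)
    ov <- interleaflet_overlap(
      rasterize_states(fu, fl, tu, tl, config$cell_size %||% 0.5))
    list(frame = fr, tess = tu, flags = fu, clusters = cs, overlap = ov)
  })

  last <- per_frame[[length(per_frame)]]
  rdf <- rdf2d(an_frames, species = rdf_species,
               bin_width = config$bin_width %||% 0.1,
               normalize = config$rdf_normalize %||% "all_sites")
  xi_fit <- fit_correlation_length(rdf, cl_cfg$exp_fit_range)

  # persistence: density-map contrast retained from the shortest to the
  # longest window over the full trajectory
  persistence <- NA_real_
  times <- vapply(frames, function(f) f$time, numeric(1))
  span <- max(times) - min(times)
  if (length(frames) >= 4 && span > 0) {
    short <- density_map(frames, species = rdf_species,
                         window_ns = span / 4)
    long <- density_map(frames, species = rdf_species, window_ns = span)
    c_short <- mean(vapply(short, map_contrast, numeric(1)))
    c_long <- map_contrast(long[[1]])
    persistence <- (c_long - 1) / max(c_short - 1, 1e-9)
  }

  mean_overlap <- mean(vapply(per_frame, function(p) p$overlap$overlap,
                              numeric(1)))
  verdict <- classify_phase_state(rdf, mean_overlap, persistence, xi_fit,
                                  config = cl_cfg)

  # Table-style per-frame aggregation on the final frame's tessellation
  tess <- last$tess
  flags <- last$flags
  A_L <- mean(tess$area)
  A_L_ord <- if (any(flags)) mean(tess$area[flags]) else NA_real_
  A_L_dis <- if (any(!flags)) mean(tess$area[!flags]) else NA_real_
  aps <- area_per_species(tess, subset = which(flags))
  ord_labels <- tess$labels[flags]
  summary <- data.frame(A_L = A_L, A_L_ordered = A_L_ord,
                        A_L_disord = A_L_dis)
  for (s in all_species) {
    summary[[paste0("A_", s)]] <- aps$mean_area[aps$species == s]
    summary[[paste0("C_", s)]] <-
      if (length(ord_labels)) mean(ord_labels == s) else NA_real_
  }
  sz <- NA_real_
  if (!is.null(last$frame$chains)) {
    ores <- tryCatch(chain_order(last$frame), error = function(e) NULL)
    if (!is.null(ores)) sz <- ores$mean
  }
  summary$S_z <- sz
  summary$overlap <- mean_overlap
  summary$xi <- xi_fit$xi
  summary$phase <- verdict$label

  out <- structure(list(summary = summary, verdict = verdict,
                        clusters = lapply(per_frame, `[[`, "clusters"),
                        overlap_series = do.call(rbind, lapply(per_frame,
                          function(p) data.frame(frame_time = p$frame$time,
                                                 overlap = p$overlap$overlap,
                                                 overlap_clusters =
                                                   p$overlap$overlap_clusters,
                                                 f_upper = p$overlap$f_upper,
                                                 f_lower = p$overlap$f_lower))),
                        rdf = rdf, xi_fit = xi_fit,
                        persistence = persistence,
                        frames_analyzed = length(an_frames),
                        ordered_species = ordered_species),
                   class = "bilayer_analysis")

  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$overlap_series,
              file.path(config$out, "overlap_timeseries.csv"),
              row.names = FALSE)
    export_clusters(out$clusters, file.path(config$out, "clusters.csv"))
    write.csv(as.data.frame(rdf), file.path(config$out, "rdf.csv"),
              row.names = FALSE)
    jsonlite::write_json(c(as.list(summary),
                           list(persistence = persistence,
                                frames_analyzed = length(an_frames))),
                         file.path(config$out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}

#' @export
print.bilayer_analysis <- function(x, ...) {
  cat(sprintf("<bilayer_analysis> %d frame(s) analysed, phase: %s\n",
              x$frames_analyzed,
              if (is.na(x$verdict$label)) "withheld" else x$verdict$label))
  s <- x$summary
  cat(sprintf("  A_L %.3f nm^2 (ordered %.3f / disordered %.3f)\n",
              s$A_L, s$A_L_ordered, s$A_L_disord))
  cat(sprintf("  overlap %.3f, xi %s nm, persistence %s\n", s$overlap,
              format(s$xi, digits = 3), format(x$persistence, digits = 3)))
  invisible(x)
}

#' @export
summary.bilayer_analysis <- function(object, ...) {
  print(object)
  cat("\nPer-cluster statistics (last analysed frame):\n")
  print(object$clusters[[length(object$clusters)]]$clusters)
  invisible(object$summary)
}
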