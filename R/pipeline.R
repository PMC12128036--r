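#' Willard-Chandler surface of one aggregate
#'
#' Builds the Gaussian density of all the aggregate's surfactant beads in a
#' padded local box (the unwrapped aggregate is re-centered so no periodic
#' seam cuts it), extracts the isosurface and measures it.
#'
#' @param aggregate A non-percolating, unwrapped `"cg_aggregate"`.
#' @param params A [wc_params()].
#' @param mode Density mode, see [gaussian_density_grid()].
#' @return List: `mesh`, `area`, `volume` (material), `outer_volume`,
#'   `n_components`.
#' @export
aggregate_surface <- function(aggregate, params = wc_params(),
                              mode = "supercell") {
  if (isTRUE(aggregate$percolating)) {
    stop("percolation error: per-aggregate surfaces need a non-percolating aggregate",
         call. = FALSE)
  }
  pts <- aggregate$coords
  pad <- params$truncation * params$bandwidth + 2 * params$spacing
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  local_box <- cg_box(pmax(hi - lo, 4 * params$spacing))
  field <- gaussian_density_grid(sweep(pts, 2, lo), local_box, params, mode = mode)
  mesh <- willard_chandler_surface(field, params)
  av <- mesh_area_volume(mesh)
  list(mesh = mesh, area = av$area, volume = av$volume,
       outer_volume = av$outer_volume, n_components = mesh$n_components)
}

#' Isotropic-phase analysis pipeline
#'
#' Per frame: single-linkage clustering of tail beads, unwrapping and
#' percolation flagging; for every qualifying aggregate (aggregation number
#' at or above the reporting threshold, non-percolating) the shape
#' descriptors and Willard-Chandler surface metrics; then reduction to
#' per-property system timeseries and, when enough frames are present,
#' MSER/ADF equilibration analysis.
#'
#' @param trajectory A [cg_trajectory()].
#' @param params A [cluster_params()] (reporting threshold included).
#' @param wc A [wc_params()].
#' @param compute_surfaces Set `FALSE` to skip the (costlier) surface stage.
#' @param confidence ADF confidence for the convergence report.
#' @return List: `aggregates` (per-frame cluster table), `properties`
#'   (per-aggregate property table), `timeseries` (list of
#'   [property_timeseries()]), `convergence` (a [convergence_report()] or
#'   NULL when fewer than 4 time points), `warnings` (named counters:
#'   percolating aggregates skipped, degenerate surfaces).
#' @export
run_isotropic_pipeline <- function(trajectory, params = cluster_params(),
                                   wc = wc_params(), compute_surfaces = TRUE,
                                   confidence = 0.99, output_dir = NULL) {
  if (!inherits(trajectory, "cg_trajectory") || !length(trajectory$frames)) {
    stop("empty-input error: need a trajectory with at least one frame", call. = FALSE)
  }
  agg_rows <- list()
  prop_rows <- list()
  counters <- c(percolating = 0L, degenerate_surface = 0L)
  for (fi in seq_along(trajectory$frames)) {
    frame <- trajectory$frames[[fi]]
    aggs <- find_aggregates(frame, params)
    agg_rows[[fi]] <- aggregate_table(aggs, frame)
    qual <- Filter(function(a) a$n >= params$min_aggregation_number, aggs)
    rows <- lapply(seq_along(qual), function(ai) {
      a <- qual[[ai]]
      if (a$percolating) {
        counters["percolating"] <<- counters["percolating"] + 1L
        return(NULL)
      }
      sd_ <- shape_descriptors(a)
      row <- data.frame(
        time = a$time, aggregate_id = ai, n = a$n,
        aggregation_number = as.numeric(a$n),
        normalized_n = normalized_aggregation_number(a, frame),
        r_g = sd_$r_g, a = sd_$semiaxes[1], b = sd_$semiaxes[2],
        c = sd_$semiaxes[3], e_ab = sd_$e_ab, e_ac = sd_$e_ac,
        class = if (is.null(sd_$class)) NA_character_ else sd_$class,
        area = NA_real_, volume = NA_real_, area_per_surfactant = NA_real_,
        volume_per_surfactant = NA_real_, sa_to_volume = NA_real_,
        stringsAsFactors = FALSE
      )
      if (compute_surfaces) {
        surf <- tryCatch(aggregate_surface(a, wc), error = function(e) NULL)
        if (is.null(surf) || !is.finite(surf$volume) || surf$volume <= 0) {
          counters["degenerate_surface"] <<- counters["degenerate_surface"] + 1L
        } else {
          pm <- per_surfactant_metrics(surf$area, surf$volume, a$n)
          row$area <- surf$area
          row$volume <- surf$volume
          row$area_per_surfactant <- pm$area_per_surfactant
          row$volume_per_surfactant <- pm$volume_per_surfactant
          row$sa_to_volume <- pm$sa_to_volume
        }
      }
      row
    })
    prop_rows[[fi]] <- do.call(rbind, rows)
  }
  properties <- do.call(rbind, prop_rows)
  out <- list(aggregates = do.call(rbind, agg_rows), properties = properties,
              timeseries = NULL, convergence = NULL, warnings = counters)
  if (!is.null(properties) && nrow(properties)) {
    props <- c("sa_to_volume", "area_per_surfactant", "volume_per_surfactant",
               "r_g", "aggregation_number")
    props <- props[vapply(props, function(p) any(is.finite(properties[[p]])),
                          logical(1))]
    ts <- suppressMessages(reduce_aggregate_properties(
      properties, properties = props, min_n = params$min_aggregation_number))
    out$timeseries <- ts
    if (all(vapply(ts, function(s) length(s$values), integer(1)) >= 4)) {
      out$convergence <- convergence_report(ts, confidence = confidence)
    }
  }
  if (!is.null(output_dir)) .write_pipeline_outputs(out, params, wc, output_dir)
  out
}

# machine-readable run outputs: resolved parameters plus CSV/JSON tables
.write_pipeline_outputs <- function(out, params, wc, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(cluster_params = unclass(params), wc_params = unclass(wc),
         warnings = as.list(out$warnings)),
    file.path(output_dir, "config.json"), auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(out$aggregates, file.path(output_dir, "aggregates.csv"),
                   row.names = FALSE)
  if (!is.null(out$properties)) {
    utils::write.csv(out$properties, file.path(output_dir, "properties.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$convergence)) {
    utils::write.csv(out$convergence$table,
                     file.path(output_dir, "convergence.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(as.list(out$convergence$table),
        list(final_convergence_time = out$convergence$final_convergence_time)),
      file.path(output_dir, "convergence.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(output_dir)
}

#' Bilayer analysis pipeline
#'
#' For every frame after `t_min`: the Willard-Chandler surface of all
#' surfactant beads over the full periodic box, leaflet identification by
#' mesh connectivity, the vertex-wise nearest-neighbor thickness
#' distribution, and the area per headgroup. Frames whose surface does not
#' split into two leaflets are skipped and counted.
#'
#' @param trajectory A [cg_trajectory()] of lamellar frames.
#' @param wc A [wc_params()].
#' @param t_min Only frames with `time > t_min` (ns) are analyzed.
#' @return List: `per_frame` (data.frame: time, mean_thickness,
#'   area_per_headgroup, n_extra_components), `thickness` (pooled distance
#'   distribution, Angstrom), `mean_thickness`, `sd_thickness`,
#'   `mean_area_per_headgroup`, `n_skipped`.
#' @export
run_bilayer_pipeline <- function(trajectory, wc = wc_params(), t_min = 30,
                                 output_dir = NULL) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  sel <- which(trajectory$times > t_min)
  if (!length(sel)) {
    stop("empty-selection error: no frames after t_min = ", t_min, " ns", call. = FALSE)
  }
  rows <- list()
  pooled <- list()
  n_skipped <- 0L
  for (fi in sel) {
    frame <- trajectory$frames[[fi]]
    surf_mols <- surfactant_molecules(frame)
    beads <- which(frame$mol_id %in% surf_mols)
    res <- tryCatch({
      field <- gaussian_density_grid(frame$coords[beads, , drop = FALSE],
                                     frame$box, wc, mode = "supercell")
      mesh <- willard_chandler_surface(field, wc)
      leaf <- withCallingHandlers(
        split_bilayer_leaflets(mesh),
        warning = function(w) invokeRestart("muffleWarning"))
      th <- bilayer_thickness(leaf$upper, leaf$lower)
      aph <- area_per_headgroup(leaf$upper, leaf$lower, length(surf_mols))
      list(th = th, aph = aph, extra = leaf$n_extra_components)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      time = frame$time, mean_thickness = res$th$mean,
      area_per_headgroup = res$aph, n_extra_components = res$extra)
    pooled[[length(pooled) + 1L]] <- res$th$distances
  }
  if (!length(rows)) {
    stop("no analyzable bilayer frame after t_min (", n_skipped, " skipped)",
         call. = FALSE)
  }
  per_frame <- do.call(rbind, rows)
  thickness <- unlist(pooled)
  out <- list(per_frame = per_frame, thickness = thickness,
              mean_thickness = mean(thickness), sd_thickness = stats::sd(thickness),
              mean_area_per_headgroup = mean(per_frame$area_per_headgroup),
              n_skipped = n_skipped)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(wc_params = unclass(wc), t_min = t_min, n_skipped = n_skipped,
           mean_thickness = out$mean_thickness,
           mean_area_per_headgroup = out$mean_area_per_headgroup,
           thickness_percentiles = as.list(stats::quantile(
             thickness, c(0.05, 0.25, 0.5, 0.75, 0.95)))),
      file.path(output_dir, "bilayer_report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(per_frame, file.path(output_dir, "bilayer_per_frame.csv"),
                     row.names = FALSE)
  }
  out
}

#' Convert a molar concentration to weight percent
#'
#' `100 * m_solute / (m_solute + rho_solvent)` with
#' `m_solute = c_mM * molar_mass / 1e6` kg per litre of solvent; e.g. 7.5 mM
#' of a 444.6 g/mol surfactant is ~0.33 wt %.
#'
#' @param c_mM Concentration in mmol/L.
#' @param molar_mass Solute molar mass, g/mol (default 444.6, the real molar
#'   mass of AOT).
#' @param solvent_density Solvent density, g/mL (default 1.0, water).
#' @return Weight percent.
#' @export
#' @examples
#' wtpercent_from_millimolar(7.5)  # ~0.33
wtpercent_from_millimolar <- function(c_mM, molar_mass = 444.6,
                                      solvent_density = 1.0) {
  if (any(c_mM < 0) || molar_mass <= 0 || solvent_density <= 0) {
    stop("concentration must be >= 0 and molar mass / density positive", call. = FALSE)
  }
  solute <- c_mM * molar_mass / 1e6  # kg per litre of solvent
  100 * solute / (solute + solvent_density)
}
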