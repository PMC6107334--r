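#' Configuration of a full analysis run
#'
#' A run either simulates its input (`simulation = simulation_config(...)`)
#' or reads it (`tracks_path` / `scene_path`). Stages execute in dependency
#' order: drift correction before track metrics, metrics before circular
#' tests. Every statistical test in the report carries a method note and the
#' seed that produced it; per-stage seeds are derived from the single global
#' seed so inserting a stage never perturbs another stage's random stream.
#'
#' @param simulation optional [simulation_config()].
#' @param tracks_path,scene_path optional input files (native track CSV,
#'   scene JSON).
#' @param analyses stages to run.
#' @param dc_radius condensate radius used for density/fraction regions, um.
#' @param entry_radius condensate entry radius for truncation, um.
#' @param distance_threshold far/near grouping threshold, um.
#' @param truncate_at_entry truncate dc tracks at condensate entry.
#' @param n_permutations Watson U2 permutations.
#' @param n_mc Monte-Carlo draws for the sphere-uniformity null.
#' @param alpha_flag significance level used for the report's signature
#'   flags (default 0.01).
#' @param bias_median_threshold directional bias is only flagged when the
#'   group's median escape angle falls below this value (degrees, default
#'   45): inward migration concentrates angles well below the 90-degree
#'   isotropic median, whereas mere statistical non-uniformity (e.g. weak
#'   boundary effects in crowded tissue) does not.
#' @param out_dir optional output directory (CSV tables + JSON summary +
#'   text report).
#' @param seed global seed.
#' @return a `run_config`.
#' @export
run_config <- function(simulation = NULL, tracks_path = NULL, scene_path = NULL,
                       analyses = c("directionality", "density", "neighbors",
                                    "fractions"),
                       dc_radius = NULL, entry_radius = 15,
                       distance_threshold = 30, truncate_at_entry = FALSE,
                       n_permutations = 999, n_mc = 2000, alpha_flag = 0.01,
                       bias_median_threshold = 45, out_dir = NULL, seed = 1L) {
  if (is.null(simulation) && is.null(tracks_path) && is.null(scene_path)) {
    stopf("run_config needs a simulation or at least one input path")
  }
  for (p in c(tracks_path, scene_path)) {
    if (!is.null(p) && !file.exists(p)) stopf("input file '%s' does not exist", p)
  }
  known <- c("directionality", "density", "neighbors", "fractions")
  bad <- setdiff(analyses, known)
  if (length(bad)) stopf("unknown analysis stage(s): %s", paste(bad, collapse = ", "))
  structure(list(simulation = simulation, tracks_path = tracks_path,
                 scene_path = scene_path, analyses = analyses,
                 dc_radius = dc_radius, entry_radius = entry_radius,
                 distance_threshold = distance_threshold,
                 truncate_at_entry = truncate_at_entry,
                 n_permutations = n_permutations, n_mc = n_mc,
                 alpha_flag = alpha_flag,
                 bias_median_threshold = bias_median_threshold,
                 out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Field names mirror [run_config()]; a `simulation:` block mirrors
#' [simulation_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    sim <- do.call(simulation_config, y$simulation)
  }
  args <- y[setdiff(names(y), "simulation")]
  do.call(run_config, c(list(simulation = sim), args))
}

test_to_list <- function(t) {
  list(statistic_name = t$statistic_name, statistic = t$statistic,
       p_value = t$p_value, n = t$n, m = if (is.na(t$m)) NULL else t$m,
       method_note = t$method_note)
}

#' Execute a full analysis run
#'
#' Runs the requested stages and returns (and optionally writes) a report
#' bundle: per-stage tables, every statistical test with its provenance
#' note, and three signature flags summarising the condensation mechanism
#' the data support at `alpha_flag`:
#' `directional_bias_dc_far` (net inward motion of initially-distant
#' condensate candidates, one-sided sphere-uniformity test),
#' `directional_bias_interfollicular` (the same test on control cells, which
#' should stay quiet), and `proliferation_signal` (S/G2/M fraction among
#' condensate cells exceeding the interfollicular fraction, one-sided
#' two-proportion test).
#'
#' @param config a [run_config()].
#' @return a `dc_pipeline_report` (list), invisibly written to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message("[dcmorph] ", line)
  }
  cfg_hash <- fnv1a(paste(deparse(config[setdiff(names(config), "out_dir")]),
                          collapse = ""))
  logmsg("dcmorph %s | config %s | seed %d | units: um, min, degrees",
         as.character(utils::packageVersion("dcmorph")), cfg_hash, config$seed)

  # --- input stage
  scenes <- list()
  dc_radius <- config$dc_radius
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_condensation(sim_cfg, scenes = "last")
    tracks <- sim$tracks
    scenes <- sim$scenes
    dc_radius <- dc_radius %||% sim_cfg$dc_radius
    logmsg("simulated %s-mode tracks: %d cells, %d frames (stage seed %d)",
           sim_cfg$mode, sim_cfg$n_cells, sim_cfg$n_frames, sim_cfg$seed)
  } else {
    tracks <- NULL
    if (!is.null(config$tracks_path)) {
      tracks <- read_tracks(config$tracks_path)
      logmsg("read %d track rows from %s", nrow(tracks), config$tracks_path)
    }
    if (!is.null(config$scene_path)) {
      scenes <- list(input = read_scene(config$scene_path))
      logmsg("read scene with %d cells from %s", nrow(scenes[[1]]$cells),
             config$scene_path)
    }
  }
  dc_radius <- dc_radius %||% 15

  tests <- list()
  tables <- list()
  metrics <- NULL
  center <- NULL

  if (!is.null(tracks)) {
    # --- drift correction (before any metric computation)
    if (any(tracks$cell_class == "reference")) {
      tracks <- correct_drift(tracks)
      logmsg("drift-corrected against %d reference track(s)",
             length(unique(tracks$track_id[tracks$cell_class == "reference"])))
    } else {
      logmsg("no reference cells: skipping drift correction")
    }
    center <- tryCatch(estimate_dc_center(tracks), error = function(e) NULL)
    if (is.null(center) && length(scenes)) {
      center <- scenes[[length(scenes)]]$references$dc_center
    }
    if (is.null(center)) {
      stopf("cannot locate the condensate centre (no sox2+ cells, no scene reference)")
    }
    logmsg("condensate centre at (%.1f, %.1f, %.1f) um", center[1], center[2], center[3])
    metrics <- compute_track_metrics(tracks, center,
                                     entry_radius = config$entry_radius,
                                     truncate = config$truncate_at_entry,
                                     threshold = config$distance_threshold)
    tables$track_metrics <- metrics
  }

  if ("directionality" %in% config$analyses) {
    if (is.null(metrics)) stopf("directionality stage requires tracks")
    grp <- group_by_initial_distance(metrics, config$distance_threshold)
    sph_seed <- stage_seed(config$seed, "directionality")
    for (g in c("dc_far", "dc_near", "interfollicular")) {
      ang <- grp[[g]]$escape_angle_deg
      ang <- ang[!is.na(ang)]
      if (length(ang) >= 4) {
        tests[[paste0("sphere_uniformity_", g)]] <-
          sphere_uniformity_test(angle_sample(ang, "axial_magnitude"),
                                 n_mc = config$n_mc, seed = sph_seed,
                                 alternative = "inward")
      }
      ang2 <- grp[[g]]$escape_angle_xy_deg
      ang2 <- ang2[!is.na(ang2)]
      if (length(ang2) >= 4) {
        tests[[paste0("rayleigh_", g)]] <-
          rayleigh_test(angle_sample(ang2, "planar_signed"))
      }
    }
    if (nrow(grp$dc_far) >= 8 && nrow(grp$interfollicular) >= 8) {
      a1 <- grp$dc_far$escape_angle_xy_deg
      a2 <- grp$interfollicular$escape_angle_xy_deg
      tests$watson_dc_far_vs_if <-
        watson_u2_test(angle_sample(a1[!is.na(a1)], "planar_signed"),
                       angle_sample(a2[!is.na(a2)], "planar_signed"),
                       n_permutations = config$n_permutations,
                       seed = stage_seed(config$seed, "watson"))
    }
    tables$escape_angle_medians <- data.frame(
      group = names(grp),
      n = vapply(grp, nrow, integer(1)),
      median_escape_angle_deg = vapply(grp, function(d)
        stats::median(d$escape_angle_deg, na.rm = TRUE), numeric(1)))
    logmsg("directionality: groups n = %s",
           paste(sprintf("%s %d", names(grp), vapply(grp, nrow, integer(1))),
                 collapse = ", "))
  }

  final_scene <- if (length(scenes)) scenes[[length(scenes)]] else NULL
  if (!is.null(final_scene) && !is.null(center)) {
    final_scene$regions$dc <- region_sphere(center, dc_radius)
  }

  if ("density" %in% config$analyses) {
    if (is.null(final_scene)) stopf("density stage requires a scene")
    # clone the condensate sphere to an interfollicular offset (identical
    # volume), pushed toward the farthest corner of the xy extent
    ext <- apply(scene_positions(final_scene), 2, max)
    off_dir <- ifelse(center[1:2] < ext[1:2] / 2, 1, -1)
    offset <- c(off_dir * 3 * dc_radius, 0)
    sc <- clone_region_at(final_scene, "dc", offset, "if_control")
    dens <- region_density(sc, c("dc", "if_control"))
    tables$density <- as.data.frame(dens)
    tables$density_ratios <- attr(dens, "ratios")
    logmsg("density: DC %.2f vs IF %.2f cells/1e4 um^3 (ratio %.2f)",
           dens$density_per_1e4_um3[1], dens$density_per_1e4_um3[2],
           attr(dens, "ratios")$ratio[1])
  }

  if ("neighbors" %in% config$analyses) {
    if (is.null(final_scene)) stopf("neighbors stage requires a scene")
    nb <- tryCatch(nearest_neighbor_labels(final_scene, "sox2", "sox2", "tdtomato"),
                   error = function(e) NULL)
    if (is.null(nb)) {
      logmsg("neighbors: skipped (insufficient labelled condensate cells)")
    } else {
      tables$neighbors <- nb$per_focal
      tables$neighbor_summary <- as.data.frame(nb$summary)
      tests$neighbor_randomness <- tryCatch(neighbor_randomness_test(nb),
                                            error = function(e) NULL)
      if (is.null(tests$neighbor_randomness)) tests$neighbor_randomness <- NULL
    }
  }

  proliferation_signal <- NA
  if ("fractions" %in% config$analyses) {
    if (is.null(final_scene)) stopf("fractions stage requires a scene")
    cells <- final_scene$cells
    dcp <- cells$sox2
    n_dc <- sum(dcp); n_if <- sum(!dcp)
    if (n_dc >= 5 && n_if >= 5) {
      sgm_dc <- sum(cells$fucci_sgm[dcp]); sgm_if <- sum(cells$fucci_sgm[!dcp])
      tab <- data.frame(compartment = c("dc", "interfollicular"),
                        n = c(n_dc, n_if),
                        sgm_fraction = c(sgm_dc / n_dc, sgm_if / n_if),
                        g1_fraction = c(1 - sgm_dc / n_dc, 1 - sgm_if / n_if))
      tables$cycle_fractions <- tab
      pt <- suppressWarnings(stats::prop.test(c(sgm_dc, sgm_if), c(n_dc, n_if),
                                              alternative = "greater"))
      tests$sgm_dc_vs_if <- dc_test_result(
        "two-proportion chi-square", unname(pt$statistic), pt$p.value,
        n_dc, n_if,
        method_note = "one-sided: S/G2/M fraction DC > IF")
      proliferation_signal <- pt$p.value < config$alpha_flag
      if ("tdtomato" %in% names(cells) && n_dc > 0) {
        lf <- label_fraction(sum(cells$tdtomato[dcp]), n_dc)
        tables$lineage_label <- data.frame(k = lf$k, n = lf$n,
                                           percent = lf$percent,
                                           ci_low = lf$ci[1] * 100,
                                           ci_high = lf$ci[2] * 100)
      }
      logmsg("fractions: DC S/G2/M %.2f (n=%d) vs IF %.2f (n=%d)",
             tab$sgm_fraction[1], n_dc, tab$sgm_fraction[2], n_if)
    } else {
      logmsg("fractions: skipped (too few condensate or interfollicular cells)")
    }
  }

  flag <- function(t) !is.null(t) && is.finite(t$p_value) &&
    t$p_value < config$alpha_flag
  med_of <- function(g) {
    tb <- tables$escape_angle_medians
    if (is.null(tb)) return(NA_real_)
    tb$median_escape_angle_deg[tb$group == g]
  }
  bias_flag <- function(g) {
    t <- tests[[paste0("sphere_uniformity_", g)]]
    isTRUE(flag(t) && t$statistic > 0 &&
             is.finite(med_of(g)) && med_of(g) < config$bias_median_threshold)
  }
  signatures <- list(
    directional_bias_dc_far = bias_flag("dc_far"),
    directional_bias_interfollicular = bias_flag("interfollicular"),
    proliferation_signal = isTRUE(proliferation_signal))
  logmsg("signatures at alpha=%.3g: bias(dc_far)=%s bias(IF)=%s proliferation=%s",
         config$alpha_flag, signatures[[1]], signatures[[2]], signatures[[3]])

  summary_obj <- list(
    package_version = as.character(utils::packageVersion("dcmorph")),
    config_hash = cfg_hash,
    seed = config$seed,
    units = list(length = "um", time = "min", angle = "degrees"),
    signatures = signatures,
    tests = lapply(tests, test_to_list),
    tables = lapply(tables, function(t) as.data.frame(t)))

  report <- structure(list(summary = summary_obj, tests = tests,
                           tables = tables, signatures = signatures,
                           log = log_lines, config = config),
                      class = "dc_pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      utils::write.csv(as.data.frame(tables[[nm]]),
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary_obj, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(format(report), "", "log:", paste(" ", log_lines)),
               file.path(config$out_dir, "report.txt"))
  }
  report
}

#' @export
format.dc_pipeline_report <- function(x, ...) {
  out <- c("dcmorph pipeline report",
           "units: micrometres, minutes, degrees",
           sprintf("seed: %d  config: %s", x$config$seed,
                   x$summary$config_hash),
           "",
           "signature flags:",
           sprintf("  %s: %s", names(x$signatures), unlist(x$signatures)),
           "",
           "statistical tests:")
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    out <- c(out, sprintf("  %s: %s = %.6g, p = %.4g [%s]",
                          nm, t$statistic_name, t$statistic, t$p_value,
                          t$method_note))
  }
  out
}

#' @export
print.dc_pipeline_report <- function(x, ...) {
  cat(paste(format(x), collapse = "\n"), "\n")
  invisible(x)
}
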