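#' Configuration for the agent-based condensation simulator
#'
#' The simulator emulates the three classical hypotheses for how a local
#' increase in mesenchymal cell density arises beneath a placode:
#' `proliferation` (locally increased mitotic activity), `migration`
#' (directed movement toward the condensate centre) and `nondispersal`
#' (cells that reach the condensate fail to leave), plus a `null` unbiased
#' random walk. Defaults encode the study conditions of explant time-lapse
#' imaging of early condensate formation: 20-min sampling over ~13 h,
#' a 15-um condensate radius (half the ~30-um condensate diameter), ~2x
#' seeded density contrast (an incipient condensate is already visible when
#' imaging starts), Fucci G1 fractions of 0.95 in the condensate vs 0.50
#' interfollicularly, a 65% lineage-label fraction, and >= 7 stationary
#' reference cells for drift correction. Cell speeds (0.3 +/- 0.1 um/min)
#' are illustrative: no measured fibroblast speed distribution is available.
#'
#' @param mode condensation mechanism regime.
#' @param n_cells number of motile cells at frame 0. The default gives an
#'   interfollicular density of ~11 cells per 1e4 um^3, matching embryonic
#'   upper-dermis packing (nuclei ~6 um across, ~10 um apart).
#' @param domain_extent xyz box size, um.
#' @param dc_center condensate centre, um (default: domain centre).
#' @param dc_radius condensate radius, um.
#' @param recruitment_radius cells starting within this distance of the
#'   centre are `dc_candidate`s (fated, marker-acquiring); the rest are
#'   interfollicular controls.
#' @param bias_kappa von Mises-Fisher concentration of the inward bias
#'   applied (migration mode only) to dc_candidate cells outside `dc_radius`;
#'   0 = isotropic.
#' @param speed_mean,speed_sd per-step speed distribution, um/min
#'   (truncated at 0).
#' @param frame_interval acquisition cadence, min.
#' @param n_frames number of frames (>= 2).
#' @param division_rate_dc,division_rate_if division rates, events/cell/hour,
#'   applied inside/outside `dc_radius` in proliferation mode. The
#'   proliferation default (0.2/h) is calibrated so that division balances
#'   diffusive dispersal and the regime actually produces the ~2x
#'   condensate/interfollicular density contrast it is meant to explain.
#' @param trap_factor multiplicative speed reduction inside `dc_radius`
#'   (migration and nondispersal modes).
#' @param cycle_g1_fraction_dc,cycle_g1_fraction_if probability that a cell
#'   (that did not divide during the simulation) is in G1, by final position.
#' @param label_fraction lineage-label (tdTomato) probability for
#'   dc_candidate cells.
#' @param label_clustering accepted for interface parity with
#'   [scene_spec()]; spatial label clustering emerges dynamically in the
#'   simulator rather than being imposed, so this knob only affects
#'   [generate_point_scene()] scenes.
#' @param density_contrast seeded condensate/interfollicular density ratio
#'   at frame 0 (an incipient condensate exists when imaging starts).
#' @param n_reference_cells stationary fiducial cells.
#' @param drift_per_frame optional global drift injected after simulation.
#' @param nuclear_diameter daughter placement distance on division, um.
#' @param seed RNG seed; identical configs give bit-identical output.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(mode = c("null", "migration", "proliferation",
                                       "nondispersal"),
                              n_cells = 1500L,
                              domain_extent = c(150, 150, 60),
                              dc_center = domain_extent / 2,
                              dc_radius = 15,
                              recruitment_radius = 60,
                              bias_kappa = NULL,
                              speed_mean = 0.3,
                              speed_sd = 0.1,
                              frame_interval = 20,
                              n_frames = 40L,
                              division_rate_dc = NULL,
                              division_rate_if = 0,
                              trap_factor = NULL,
                              cycle_g1_fraction_dc = NULL,
                              cycle_g1_fraction_if = 0.5,
                              label_fraction = 0.65,
                              label_clustering = 0,
                              n_reference_cells = 7L,
                              drift_per_frame = c(0, 0, 0),
                              density_contrast = 2,
                              nuclear_diameter = 6,
                              seed = 1L) {
  mode <- match.arg(mode)
  bias_kappa <- bias_kappa %||% if (mode == "migration") 8 else 0
  division_rate_dc <- division_rate_dc %||%
    if (mode == "proliferation") 0.2 else 0
  trap_factor <- trap_factor %||%
    if (mode %in% c("migration", "nondispersal")) 0.3 else 1
  cycle_g1_fraction_dc <- cycle_g1_fraction_dc %||%
    if (mode == "proliferation") 0.5 else 0.95
  cfg <- list(mode = mode, n_cells = as.integer(n_cells),
              domain_extent = as.numeric(domain_extent),
              dc_center = as.numeric(dc_center), dc_radius = dc_radius,
              recruitment_radius = recruitment_radius,
              bias_kappa = bias_kappa, speed_mean = speed_mean,
              speed_sd = speed_sd, frame_interval = frame_interval,
              n_frames = as.integer(n_frames),
              division_rate_dc = division_rate_dc,
              division_rate_if = division_rate_if,
              trap_factor = trap_factor,
              cycle_g1_fraction_dc = cycle_g1_fraction_dc,
              cycle_g1_fraction_if = cycle_g1_fraction_if,
              label_fraction = label_fraction,
              label_clustering = label_clustering,
              n_reference_cells = as.integer(n_reference_cells),
              drift_per_frame = as.numeric(drift_per_frame),
              density_contrast = density_contrast,
              nuclear_diameter = nuclear_diameter,
              seed = as.integer(seed))
  with(cfg, {
    if (n_frames < 2L) stopf("n_frames must be >= 2")
    if (n_cells < 1L) stopf("n_cells must be >= 1")
    if (any(c(division_rate_dc, division_rate_if, bias_kappa) < 0))
      stopf("rates and bias_kappa must be >= 0")
    fr <- c(cycle_g1_fraction_dc, cycle_g1_fraction_if, label_fraction,
            label_clustering, trap_factor)
    if (any(fr < 0 | fr > 1)) stopf("fractions and trap_factor must lie in [0,1]")
    if (dc_radius >= min(domain_extent) / 2)
      stopf("dc_radius must be smaller than half the smallest domain extent")
    if (any(dc_center < 0) || any(dc_center > domain_extent))
      stopf("dc_center lies outside the domain")
    if (n_reference_cells < 0L) stopf("n_reference_cells must be >= 0")
    if (frame_interval <= 0) stopf("frame_interval must be positive")
  })
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> mode=%s, %d cells (+%d reference), %d frames x %g min, seed %d\n",
              x$mode, x$n_cells, x$n_reference_cells, x$n_frames,
              x$frame_interval, x$seed))
  invisible(x)
}

reflect_into <- function(x, lo, hi) {
  # single reflection suffices: steps are far smaller than the domain
  x <- ifelse(x < lo, 2 * lo - x, x)
  ifelse(x > hi, 2 * hi - x, x)
}

#' Simulate condensation dynamics
#'
#' Biased-random-walk agents: per-frame displacement is
#' `speed * frame_interval` along a direction drawn from a von Mises-Fisher
#' distribution about the cell-to-centre unit vector with concentration
#' `bias_kappa` (kappa = 0 is isotropic). In migration mode the bias applies
#' to condensate-candidate cells outside the condensate and speed is reduced
#' by `trap_factor` inside it; nondispersal applies only the trap;
#' proliferation applies no bias but divides cells inside the condensate at
#' `division_rate_dc` (daughters placed one nuclear diameter away in a random
#' direction, continuing as independent tracks with suffixed ids); null is an
#' unbiased walk. Domain walls reflect. Reference cells are emitted as
#' exactly stationary tracks before any drift injection.
#'
#' Markers assigned at the end: `sox2` for cells inside the condensate at the
#' final frame (acquired de novo on entry), `fucci_g1` / `fucci_sgm` from the
#' per-region G1 fractions with cells that divided during the simulation
#' forced into S/G2/M, `edu` for divided lineages, and `tdtomato` lineage
#' labels on dc_candidates at `label_fraction`.
#'
#' @param config a [simulation_config()].
#' @param scenes which frames to materialise as `scene_frame`s:
#'   `"last"` (default), `"all"`, `"none"`, or integer frame numbers.
#' @return list with `tracks` (a `track_table`), `scenes` (named list of
#'   `scene_frame`s), and `config`.
#' @export
simulate_condensation <- function(config, scenes = "last") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ext <- config$domain_extent
  ctr <- config$dc_center
  dt_min <- config$frame_interval
  dt_hr <- dt_min / 60
  nf <- config$n_frames

  # --- initial placement with seeded density contrast inside the condensate
  v_dc <- 4 / 3 * pi * config$dc_radius^3
  v_all <- prod(ext)
  w_in <- config$density_contrast * v_dc /
    (v_all - v_dc + config$density_contrast * v_dc)
  n_in <- stats::rbinom(1, config$n_cells, w_in)
  pos_in <- if (n_in > 0) {
    sweep(runif_sphere(n_in) * (config$dc_radius * stats::runif(n_in)^(1 / 3)),
          2, ctr, `+`)
  } else matrix(numeric(0), ncol = 3)
  n_out <- config$n_cells - n_in
  pos_out <- matrix(numeric(0), ncol = 3)
  while (nrow(pos_out) < n_out) {
    cand <- cbind(stats::runif(n_out, 0, ext[1]), stats::runif(n_out, 0, ext[2]),
                  stats::runif(n_out, 0, ext[3]))
    keep <- vec_norm(sweep(cand, 2, ctr)) > config$dc_radius
    pos_out <- rbind(pos_out, cand[keep, , drop = FALSE])
  }
  pos <- rbind(pos_in, pos_out[seq_len(n_out), , drop = FALSE])
  ids <- sprintf("cell_%04d", seq_len(config$n_cells))
  init_dist <- vec_norm(sweep(pos, 2, ctr))
  cls <- ifelse(init_dist <= config$recruitment_radius, "dc_candidate",
                "interfollicular")
  divided <- rep(FALSE, config$n_cells)
  n_suffix <- integer(config$n_cells)
  ever_inside <- init_dist <= config$dc_radius

  frames_rec <- vector("list", nf)
  frames_rec[[1]] <- data.frame(track_id = ids, frame = 0L, x_um = pos[, 1],
                                y_um = pos[, 2], z_um = pos[, 3],
                                stringsAsFactors = FALSE)
  for (k in seq_len(nf - 1L)) {
    n <- nrow(pos)
    to_ctr <- sweep(pos, 2, ctr, `-`) * -1
    dist_c <- vec_norm(to_ctr)
    inside <- dist_c <= config$dc_radius
    dirs <- runif_sphere(n)
    if (config$mode == "migration" && config$bias_kappa > 0) {
      biased <- cls == "dc_candidate" & !inside & dist_c > 1e-9
      if (any(biased)) {
        dirs[biased, ] <- rvmf(sum(biased), unitize(to_ctr[biased, , drop = FALSE]),
                               config$bias_kappa)
      }
    }
    step <- rspeed(n, config$speed_mean, config$speed_sd) * dt_min
    if (config$mode %in% c("migration", "nondispersal")) {
      step[inside] <- step[inside] * config$trap_factor
    }
    pos <- pos + dirs * step
    for (ax in 1:3) pos[, ax] <- reflect_into(pos[, ax], 0, ext[ax])
    ever_inside <- ever_inside | vec_norm(sweep(pos, 2, ctr)) <= config$dc_radius

    if (config$mode == "proliferation" &&
        (config$division_rate_dc > 0 || config$division_rate_if > 0)) {
      p_div <- ifelse(inside, config$division_rate_dc, config$division_rate_if) * dt_hr
      div_now <- stats::runif(n) < p_div
      if (any(div_now)) {
        for (j in which(div_now)) {
          n_suffix[j] <- n_suffix[j] + 1L
          daughter_id <- paste0(ids[j], letters[min(n_suffix[j], 26L)])
          dpos <- pos[j, ] + runif_sphere(1)[1, ] * config$nuclear_diameter
          dpos <- pmin(pmax(dpos, 0), ext)
          pos <- rbind(pos, dpos)
          ids <- c(ids, daughter_id)
          cls <- c(cls, cls[j])
          divided[j] <- TRUE
          divided <- c(divided, TRUE)
          n_suffix <- c(n_suffix, 0L)
          # Sox2 status is heritable; born-inside daughters acquire it anyway
          ever_inside <- c(ever_inside,
                           ever_inside[j] ||
                             sqrt(sum((dpos - ctr)^2)) <= config$dc_radius)
        }
      }
    }
    frames_rec[[k + 1L]] <- data.frame(track_id = ids, frame = k,
                                       x_um = pos[, 1], y_um = pos[, 2],
                                       z_um = pos[, 3], stringsAsFactors = FALSE)
  }

  # --- final-state marker assignment
  final_dist <- vec_norm(sweep(pos, 2, ctr))
  in_dc_final <- final_dist <= config$dc_radius
  # Sox2 is acquired de novo on condensate entry and then persists
  sox2 <- ever_inside
  g1_prob <- ifelse(in_dc_final, config$cycle_g1_fraction_dc,
                    config$cycle_g1_fraction_if)
  fucci_g1 <- stats::runif(length(ids)) < g1_prob
  fucci_g1[divided] <- FALSE
  tdtomato <- cls == "dc_candidate" & stats::runif(length(ids)) < config$label_fraction
  markers <- data.frame(track_id = ids, cell_class = cls, sox2 = sox2,
                        fucci_g1 = fucci_g1, fucci_sgm = !fucci_g1,
                        tdtomato = tdtomato, edu = divided,
                        stringsAsFactors = FALSE)

  # --- reference cells: uniform, exactly stationary
  if (config$n_reference_cells > 0L) {
    rpos <- cbind(stats::runif(config$n_reference_cells, 0, ext[1]),
                  stats::runif(config$n_reference_cells, 0, ext[2]),
                  stats::runif(config$n_reference_cells, 0, ext[3]))
    rid <- sprintf("ref_%02d", seq_len(config$n_reference_cells))
    ref_rec <- do.call(rbind, lapply(0:(nf - 1L), function(k) {
      data.frame(track_id = rid, frame = k, x_um = rpos[, 1], y_um = rpos[, 2],
                 z_um = rpos[, 3], stringsAsFactors = FALSE)
    }))
    markers <- rbind(markers,
                     data.frame(track_id = rid, cell_class = "reference",
                                sox2 = FALSE, fucci_g1 = FALSE, fucci_sgm = FALSE,
                                tdtomato = FALSE, edu = FALSE,
                                stringsAsFactors = FALSE))
  } else ref_rec <- NULL

  long <- do.call(rbind, c(frames_rec, list(ref_rec)))
  long <- merge(long, markers, by = "track_id", sort = FALSE)
  long$time_min <- long$frame * dt_min
  tracks <- track_table(long[, c("track_id", "frame", "time_min", "x_um", "y_um",
                                 "z_um", "cell_class", "sox2", "fucci_g1",
                                 "fucci_sgm", "tdtomato", "edu")])
  if (any(config$drift_per_frame != 0)) {
    tracks <- inject_drift(tracks, config$drift_per_frame)
  }

  scene_frames <- if (identical(scenes, "all")) 0:(nf - 1L)
                  else if (identical(scenes, "last")) nf - 1L
                  else if (identical(scenes, "none")) integer(0)
                  else as.integer(scenes)
  scene_list <- list()
  for (f in scene_frames) {
    snap <- tracks[tracks$frame == f & tracks$cell_class != "reference", ,
                   drop = FALSE]
    cells <- data.frame(id = snap$track_id, x_um = snap$x_um, y_um = snap$y_um,
                        z_um = snap$z_um, sox2 = snap$sox2,
                        fucci_g1 = snap$fucci_g1, fucci_sgm = snap$fucci_sgm,
                        tdtomato = snap$tdtomato, edu = snap$edu,
                        dc_candidate = snap$cell_class == "dc_candidate",
                        stringsAsFactors = FALSE)
    scene_list[[sprintf("frame_%03d", f)]] <-
      scene_frame(cells,
                  regions = list(dc = region_sphere(ctr, config$dc_radius)),
                  references = list(dc_center = ctr))
  }
  list(tracks = tracks, scenes = scene_list, config = config)
}
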