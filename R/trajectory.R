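#' Correct translational tissue drift using non-motile reference cells
#'
#' For each frame k, the mean displacement (relative to frame 0) of the
#' reference-class tracks is subtracted from every position at frame k. After
#' correction the reference cells are stationary up to their internal scatter.
#' A warning is issued when fewer than 7 reference cells are available (the
#' practical minimum for stable drift estimates in explant imaging).
#'
#' @param tracks a `track_table` containing at least one `reference` track
#'   spanning every frame present in the table.
#' @return the drift-corrected `track_table`.
#' @export
correct_drift <- function(tracks) {
  stopifnot(inherits(tracks, "track_table"))
  refs <- tracks[tracks$cell_class == "reference", , drop = FALSE]
  if (!nrow(refs)) stopf("no reference tracks: drift correction needs non-motile cells")
  frames <- sort(unique(tracks$frame))
  ref_ids <- unique(refs$track_id)
  if (length(ref_ids) < 7) {
    warnf("only %d reference cell(s); at least 7 non-motile cells are recommended",
          length(ref_ids))
  }
  for (id in ref_ids) {
    f <- refs$frame[refs$track_id == id]
    if (!all(frames %in% f)) {
      stopf("reference track '%s' has gaps (misses %d frame(s))",
            id, sum(!frames %in% f))
    }
  }
  refs <- refs[order(refs$track_id, refs$frame), , drop = FALSE]
  # per-reference displacement relative to its own frame-0 position
  pos <- as.matrix(refs[, c("x_um", "y_um", "z_um")])
  first_idx <- !duplicated(refs$track_id)
  origin <- pos[first_idx, , drop = FALSE][match(refs$track_id, refs$track_id[first_idx]), ,
                                           drop = FALSE]
  disp <- pos - origin
  drift <- rowsum(disp, group = match(refs$frame, frames)) / length(ref_ids)
  k <- match(tracks$frame, frames)
  tracks$x_um <- tracks$x_um - drift[k, 1]
  tracks$y_um <- tracks$y_um - drift[k, 2]
  tracks$z_um <- tracks$z_um - drift[k, 3]
  tracks
}

#' Escape angle between a displacement and the direction to a centre
#'
#' The escape angle alpha is the angle between the cell trajectory vector
#' `a = end - start` and `b = center - start`, from
#' `cos(alpha) = (a . b) / (|a| |b|)`. 0 deg is motion straight toward the
#' centre, 90 deg orthogonal, 180 deg straight away.
#'
#' @param start,end,center xyz positions (um).
#' @return angle in degrees, in \[0, 180\].
#' @export
escape_angle <- function(start, end, center) {
  a <- as.numeric(end) - as.numeric(start)
  b <- as.numeric(center) - as.numeric(start)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0) stopf("undefined escape angle: zero net displacement")
  if (nb == 0) stopf("undefined escape angle: start coincides with the centre")
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

# vectorised escape angles; NA where undefined
escape_angle_vec <- function(a, b) {
  na <- vec_norm(a); nb <- vec_norm(b)
  ok <- na > 0 & nb > 0
  ca <- rowSums(a * b) / (na * nb)
  out <- rep(NA_real_, nrow(a))
  out[ok] <- acos(pmax(-1, pmin(1, ca[ok]))) * 180 / pi
  out
}

# signed planar (xy-projection) angle of displacement relative to the
# direction toward the centre, in [0, 360)
escape_angle_xy_vec <- function(a, b) {
  ok <- (a[, 1]^2 + a[, 2]^2) > 0 & (b[, 1]^2 + b[, 2]^2) > 0
  ang <- atan2(a[, 2], a[, 1]) - atan2(b[, 2], b[, 1])
  out <- rep(NA_real_, nrow(a))
  out[ok] <- (ang[ok] * 180 / pi) %% 360
  out
}

#' Per-track motility metrics and escape angles
#'
#' Computes, for every non-reference track with positive duration:
#' `velocity = track length / duration`, `net velocity = displacement length
#' / duration`, `straightness = displacement length / track length`, the 3D
#' escape angle (and its signed 2D-projection variant) toward the relevant
#' centre, and the initial distance to the condensate centre. Condensate
#' candidates use `center`; interfollicular tracks use `if_center` (default:
#' the centroid of their own starting positions — an arbitrary migration
#' centre). With `truncate = TRUE`, each `dc_candidate` track is cut at its
#' first frame closer than `entry_radius` to the centre before metrics are
#' computed, so that only migration up to condensate entry is measured;
#' tracks that already start inside are left whole.
#'
#' @param tracks a drift-corrected `track_table`.
#' @param center condensate centre, xyz um (see [estimate_dc_center()]).
#' @param entry_radius condensate entry radius, um (default 15, half the
#'   typical 30 um condensate diameter). `0` disables truncation.
#' @param truncate cut dc_candidate tracks at condensate entry.
#' @param if_center optional interfollicular migration centre.
#' @param threshold initial-distance grouping threshold, um (default 30).
#' @return a `trajectory_metrics` data.frame, one row per usable track.
#' @export
compute_track_metrics <- function(tracks, center, entry_radius = 15,
                                  truncate = FALSE, if_center = NULL,
                                  threshold = 30) {
  stopifnot(inherits(tracks, "track_table"), length(center) == 3)
  if (entry_radius < 0) stopf("entry_radius must be >= 0")
  center <- as.numeric(center)
  mov <- tracks[tracks$cell_class != "reference", , drop = FALSE]
  if (!nrow(mov)) stopf("no analyzable (non-reference) tracks")
  mov <- mov[order(mov$track_id, mov$frame), , drop = FALSE]
  if (is.null(if_center)) {
    iff <- mov[mov$cell_class == "interfollicular" & !duplicated(mov$track_id), ,
               drop = FALSE]
    if_center <- if (nrow(iff)) colMeans(iff[, c("x_um", "y_um", "z_um")]) else center
  }
  if_center <- as.numeric(if_center)

  truncated_ids <- character(0)
  if (truncate && entry_radius > 0) {
    pos <- as.matrix(mov[, c("x_um", "y_um", "z_um")])
    dist_c <- vec_norm(sweep(pos, 2, center))
    rn <- stats::ave(seq_len(nrow(mov)), mov$track_id, FUN = seq_along)
    inside <- dist_c < entry_radius & mov$cell_class == "dc_candidate"
    entry_rn <- stats::ave(ifelse(inside, rn, Inf), mov$track_id, FUN = min)
    # truncate only at entries after the first frame (tracks starting inside
    # are left whole); keep rows up to and including the entry frame
    cut_at <- ifelse(entry_rn >= 2, entry_rn, Inf)
    keep <- rn <= cut_at
    truncated_ids <- unique(mov$track_id[is.finite(cut_at)])
    mov <- mov[keep, , drop = FALSE]
  }

  id <- mov$track_id
  pos <- as.matrix(mov[, c("x_um", "y_um", "z_um")])
  firsts <- !duplicated(id)
  lasts <- !duplicated(id, fromLast = TRUE)
  n_pts <- as.vector(table(factor(id, levels = id[firsts])))
  # segment lengths, dropping cross-track differences
  seg <- sqrt(rowSums(diff(pos)^2))
  same <- id[-1] == id[-length(id)]
  seg_id <- id[-1][same]
  track_len <- rep(0, sum(firsts))
  names(track_len) <- id[firsts]
  if (length(seg_id)) {
    tl <- rowsum(seg[same], group = seg_id)
    track_len[rownames(tl)] <- tl[, 1]
  }
  p0 <- pos[firsts, , drop = FALSE]
  p1 <- pos[lasts, , drop = FALSE]
  disp_vec <- p1 - p0
  disp_len <- vec_norm(disp_vec)
  duration <- mov$time_min[lasts] - mov$time_min[firsts]
  cls <- mov$cell_class[firsts]
  ctr_mat <- matrix(if_center, nrow = sum(firsts), ncol = 3, byrow = TRUE)
  is_dc <- cls == "dc_candidate"
  ctr_mat[is_dc, ] <- matrix(center, nrow = sum(is_dc), ncol = 3, byrow = TRUE)
  bvec <- ctr_mat - p0
  init_dist <- vec_norm(sweep(p0, 2, center))
  res <- data.frame(
    track_id = id[firsts],
    cell_class = cls,
    group = ifelse(!is_dc, "interfollicular",
                   ifelse(init_dist > threshold, "dc_far", "dc_near")),
    track_length_um = unname(track_len[id[firsts]]),
    displacement_um = disp_len,
    duration_min = duration,
    stringsAsFactors = FALSE)
  res$velocity_um_min <- res$track_length_um / res$duration_min
  res$net_velocity_um_min <- res$displacement_um / res$duration_min
  res$straightness <- ifelse(res$track_length_um > 0,
                             res$displacement_um / res$track_length_um, NA_real_)
  res$escape_angle_deg <- escape_angle_vec(disp_vec, bvec)
  res$escape_angle_xy_deg <- escape_angle_xy_vec(disp_vec, bvec)
  res$initial_distance_um <- init_dist
  res$truncated_at_entry <- res$track_id %in% truncated_ids
  usable <- n_pts >= 2L & duration > 0
  if (any(!usable)) {
    warnf("%d track(s) excluded (single point or zero duration)", sum(!usable))
  }
  res <- res[usable, , drop = FALSE]
  if (!nrow(res)) stopf("no usable tracks after exclusion")
  rownames(res) <- NULL
  class(res) <- unique(c("trajectory_metrics", class(res)))
  res
}

#' Partition track metrics by initial distance to the condensate centre
#'
#' Condensate-candidate tracks split at the threshold (default 30 um, the
#' average condensate diameter): strictly greater is `dc_far`, less-or-equal
#' is `dc_near` (the boundary is assigned to near). Interfollicular tracks
#' pass through unchanged. The partition is exhaustive and disjoint.
#'
#' @param metrics a `trajectory_metrics` data.frame.
#' @param threshold distance threshold, um.
#' @return named list of data.frames: `dc_far`, `dc_near`, `interfollicular`.
#' @export
group_by_initial_distance <- function(metrics, threshold = 30) {
  stopifnot(inherits(metrics, "trajectory_metrics"), nrow(metrics) > 0)
  dc <- metrics$cell_class == "dc_candidate"
  list(dc_far = metrics[dc & metrics$initial_distance_um > threshold, , drop = FALSE],
       dc_near = metrics[dc & metrics$initial_distance_um <= threshold, , drop = FALSE],
       interfollicular = metrics[!dc, , drop = FALSE])
}

#' Estimate the condensate centre from marker-positive cells
#'
#' The centre is the centroid of the final-frame positions of cells carrying
#' the condensate marker (default `sox2`), mirroring the definition of the
#' condensate centre as the centre of the condensate reporter signal.
#'
#' @param tracks a `track_table` with the marker column.
#' @param marker marker column name.
#' @param frame `"last"` (default) or a frame number.
#' @return xyz centre, um.
#' @export
estimate_dc_center <- function(tracks, marker = "sox2", frame = "last") {
  stopifnot(inherits(tracks, "track_table"))
  if (!marker %in% names(tracks)) stopf("marker column '%s' not present", marker)
  f <- if (identical(frame, "last")) max(tracks$frame) else as.integer(frame)
  sel <- tracks$frame == f & tracks[[marker]] & tracks$cell_class != "reference"
  if (!any(sel)) stopf("no %s-positive cells at frame %d", marker, f)
  colMeans(tracks[sel, c("x_um", "y_um", "z_um")])
}
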