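#' Configuration for the synthetic muscle volume generator
#'
#' The generator emulates the geometry that segmented volume-EM muscle data
#' present to the analysis pipeline: parallel quasi-cylindrical myofibrils
#' along the longitudinal axis, periodic sarcomeres separated by thin
#' sarcotubular (SRT) gaps, and split/merge junction events at sarcomere
#' boundaries, inside an enclosing cell mask. Every event and per-sarcomere
#' branching flag is returned as ground truth, so topology recovery can be
#' validated exactly.
#'
#' Event model: each (myofibril, sarcomere) independently hosts at most one
#' junction event at its downstream sarcomere boundary, with probability
#' `p_single` of a single event (2 resultant segments) and `p_multi` of a
#' multi event (`k >= 3` resultant segments, `k` drawn from
#' `multi_multiplicity_pmf`). Each event is realized as a split with
#' probability `1 - p_merge_fraction` and as its longitudinal mirror image (a
#' merge) otherwise. Branch count is `k - 1` either way. Volumes begin and
#' end with a partial-sarcomere pad beyond the outermost SRT plane, so every
#' counted sarcomere has both boundaries inside the field of view and the
#' realized branching fraction is an unbiased estimate of
#' `p_single + p_multi`.
#'
#' Default geometry is desk-scale realistic for tubular insect muscle imaged
#' at 10 nm and binned to 20 nm: 3.2 um sarcomeres, 0.4 um myofibril radius,
#' 40 nm SRT gaps. Tests and examples pass smaller grids explicitly.
#'
#' @param grid_shape integer length-3 `(n_long, n_row, n_col)` voxel counts.
#' @param voxel_size numeric length-3 voxel size in nm.
#' @param n_myofibrils number of myofibrils (excluding `n_exiting`).
#' @param myofibril_radius_mean,myofibril_radius_sd radius distribution (nm).
#' @param sarcomere_length sarcomere length (nm).
#' @param srt_gap_thickness thickness of the SRT plane between sarcomeres (nm).
#' @param p_single,p_multi per-sarcomere probabilities of single and
#'   multi-branching events; their sum must be <= 1.
#' @param multi_multiplicity_pmf named probability vector over resultant
#'   segment counts `k >= 3` for multi events. The default is calibrated so
#'   that `E[k - 1] = 2.656`, the value implied by inverting the highly
#'   branched leg-muscle regime (27.2% single, 38.7% multi, 13.0 branches per
#'   10 sarcomeres).
#' @param p_merge_fraction fraction of events realized as merges.
#' @param peripheral_bias >= 0; 0 places events uniformly, larger values
#'   concentrate events on myofibrils near the cell boundary while keeping
#'   the mean event rate at `p_single + p_multi`.
#' @param cell_margin margin of the cell mask around the myofibril bundle (nm).
#' @param n_exiting number of extra myofibrils that drift out of the lateral
#'   field of view (used to validate censoring; they carry no events).
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @return An object of class `generator_config`.
#' @seealso [generate_muscle_volume()], [expected_statistics()],
#'   [muscle_type_rates()]
#' @export
generator_config <- function(grid_shape = c(1024L, 256L, 256L),
                             voxel_size = c(20, 20, 20),
                             n_myofibrils = 4L,
                             myofibril_radius_mean = 400,
                             myofibril_radius_sd = 0,
                             sarcomere_length = 3200,
                             srt_gap_thickness = 40,
                             p_single = 0,
                             p_multi = 0,
                             multi_multiplicity_pmf = NULL,
                             p_merge_fraction = 0.5,
                             peripheral_bias = 0,
                             cell_margin = 100,
                             n_exiting = 0L,
                             seed = 1L) {
  if (is.null(multi_multiplicity_pmf)) {
    ek1 <- (1.30 - 0.272) / 0.387           # E[k-1] implied by the leg regime
    p5 <- 0.12; p6 <- 0.05
    p4 <- ek1 - 2 - (2 * p5 + 3 * p6)        # solve 2 p3 + 3 p4 + 4 p5 + 5 p6
    p3 <- 1 - p4 - p5 - p6
    multi_multiplicity_pmf <- c(`3` = p3, `4` = p4, `5` = p5, `6` = p6)
  }
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size = as.numeric(voxel_size),
              n_myofibrils = as.integer(n_myofibrils),
              myofibril_radius_mean = myofibril_radius_mean,
              myofibril_radius_sd = myofibril_radius_sd,
              sarcomere_length = sarcomere_length,
              srt_gap_thickness = srt_gap_thickness,
              p_single = p_single, p_multi = p_multi,
              multi_multiplicity_pmf = multi_multiplicity_pmf,
              p_merge_fraction = p_merge_fraction,
              peripheral_bias = peripheral_bias,
              cell_margin = cell_margin,
              n_exiting = as.integer(n_exiting),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stop("grid_shape must be 3 positive integers", call. = FALSE)
    if (length(voxel_size) != 3L || any(voxel_size <= 0))
      stop("voxel_size must be positive", call. = FALSE)
    if (p_single < 0 || p_multi < 0 || p_single + p_multi > 1)
      stop("need p_single, p_multi >= 0 and p_single + p_multi <= 1",
           call. = FALSE)
    if (p_merge_fraction < 0 || p_merge_fraction > 1)
      stop("p_merge_fraction must be in [0, 1]", call. = FALSE)
    if (peripheral_bias < 0) stop("peripheral_bias must be >= 0",
                                  call. = FALSE)
    if (any(c(myofibril_radius_mean, sarcomere_length,
              srt_gap_thickness) <= 0) || cell_margin < 0 ||
        myofibril_radius_sd < 0)
      stop("geometric parameters must be positive", call. = FALSE)
    ks <- as.integer(names(multi_multiplicity_pmf))
    if (any(is.na(ks)) || any(ks < 3L))
      stop("multi_multiplicity_pmf must be named with counts k >= 3",
           call. = FALSE)
    if (any(multi_multiplicity_pmf < 0) ||
        abs(sum(multi_multiplicity_pmf) - 1) > 1e-8)
      stop("multi_multiplicity_pmf must sum to 1", call. = FALSE)
    if (n_myofibrils < 1L) stop("need at least one myofibril", call. = FALSE)
    if (n_exiting < 0L) stop("n_exiting must be >= 0", call. = FALSE)
  })
  invisible(cfg)
}

#' Per-sarcomere branching rates matching the wild-type and misexpression
#' muscle regimes
#'
#' Returns `(p_single, p_multi)` pairs reproducing the reported group-mean
#' branching statistics of each muscle type, for use with
#' [generator_config()]. Where only the total branching percentage was
#' reported, single/multi rates are derived from the reported branches per 10
#' sarcomere lengths (or, failing that, apportioned using the leg-muscle
#' single:multi ratio).
#'
#' @param type one of `"IF"`, `"TDT"`, `"DF"`, `"leg"`, `"H15_KD_TDT"`,
#'   `"salm_KD_IF"`, `"NCDN_KD_IF"`.
#' @return named numeric `c(p_single=, p_multi=)`.
#' @export
muscle_type_rates <- function(type = c("IF", "TDT", "DF", "leg",
                                       "H15_KD_TDT", "salm_KD_IF",
                                       "NCDN_KD_IF")) {
  type <- match.arg(type)
  ek1 <- (1.30 - 0.272) / 0.387
  from_b10 <- function(total, b10) {
    pm <- (b10 / 10 - total) / (ek1 - 1)
    c(p_single = total - pm, p_multi = pm)
  }
  leg_ratio <- function(total) {
    c(p_single = total * 0.272 / 0.659, p_multi = total * 0.387 / 0.659)
  }
  switch(type,
         IF = c(p_single = 0, p_multi = 0),
         leg = c(p_single = 0.272, p_multi = 0.387),
         TDT = from_b10(0.108, 1.8),
         H15_KD_TDT = from_b10(0.782, 14.0),
         salm_KD_IF = from_b10(0.452, 6.9),
         DF = leg_ratio(0.324),
         NCDN_KD_IF = leg_ratio(0.538))
}

#' Closed-form expected branching statistics for a generator configuration
#'
#' The analytic twin of [branching_statistics()]: what the analysis should
#' recover, in expectation, from volumes generated with `config`.
#'
#' @param config a [generator_config()].
#' @return list with `pct_branching_sarcomeres`, `pct_single`, `pct_multi`
#'   (percent of sarcomeres) and `branches_per_10` (branches per 10 sarcomere
#'   lengths, `10 (p_single + p_multi E[k-1])`; merges contribute
#'   identically to splits).
#' @export
expected_statistics <- function(config) {
  validate_generator_config(config)
  ks <- as.numeric(names(config$multi_multiplicity_pmf))
  ek1 <- sum((ks - 1) * config$multi_multiplicity_pmf)
  list(pct_branching_sarcomeres = 100 * (config$p_single + config$p_multi),
       pct_single = 100 * config$p_single,
       pct_multi = 100 * config$p_multi,
       branches_per_10 = 10 * (config$p_single + config$p_multi * ek1))
}

# disk pixel offsets for a given radius (voxel units, possibly anisotropic)
disk_offsets <- function(r_row, r_col) {
  mr <- ceiling(r_row); mc <- ceiling(r_col)
  dr <- rep(-mr:mr, times = 2 * mc + 1)
  dc <- rep(-mc:mc, each = 2 * mr + 1)
  keep <- (dr / r_row)^2 + (dc / r_col)^2 <= 1
  cbind(dr = dr[keep], dc = dc[keep])
}

#' Generate a ground-truthed synthetic muscle volume
#'
#' @param config a [generator_config()].
#' @return A list of class `synthetic_muscle` with elements `labels`
#'   ([labeled_volume()]), `cell` and `srt` ([mask_volume()]s), and `truth`,
#'   a `synthetic_ground_truth` list holding `segments`, `events`,
#'   `flags` (myofibril x sarcomere branching matrix), `per_myofibril`,
#'   `n_sarcomeres`, `plane_starts`, `max_gap` (the slice gap the segment
#'   graph must bridge) and the `config`.
#' @export
generate_muscle_volume <- function(config) {
  validate_generator_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  nz <- config$grid_shape[1]; nr <- config$grid_shape[2]
  nc <- config$grid_shape[3]
  dz <- config$voxel_size[1]; dy <- config$voxel_size[2]
  dx <- config$voxel_size[3]

  L <- max(3L, as.integer(round(config$sarcomere_length / dz)))
  g <- max(1L, as.integer(round(config$srt_gap_thickness / dz)))
  max_gap <- g + 2L
  pad <- max(2L, as.integer(ceiling(0.3 * L)))
  if (floor(0.6 * L) - floor(0.4 * L) <= max_gap + 1L) {
    stop("sarcomere_length too small relative to srt_gap_thickness ",
         "(stub separation would be ambiguous)", call. = FALSE)
  }
  n_sarc <- (nz - 2L * pad - g) %/% (L + g)
  if (n_sarc < 1L) {
    stop("grid too short along the longitudinal axis for even one sarcomere",
         call. = FALSE)
  }
  # plane i (i = 0..n_sarc) occupies plane_start[i+1] .. +g-1
  plane_start <- pad + (0:n_sarc) * (L + g) + 1L
  sarc_start <- plane_start[1:n_sarc] + g          # first slice of sarcomere i
  z_cap <- plane_start[n_sarc + 1L] + g - 1L + pad  # trailing partial pad

  # --- lateral packing -------------------------------------------------------
  n_total <- config$n_myofibrils + config$n_exiting
  radii <- pmax(2L, as.integer(round(
    stats::rnorm(n_total, config$myofibril_radius_mean / dy,
                 config$myofibril_radius_sd / dy))))
  half <- as.integer(ceiling(1.5 * max(radii))) + 1L
  marg <- as.integer(ceiling(config$cell_margin / dy))
  spacing <- 2L * half + 1L
  rpos <- seq(half + marg + 1L, nr - half - marg, by = spacing)
  cpos <- seq(half + marg + 1L, nc - half - marg, by = spacing)
  if (length(rpos) * length(cpos) < n_total) {
    stop("cannot pack ", n_total, " myofibrils of radius ~", max(radii),
         " voxels into a ", nr, "x", nc, " cross-section", call. = FALSE)
  }
  centers <- cbind(rep(rpos, times = length(cpos)),
                   rep(cpos, each = length(rpos)))
  # exiting myofibrils take lanes in the first column block (near col face 1)
  ord <- order(centers[, 2], centers[, 1])
  centers <- centers[ord, , drop = FALSE]
  exiting <- c(rep(TRUE, config$n_exiting),
               rep(FALSE, config$n_myofibrils))
  centers <- centers[seq_len(n_total), , drop = FALSE]

  # --- event draws -----------------------------------------------------------
  p_tot <- config$p_single + config$p_multi
  w <- rep(1, n_total)
  if (config$peripheral_bias > 0 && p_tot > 0) {
    # lane distance to the cell bounding box, in voxels
    box <- c(min(centers[, 1]) - half - marg, max(centers[, 1]) + half + marg,
             min(centers[, 2]) - half - marg, max(centers[, 2]) + half + marg)
    d_m <- pmin(centers[, 1] - box[1], box[2] - centers[, 1],
                centers[, 2] - box[3], box[4] - centers[, 2])
    w <- exp(config$peripheral_bias * (1 - d_m / max(d_m, 1)))
  }
  keep_idx <- which(!exiting)
  w_scale <- w / mean(w[keep_idx])

  kvals <- as.integer(names(config$multi_multiplicity_pmf))
  kprob <- as.numeric(config$multi_multiplicity_pmf)

  ev_type <- matrix("", n_total, n_sarc)     # "", "single", "multi"
  ev_kind <- matrix("", n_total, n_sarc)     # "split", "merge"
  ev_k <- matrix(2L, n_total, n_sarc)        # resultant segment count
  for (m in seq_len(n_total)) {
    if (exiting[m] || p_tot == 0) next
    ps <- min(1, config$p_single * w_scale[m])
    pm <- min(1 - ps, config$p_multi * w_scale[m])
    u <- stats::runif(n_sarc)
    hit_s <- u < ps
    hit_m <- !hit_s & u < ps + pm
    for (i in seq_len(n_sarc)) {
      if (hit_s[i]) {
        ev_type[m, i] <- "single"; ev_k[m, i] <- 2L
      } else if (hit_m[i]) {
        ev_type[m, i] <- "multi"
        ev_k[m, i] <- sample(kvals, 1L, prob = kprob)
      } else next
      ev_kind[m, i] <- if (stats::runif(1) < config$p_merge_fraction)
        "merge" else "split"
    }
  }

  # --- build segment plan ----------------------------------------------------
  seg <- list(); evs <- list()
  label_counter <- n_total
  state_label <- seq_len(n_total)
  state_start <- rep(1L, n_total)
  stub_len <- as.integer(floor(0.4 * L))

  add_seg <- function(label, m, z1, z2, cr, cc, radius, kind) {
    seg[[length(seg) + 1L]] <<- list(label = label, myofibril = m,
                                     z_first = z1, z_last = z2, cr = cr,
                                     cc = cc, radius = radius, kind = kind)
  }

  # exiting myofibrils: drift toward column face 1, one jump per plane crossed
  drift_step <- integer(n_total)
  for (m in which(exiting)) {
    c0 <- centers[m, 2]; r <- radii[m]
    nb <- max(1L, as.integer(floor(0.6 * (n_sarc + 1))))
    drift_step[m] <- min(2L * r - 1L, max(1L, as.integer(ceiling((c0 + r) / nb))))
  }

  for (i in seq_len(n_sarc)) {
    p1 <- plane_start[i + 1L]              # downstream plane of sarcomere i
    for (m in seq_len(n_total)) {
      ty <- ev_type[m, i]
      if (ty == "") next
      k <- ev_k[m, i]
      kind <- ev_kind[m, i]
      cr <- centers[m, 1]; cc <- centers[m, 2]; r <- radii[m]
      rs <- max(2L, as.integer(floor(r / 2)))
      # stubs equally spaced around the parent axis (separation >= 72 deg,
      # so sibling stubs of radius r/2 at offset r never collide)
      angs <- stats::runif(1, 0, 2 * pi) +
        2 * pi * (seq_len(k - 1L) - 1L) / (k - 1L)
      child_z <- p1 + g                     # first slice after the plane
      if (kind == "split") {
        add_seg(state_label[m], m, state_start[m], p1 - 1L, cr, cc, r, "main")
        cont <- label_counter + 1L
        stubs <- cont + seq_len(k - 1L)
        label_counter <- cont + k - 1L
        for (j in seq_len(k - 1L)) {
          scr <- cr + as.integer(round(r * cos(angs[j])))
          scc <- cc + as.integer(round(r * sin(angs[j])))
          # stubs never reach the trailing cap: they must not look like
          # first-slice seeds when the longitudinal axis is reversed
          z2 <- max(child_z + 1L,
                    min(child_z + stub_len - 1L, z_cap - max_gap - 2L))
          add_seg(stubs[j], m, child_z, z2, scr, scc, rs, "stub")
        }
        evs[[length(evs) + 1L]] <- list(
          myofibril = m, sarcomere = i, z_position = child_z,
          type = "split", classification = if (k == 2L) "single" else "multi",
          branch_count = k - 1L, parents = state_label[m],
          children = c(cont, stubs))
        state_label[m] <- cont
        state_start[m] <- child_z
      } else {                              # merge, mirrored split
        stubs <- label_counter + seq_len(k - 1L)
        child <- label_counter + k
        label_counter <- child
        stub_z1 <- sarc_start[i] + as.integer(floor(0.6 * L))
        for (j in seq_len(k - 1L)) {
          scr <- cr + as.integer(round(r * cos(angs[j])))
          scc <- cc + as.integer(round(r * sin(angs[j])))
          add_seg(stubs[j], m, stub_z1, p1 - 1L, scr, scc, rs, "stub")
        }
        add_seg(state_label[m], m, state_start[m], p1 - 1L, cr, cc, r, "main")
        evs[[length(evs) + 1L]] <- list(
          myofibril = m, sarcomere = i, z_position = child_z,
          type = "merge", classification = if (k == 2L) "single" else "multi",
          branch_count = k - 1L, parents = c(state_label[m], stubs),
          children = child)
        state_label[m] <- child
        state_start[m] <- child_z
      }
    }
  }
  # close final segments
  for (m in seq_len(n_total)) {
    if (exiting[m]) next
    add_seg(state_label[m], m, state_start[m], z_cap,
            centers[m, 1], centers[m, 2], radii[m], "main")
  }

  # --- stamp volume ----------------------------------------------------------
  labels <- array(0L, c(nz, nr, nc))
  plane_slices <- unlist(lapply(plane_start, function(p) p:(p + g - 1L)))
  is_plane <- rep(FALSE, nz); is_plane[plane_slices] <- TRUE

  stamp <- function(label, z1, z2, cr, cc, radius, skip_planes) {
    zs <- z1:z2
    if (skip_planes) zs <- zs[!is_plane[zs]]
    if (length(zs) == 0L) return(invisible())
    off <- disk_offsets(radius, radius)
    pr <- cr + off[, 1]; pc <- cc + off[, 2]
    ok <- pr >= 1L & pr <= nr & pc >= 1L & pc <= nc
    if (!any(ok)) return(invisible())
    flat <- (pr[ok] - 1L) * nz + (pc[ok] - 1L) * nz * nr
    idx <- rep(flat, each = length(zs)) + zs
    labels[idx] <<- label
    invisible()
  }

  ord_kind <- order(vapply(seg, function(s) s$kind == "stub", logical(1)))
  for (s in seg[ord_kind]) {
    stamp(s$label, s$z_first, s$z_last, s$cr, s$cc, s$radius,
          skip_planes = (s$kind == "main"))
  }
  # exiting myofibrils: per-block stamping with lateral drift
  for (m in which(exiting)) {
    r <- radii[m]; cc <- centers[m, 2]; cr <- centers[m, 1]
    # blocks: leading pad, sarcomeres 1..n, trailing pad (planes excluded);
    # the center jumps by drift_step at every plane crossed
    bstart <- c(1L, sarc_start, plane_start[n_sarc + 1L] + g)
    bend <- c(plane_start - 1L, z_cap)
    z_last_m <- NA_integer_
    for (b in seq_along(bstart)) {
      cc_b <- cc - (b - 1L) * drift_step[m]
      if (cc_b + r < 1L) break                    # fully outside
      stamp(m, bstart[b], min(bend[b], z_cap), cr, cc_b, r,
            skip_planes = FALSE)
      z_last_m <- min(bend[b], z_cap)
    }
    seg[[length(seg) + 1L]] <- list(label = m, myofibril = m, z_first = 1L,
                                    z_last = z_last_m, cr = cr, cc = cc,
                                    radius = r, kind = "main")
  }

  # --- companion masks -------------------------------------------------------
  rrange <- c(max(1L, min(centers[, 1]) - half - marg),
              min(nr, max(centers[, 1]) + half + marg))
  crange <- c(if (config$n_exiting > 0L) 1L else
                max(1L, min(centers[, 2]) - half - marg),
              min(nc, max(centers[, 2]) + half + marg))
  cell <- array(0L, c(nz, nr, nc))
  cell[, rrange[1]:rrange[2], crange[1]:crange[2]] <- 1L
  srt <- array(0L, c(nz, nr, nc))
  srt[plane_slices, rrange[1]:rrange[2], crange[1]:crange[2]] <- 1L

  # --- ground truth ----------------------------------------------------------
  seg_df <- do.call(rbind, lapply(seg, function(s)
    data.frame(label = s$label, myofibril = s$myofibril, z_first = s$z_first,
               z_last = s$z_last, kind = s$kind)))
  if (length(evs) > 0L) {
    ev_df <- data.frame(
      event_id = seq_along(evs),
      myofibril = vapply(evs, `[[`, integer(1), "myofibril"),
      sarcomere = vapply(evs, `[[`, integer(1), "sarcomere"),
      z_position = vapply(evs, function(e) as.integer(e$z_position),
                          integer(1)),
      type = vapply(evs, `[[`, character(1), "type"),
      classification = vapply(evs, `[[`, character(1), "classification"),
      branch_count = vapply(evs, function(e) as.integer(e$branch_count),
                            integer(1)))
    ev_df$parents <- lapply(evs, `[[`, "parents")
    ev_df$children <- lapply(evs, `[[`, "children")
  } else {
    ev_df <- data.frame(event_id = integer(), myofibril = integer(),
                        sarcomere = integer(), z_position = integer(),
                        type = character(), classification = character(),
                        branch_count = integer())
    ev_df$parents <- list(); ev_df$children <- list()
  }
  flags <- ev_type != ""
  per_myo <- data.frame(
    myofibril = seq_len(n_total),
    exiting = exiting,
    n_sarcomeres = n_sarc,
    n_events = as.integer(rowSums(ev_type != "")),
    branching_sarcomeres = as.integer(rowSums(flags)),
    total_branch_count = as.integer(rowSums((ev_k - 1L) * (ev_type != ""))))

  truth <- structure(list(segments = seg_df, events = ev_df, flags = flags,
                          per_myofibril = per_myo, n_sarcomeres = n_sarc,
                          plane_starts = plane_start, srt_gap = g,
                          sarcomere_voxels = L, max_gap = max_gap,
                          z_cap = z_cap, config = config),
                     class = "synthetic_ground_truth")

  structure(list(labels = labeled_volume(labels, config$voxel_size),
                 cell = mask_volume(cell, config$voxel_size, "cell"),
                 srt = mask_volume(srt, config$voxel_size, "srt"),
                 truth = truth),
            class = "synthetic_muscle")
}

#' @export
print.synthetic_muscle <- function(x, ...) {
  t <- x$truth
  cat("<synthetic_muscle> ", nrow(t$per_myofibril), " myofibrils x ",
      t$n_sarcomeres, " sarcomeres, ", nrow(t$events), " junction events (",
      sum(t$events$type == "split"), " splits / ",
      sum(t$events$type == "merge"), " merges)\n", sep = "")
  print(x$labels)
  invisible(x)
}
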