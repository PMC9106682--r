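#' Build the longitudinal segment graph of a labeled myofibril volume
#'
#' Scans the volume cross-section by cross-section (axis 1 = longitudinal)
#' and links segment labels across junctions: label `A` is a predecessor of
#' label `B` when `B`'s first occupied cross-section starts within `max_gap`
#' slices of `A`'s last occupied cross-section and their footprints overlap
#' by at least `min_overlap` voxels. A label with two or more successors
#' yields a split junction; a label with two or more predecessors yields a
#' merge. Junctions with exactly two resultant (or source) segments are
#' classified `single`, three or more `multi`; `branch_count` is that count
#' minus one. A one-to-one link is a continuation, not a junction.
#'
#' `max_gap` exists because thin sarcotubular (SRT) planes interrupt labels
#' at sarcomere boundaries; its default (4 slices) bridges an SRT gap of up
#' to 2 slices plus rounding. Gaps *within* one label are bridged by label
#' identity; an internal gap wider than `max_gap` is treated as label reuse
#' and raises a consistency error.
#'
#' @param labels a [labeled_volume()], reoriented so axis 1 is longitudinal.
#' @param min_overlap minimum footprint intersection (voxels) to link labels.
#' @param max_gap maximum number of empty slices bridged at a junction.
#' @return An object of class `segment_graph`: list with `nodes`
#'   (label, z_first, z_last, n_slices, voxel_count, touches_lateral),
#'   `events` (z_position, type, classification, branch_count, parents,
#'   children), `edges`, `centroids` (per label per slice), `censored_labels`,
#'   and the scan parameters.
#' @export
build_segment_graph <- function(labels, min_overlap = 1L, max_gap = 4L) {
  stopifnot(inherits(labels, "labeled_volume"))
  d <- labels$data
  nz <- dim(d)[1]; nr <- dim(d)[2]; nc <- dim(d)[3]
  if (!any(d > 0L)) stop("labels volume is empty", call. = FALSE)
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)

  acc <- new.env(parent = emptyenv())
  cent <- list(); ci <- 0L

  for (z in seq_len(nz)) {
    sl <- d[z, , ]
    idx <- which(sl > 0L)
    if (length(idx) == 0L) next
    labs <- sl[idx]
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    border <- rr == 1L | rr == nr | cc == 1L | cc == nc
    spl <- split(seq_along(idx), labs)
    for (key in names(spl)) {
      sel <- spl[[key]]
      a <- acc[[key]]
      if (is.null(a)) {
        a <- list(z_first = z, z_last = z, n = 0, touches = FALSE,
                  foot_first = idx[sel], foot_last = NULL, prev_z = z)
      } else {
        if (z - a$z_last - 1L > max_gap) {
          stop("label ", key, " re-appears after a gap of ",
               z - a$z_last - 1L, " slices (> max_gap = ", max_gap,
               "): label reuse or broken segment", call. = FALSE)
        }
        a$z_last <- z
      }
      a$z_last <- z
      a$n <- a$n + length(sel)
      a$touches <- a$touches || any(border[sel])
      a$foot_last <- idx[sel]
      acc[[key]] <- a
      ci <- ci + 1L
      cent[[ci]] <- c(as.integer(key), z, sum(rr[sel]), sum(cc[sel]),
                      length(sel))
    }
  }

  keys <- ls(acc)
  lab_ids <- as.integer(keys)
  o <- order(lab_ids)
  keys <- keys[o]; lab_ids <- lab_ids[o]
  nodes <- data.frame(
    label = lab_ids,
    z_first = vapply(keys, function(k) acc[[k]]$z_first, integer(1)),
    z_last = vapply(keys, function(k) acc[[k]]$z_last, integer(1)),
    voxel_count = vapply(keys, function(k) acc[[k]]$n, numeric(1)),
    touches_lateral = vapply(keys, function(k) acc[[k]]$touches, logical(1)),
    row.names = NULL)

  cm <- do.call(rbind, cent)
  centroids <- data.frame(label = cm[, 1], z = cm[, 2],
                          crow = cm[, 3] / cm[, 5],
                          ccol = cm[, 4] / cm[, 5], n = cm[, 5])
  centroids <- centroids[order(centroids$label, centroids$z), ]
  rownames(centroids) <- NULL

  # --- link ends to starts ---------------------------------------------------
  starts_by_z <- split(seq_len(nrow(nodes)), nodes$z_first)
  edges_from <- integer(); edges_to <- integer()
  for (i in seq_len(nrow(nodes))) {
    zl <- nodes$z_last[i]
    cand <- unlist(starts_by_z[as.character((zl + 1L):(zl + 1L + max_gap))],
                   use.names = FALSE)
    if (length(cand) == 0L) next
    fa <- acc[[as.character(nodes$label[i])]]$foot_last
    for (j in cand) {
      fb <- acc[[as.character(nodes$label[j])]]$foot_first
      if (sum(fb %in% fa) >= min_overlap) {
        edges_from <- c(edges_from, nodes$label[i])
        edges_to <- c(edges_to, nodes$label[j])
      }
    }
  }
  edges <- data.frame(from = edges_from, to = edges_to)

  # --- junction events -------------------------------------------------------
  evs <- list()
  if (nrow(edges) > 0L) {
    by_from <- split(edges$to, edges$from)
    by_to <- split(edges$from, edges$to)
    for (p in names(by_from)) {
      ch <- sort(by_from[[p]])
      if (length(ch) >= 2L) {
        zpos <- min(nodes$z_first[match(ch, nodes$label)])
        evs[[length(evs) + 1L]] <- list(
          z_position = zpos, type = "split",
          classification = if (length(ch) == 2L) "single" else "multi",
          branch_count = length(ch) - 1L,
          parents = as.integer(p), children = ch)
      }
    }
    for (ch in names(by_to)) {
      pa <- sort(by_to[[ch]])
      if (length(pa) >= 2L) {
        chl <- as.integer(ch)
        evs[[length(evs) + 1L]] <- list(
          z_position = nodes$z_first[match(chl, nodes$label)], type = "merge",
          classification = if (length(pa) == 2L) "single" else "multi",
          branch_count = length(pa) - 1L,
          parents = pa, children = chl)
      }
    }
  }
  events <- if (length(evs) > 0L) {
    df <- data.frame(
      event_id = seq_along(evs),
      z_position = vapply(evs, function(e) as.integer(e$z_position),
                          integer(1)),
      type = vapply(evs, `[[`, character(1), "type"),
      classification = vapply(evs, `[[`, character(1), "classification"),
      branch_count = vapply(evs, function(e) as.integer(e$branch_count),
                            integer(1)))
    df$parents <- lapply(evs, `[[`, "parents")
    df$children <- lapply(evs, `[[`, "children")
    df <- df[order(df$z_position, df$type), ]
    df$event_id <- seq_len(nrow(df))
    rownames(df) <- NULL
    df
  } else {
    df <- data.frame(event_id = integer(), z_position = integer(),
                     type = character(), classification = character(),
                     branch_count = integer())
    df$parents <- list(); df$children <- list()
    df
  }

  structure(list(nodes = nodes, events = events, edges = edges,
                 centroids = centroids,
                 censored_labels = nodes$label[nodes$touches_lateral],
                 dim = dim(d), voxel_size = labels$voxel_size,
                 min_overlap = min_overlap, max_gap = max_gap),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  cat("<segment_graph> ", nrow(x$nodes), " segments, ", nrow(x$events),
      " junction events (", sum(x$events$type == "split"), " splits / ",
      sum(x$events$type == "merge"), " merges), ",
      length(x$censored_labels), " labels touch the lateral boundary\n",
      sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# sarcomere counting along a centroid track
# ---------------------------------------------------------------------------

# SRT occupancy per slice of [z_first, z_last], sampled at the (interpolated)
# centroid position: returns logical vector over full_z
srt_profile <- function(zs, crow, ccol, srt_arr) {
  z1 <- min(zs); z2 <- max(zs)
  full_z <- z1:z2
  near <- findInterval(full_z, zs, all.inside = TRUE)
  # snap to nearest occupied slice (findInterval gives the left one)
  right <- pmin(near + 1L, length(zs))
  use_right <- abs(zs[right] - full_z) < abs(zs[near] - full_z)
  near[use_right] <- right[use_right]
  r <- as.integer(round(crow[near])); c <- as.integer(round(ccol[near]))
  dims <- dim(srt_arr)
  r <- pmin(pmax(r, 1L), dims[2]); c <- pmin(pmax(c, 1L), dims[3])
  srt_arr[cbind(full_z, r, c)] > 0L
}

# Partition [z_first, z_last] into sarcomere intervals given an SRT profile.
# Complete intervals (bounded by SRT runs on both sides) always count;
# terminal partial intervals count only when at least half the reference
# sarcomere length, so field-of-view edge pads are excluded.
sarcomere_intervals <- function(flag, z_offset, ref_len = NULL) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(z1 = starts[!r$values] + z_offset - 1L,
                   z2 = ends[!r$values] + z_offset - 1L)
  if (nrow(iv) == 0L) return(iv)
  n_runs <- sum(r$values)
  first_is_gap <- !r$values[1]
  last_is_gap <- !r$values[length(r$values)]
  iv$terminal <- FALSE
  if (first_is_gap) iv$terminal[1] <- TRUE
  if (last_is_gap) iv$terminal[nrow(iv)] <- TRUE
  # a lone interval flanked by runs on neither side is "terminal" on both
  len <- iv$z2 - iv$z1 + 1L
  complete_len <- len[!iv$terminal]
  if (is.null(ref_len)) {
    ref_len <- if (length(complete_len) > 0L) stats::median(complete_len)
               else Inf
  }
  iv$counted <- !iv$terminal | len >= 0.5 * ref_len
  iv
}

#' Count sarcomeres spanned by one segment
#'
#' With an SRT mask, a segment's sarcomere count is the number of
#' inter-SRT-plane intervals it spans along its centroid track; partial
#' terminal intervals shorter than half the local sarcomere length (e.g.
#' pads at the volume ends) are not counted. Without an SRT mask (fibrillar
#' muscle, where SRT content is ~1%), the count falls back to
#' `round(length / nominal_sarcomere_length)`, minimum 1.
#'
#' @param graph a [build_segment_graph()] result.
#' @param label segment label to count.
#' @param srt optional [mask_volume()] of the sarcotubular system.
#' @param nominal_sarcomere_length optional nominal length (nm).
#' @return integer sarcomere count (>= 1).
#' @export
count_sarcomeres <- function(graph, label, srt = NULL,
                             nominal_sarcomere_length = NULL) {
  stopifnot(inherits(graph, "segment_graph"))
  if (is.null(srt) && is.null(nominal_sarcomere_length)) {
    stop("provide an SRT mask or a nominal sarcomere length", call. = FALSE)
  }
  tr <- graph$centroids[graph$centroids$label == label, ]
  if (nrow(tr) == 0L) stop("label ", label, " not present in graph",
                           call. = FALSE)
  count_sarcomeres_track(tr, srt, nominal_sarcomere_length,
                         graph$voxel_size[1])$count
}

# shared by count_sarcomeres and track_myofibrils; returns count + intervals
count_sarcomeres_track <- function(tr, srt, nominal_nm, dz) {
  nominal_vox <- if (!is.null(nominal_nm)) nominal_nm / dz else NULL
  if (!is.null(srt)) {
    flag <- srt_profile(tr$z, tr$crow, tr$ccol, srt$data)
    if (any(flag)) {
      iv <- sarcomere_intervals(flag, min(tr$z), ref_len = NULL)
      return(list(count = max(1L, sum(iv$counted)), intervals = iv))
    }
  }
  span <- max(tr$z) - min(tr$z) + 1L
  cnt <- if (!is.null(nominal_vox)) max(1L, round(span / nominal_vox)) else 1L
  list(count = as.integer(cnt),
       intervals = data.frame(z1 = min(tr$z), z2 = max(tr$z),
                              terminal = FALSE, counted = TRUE))
}

# ---------------------------------------------------------------------------
# myofibril tracking
# ---------------------------------------------------------------------------

# mean boundary distance (nm) per segment, sampled along its centroid track
node_boundary_distances <- function(graph, boundary_distance) {
  cents <- graph$centroids
  dims <- graph$dim
  r <- pmin(pmax(as.integer(round(cents$crow)), 1L), dims[2])
  c <- pmin(pmax(as.integer(round(cents$ccol)), 1L), dims[3])
  d <- boundary_distance[cbind(cents$z, r, c)]
  vapply(split(d, cents$label), mean, numeric(1))[
    as.character(graph$nodes$label)]
}

#' Sarcolemma distances of junction events
#'
#' One distance per junction event: the mean boundary distance of the
#' event's (first) parent segment, i.e. the radial position of the myofibril
#' hosting the branch. Feed these, together with a reference sample of all
#' sarcomere positions (e.g. `rep(tracks$mean_boundary_distance,
#' tracks$sarcomeres)`), to [peripheral_bias_test()].
#'
#' @param graph a [build_segment_graph()] result.
#' @param boundary_distance distance array from [boundary_distance_map()].
#' @return numeric vector (nm), one entry per event in `graph$events`.
#' @export
branch_distances <- function(graph, boundary_distance) {
  stopifnot(inherits(graph, "segment_graph"))
  nd <- node_boundary_distances(graph, boundary_distance)
  vapply(graph$events$parents, function(p) nd[[as.character(p[1])]],
         numeric(1))
}

#' Track myofibrils through the segment graph
#'
#' One track is seeded per segment present in the first occupied
#' cross-section. Tracking proceeds down the longitudinal axis; at a split
#' the successor whose mean sarcolemma distance best matches the seed
#' segment's is followed (the structure that "keeps its place" in the cell;
#' ties break to the smaller label), and merges continue through the merged
#' segment. A track is censored when any of its segments touches the lateral
#' volume boundary or when it ends more than `max_gap` slices before the
#' last occupied cross-section (it left the field of view); censored tracks
#' are excluded from per-track statistics.
#'
#' @param graph a [build_segment_graph()] result.
#' @param boundary_distance 3D array of distances to the cell boundary in nm,
#'   from [boundary_distance_map()].
#' @param srt optional SRT [mask_volume()] used to count sarcomeres.
#' @param nominal_sarcomere_length fallback sarcomere length (nm) when no
#'   SRT mask is given.
#' @return A data.frame of class `myofibril_tracks`: one row per track with
#'   `seed_label`, `censored`, `sarcomeres`, `branching_sarcomeres`,
#'   `branching_single`, `branching_multi`, `n_events`, `total_branch_count`,
#'   `mean_boundary_distance`, and list-columns `path` and `event_ids`.
#' @export
track_myofibrils <- function(graph, boundary_distance, srt = NULL,
                             nominal_sarcomere_length = NULL) {
  stopifnot(inherits(graph, "segment_graph"))
  if (is.null(boundary_distance)) {
    stop("boundary_distance map is required for tracking", call. = FALSE)
  }
  if (!is.array(boundary_distance) ||
      !identical(dim(boundary_distance), as.integer(graph$dim))) {
    stop("boundary_distance must be an array matching the labels volume",
         call. = FALSE)
  }
  nodes <- graph$nodes
  cents <- graph$centroids
  node_dist <- node_boundary_distances(graph, boundary_distance)

  succ <- split(graph$edges$to, graph$edges$from)
  pred_n <- table(graph$edges$to)
  # map (parent) -> split event id, (child) -> merge event id
  ev <- graph$events
  split_of <- list(); merge_of <- list()
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "split") {
      split_of[[as.character(ev$parents[[i]][1])]] <- i
    } else {
      merge_of[[as.character(ev$children[[i]][1])]] <- i
    }
  }

  z_min <- min(nodes$z_first)
  z_max <- max(nodes$z_last)
  seeds <- nodes$label[nodes$z_first == z_min]
  tracks <- vector("list", length(seeds))
  paths <- vector("list", length(seeds))
  evl <- vector("list", length(seeds))

  for (s in seq_along(seeds)) {
    seed <- seeds[s]
    seed_dist <- node_dist[[as.character(seed)]]
    path <- integer(); event_ids <- integer()
    cur <- seed
    repeat {
      path <- c(path, cur)
      if (length(path) > nrow(nodes)) stop("cycle detected in segment graph",
                                           call. = FALSE)
      nxt <- succ[[as.character(cur)]]
      if (is.null(nxt) || length(nxt) == 0L) break
      if (length(nxt) >= 2L) {             # split: follow the seed's depth
        ei <- split_of[[as.character(cur)]]
        if (!is.null(ei)) event_ids <- c(event_ids, ei)
        dd <- abs(node_dist[as.character(nxt)] - seed_dist)
        # centroid-sampled distances are only meaningful at voxel
        # resolution: differences below one in-plane voxel are ties,
        # resolved to the smaller label
        tol <- max(graph$voxel_size[2:3])
        cand <- nxt[dd <= min(dd) + tol]
        cur <- min(cand)
      } else {
        ei <- merge_of[[as.character(nxt)]]
        if (!is.null(ei)) event_ids <- c(event_ids, ei)
        cur <- nxt
      }
    }
    prow <- match(path, nodes$label)
    touches <- any(nodes$touches_lateral[prow])
    ends_early <- nodes$z_last[prow[length(prow)]] < z_max - graph$max_gap
    tr <- cents[cents$label %in% path, ]
    tr <- tr[order(tr$z), ]
    sc <- count_sarcomeres_track(tr, srt, nominal_sarcomere_length,
                                 graph$voxel_size[1])
    # attribute each event to the counted sarcomere interval upstream of it
    br_iv <- integer(); br_single <- integer(); br_multi <- integer()
    tbc <- 0L
    if (length(event_ids) > 0L) {
      iv <- sc$intervals[sc$intervals$counted, , drop = FALSE]
      for (ei in event_ids) {
        ze <- ev$z_position[ei]
        up <- which(iv$z2 < ze)
        tbc <- tbc + ev$branch_count[ei]
        if (nrow(iv) == 0L) next
        # upstream attribution; an event before the first counted sarcomere
        # belongs to that sarcomere's boundary
        k <- if (length(up) == 0L) 1L else up[length(up)]
        br_iv <- c(br_iv, k)
        if (ev$classification[ei] == "single") br_single <- c(br_single, k)
        else br_multi <- c(br_multi, k)
      }
    }
    tracks[[s]] <- data.frame(
      seed_label = seed,
      censored = touches || ends_early,
      sarcomeres = sc$count,
      branching_sarcomeres = length(unique(br_iv)),
      branching_single = length(unique(br_single)),
      branching_multi = length(unique(br_multi)),
      n_events = length(event_ids),
      total_branch_count = tbc,
      mean_boundary_distance = seed_dist)
    paths[[s]] <- path
    evl[[s]] <- event_ids
  }
  out <- do.call(rbind, tracks)
  out$path <- paths
  out$event_ids <- evl
  class(out) <- c("myofibril_tracks", class(out))
  out
}

#' Per-cell branching statistics from tracked myofibrils
#'
#' Computed over uncensored tracks only (sarcomeres that leave the field of
#' view are excluded). Splits and merges both count as branching. A
#' sarcomere is branching when at least one junction event occurs at one of
#' its boundaries (events are attributed to the sarcomere immediately
#' upstream of the junction plane); a sarcomere hosting two events counts
#' once toward the branching percentage but contributes both branch counts
#' to the branch frequency.
#'
#' @param tracks a [track_myofibrils()] result.
#' @return list of class `branching_stats`:
#'   `pct_myofibrils_branched` (% of myofibrils with >= 1 branching
#'   sarcomere), `pct_sarcomeres_branched` (mean over tracks of the per-track
#'   percentage), `pct_single`, `pct_multi` (% of sarcomeres with single /
#'   multi events, pooled), `branches_per_10` (branches per 10 sarcomere
#'   lengths, pooled), plus counts.
#' @export
branching_statistics <- function(tracks) {
  stopifnot(inherits(tracks, "myofibril_tracks"))
  t <- tracks[!tracks$censored, , drop = FALSE]
  if (nrow(t) == 0L) {
    stop("no uncensored tracks: nothing to summarize", call. = FALSE)
  }
  per_track_pct <- 100 * t$branching_sarcomeres / t$sarcomeres
  res <- list(
    n_myofibrils = nrow(t),
    n_censored = sum(tracks$censored),
    n_sarcomeres = sum(t$sarcomeres),
    pct_myofibrils_branched = 100 * mean(t$n_events >= 1L),
    pct_sarcomeres_branched = mean(per_track_pct),
    per_track_pct_branched = per_track_pct,
    pct_single = 100 * sum(t$branching_single) / sum(t$sarcomeres),
    pct_multi = 100 * sum(t$branching_multi) / sum(t$sarcomeres),
    branches_per_10 = 10 * sum(t$total_branch_count) / sum(t$sarcomeres))
  class(res) <- "branching_stats"
  res
}

#' @export
print.branching_stats <- function(x, ...) {
  cat("<branching_stats> ", x$n_myofibrils, " myofibrils (",
      x$n_censored, " censored), ", x$n_sarcomeres, " sarcomeres\n",
      "  myofibrils with >= 1 branching sarcomere: ",
      sprintf("%.1f%%", x$pct_myofibrils_branched), "\n",
      "  branching sarcomeres (mean of per-myofibril %): ",
      sprintf("%.1f%%", x$pct_sarcomeres_branched), "\n",
      "  single / multi: ", sprintf("%.1f%% / %.1f%%", x$pct_single,
                                    x$pct_multi), "\n",
      "  branches per 10 sarcomere lengths: ",
      sprintf("%.2f", x$branches_per_10), "\n", sep = "")
  invisible(x)
}
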