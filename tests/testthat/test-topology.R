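test_that("a straight cylinder gives one node and no events", {
  arr <- array(0L, c(20, 9, 9))
  arr <- stamp_disk(arr, 1:20, 5, 5, 3, 1L)
  g <- build_segment_graph(labeled_volume(arr, c(20, 20, 20)))
  expect_identical(nrow(g$nodes), 1L)
  expect_identical(nrow(g$events), 0L)
  expect_identical(g$nodes$z_first, 1L)
  expect_identical(g$nodes$z_last, 20L)
  expect_error(build_segment_graph(labeled_volume(array(0L, c(4, 4, 4)))),
               "empty")
})

test_that("hand-coded junctions are detected and classified", {
  # Y: 1 -> {2, 3}: single split
  arr <- array(0L, c(20, 11, 11))
  arr <- stamp_disk(arr, 1:10, 6, 6, 3, 1L)
  arr <- stamp_disk(arr, 11:20, 5, 5, 2, 2L)
  arr <- stamp_disk(arr, 11:20, 8, 8, 2, 3L)
  g <- build_segment_graph(labeled_volume(arr, c(20, 20, 20)))
  expect_identical(nrow(g$events), 1L)
  ev <- g$events
  expect_identical(ev$type, "split")
  expect_identical(ev$classification, "single")
  expect_identical(ev$branch_count, 1L)
  expect_identical(ev$parents[[1]], 1L)
  expect_identical(sort(ev$children[[1]]), c(2L, 3L))
  expect_identical(ev$z_position, 11L)

  # 1 -> {2, 3, 4}: multi split, branch_count 2
  arr <- array(0L, c(20, 13, 13))
  arr <- stamp_disk(arr, 1:10, 7, 7, 4, 1L)
  arr <- stamp_disk(arr, 11:20, 4, 7, 2, 2L)
  arr <- stamp_disk(arr, 11:20, 9, 4, 2, 3L)
  arr <- stamp_disk(arr, 11:20, 9, 10, 2, 4L)
  g <- build_segment_graph(labeled_volume(arr, c(20, 20, 20)))
  expect_identical(nrow(g$events), 1L)
  expect_identical(g$events$type, "split")
  expect_identical(g$events$classification, "multi")
  expect_identical(g$events$branch_count, 2L)

  # reversed along z the same volume is a multi merge
  rev <- arr[20:1, , ]
  g2 <- build_segment_graph(labeled_volume(rev, c(20, 20, 20)))
  expect_identical(g2$events$type, "merge")
  expect_identical(g2$events$branch_count, 2L)
})

test_that("label reuse across a long gap raises a consistency error", {
  arr <- array(0L, c(30, 9, 9))
  arr <- stamp_disk(arr, 1:5, 5, 5, 2, 1L)
  arr <- stamp_disk(arr, 20:25, 5, 5, 2, 1L)
  expect_error(build_segment_graph(labeled_volume(arr, c(20, 20, 20))),
               "label reuse")
})

test_that("count_sarcomeres counts SRT crossings and nominal fallback", {
  # 4 SRT planes -> 5 sarcomeres (full terminal sarcomeres count)
  arr <- array(0L, c(54, 9, 9))
  srt <- array(0L, c(54, 9, 9))
  planes <- c(11L, 22L, 33L, 44L)
  occ <- setdiff(1:54, planes)
  arr <- stamp_disk(arr, occ, 5, 5, 3, 1L)
  srt[planes, , ] <- 1L
  g <- build_segment_graph(labeled_volume(arr, c(20, 20, 20)))
  expect_identical(count_sarcomeres(g, 1L,
                                    srt = mask_volume(srt, c(20, 20, 20))),
                   5L)
  # no internal SRT -> 1 sarcomere
  arr1 <- stamp_disk(array(0L, c(10, 9, 9)), 1:10, 5, 5, 3, 1L)
  g1 <- build_segment_graph(labeled_volume(arr1, c(20, 20, 20)))
  empty_srt <- mask_volume(array(0L, c(10, 9, 9)), c(20, 20, 20))
  expect_identical(count_sarcomeres(g1, 1L, srt = empty_srt), 1L)
  # 32 um at nominal 3.2 um -> 10 sarcomeres
  arr2 <- stamp_disk(array(0L, c(1600, 5, 5)), 1:1600, 3, 3, 2, 1L)
  g2 <- build_segment_graph(labeled_volume(arr2, c(20, 20, 20)))
  expect_identical(count_sarcomeres(g2, 1L,
                                    nominal_sarcomere_length = 3200), 10L)
  expect_error(count_sarcomeres(g2, 1L), "SRT mask or a nominal")
})

test_that("tracking follows the boundary-distance arg-min at splits", {
  arr <- array(0L, c(30, 15, 30))
  arr <- stamp_disk(arr, 1:14, 8, 10, 3, 1L)
  arr <- stamp_disk(arr, 15:30, 8, 5, 2, 2L)    # distance 500 nm
  arr <- stamp_disk(arr, 15:30, 8, 12, 2, 3L)   # distance 1200 nm
  g <- build_segment_graph(labeled_volume(arr, c(20, 20, 20)))
  dmap <- array(0, c(30, 15, 30))
  dmap[, , 5] <- 500; dmap[, , 10] <- 600; dmap[, , 12] <- 1200
  tr <- track_myofibrils(g, dmap, nominal_sarcomere_length = 3200)
  expect_identical(nrow(tr), 1L)
  # seed at 600 nm: child at 500 is closer than child at 1200
  expect_identical(tr$path[[1]], c(1L, 2L))
  expect_false(tr$censored[1])
  expect_identical(tr$n_events[1], 1L)
})

test_that("tracks without events pass through uncensored", {
  sim <- generate_muscle_volume(small_config(seed = 11))
  g <- build_segment_graph(sim$labels, max_gap = sim$truth$max_gap)
  tr <- track_myofibrils(g, boundary_distance_map(sim$cell), srt = sim$srt)
  expect_identical(nrow(tr), 9L)
  expect_false(any(tr$censored))
  expect_true(all(tr$n_events == 0L))
  expect_true(all(tr$sarcomeres == sim$truth$n_sarcomeres))
  expect_true(all(lengths(tr$path) == 1L))
})

test_that("exiting myofibrils are censored and excluded from statistics", {
  cfg <- small_config(n_myofibrils = 8L, n_exiting = 1L,
                      p_single = 0.2, p_multi = 0.1, seed = 12)
  sim <- generate_muscle_volume(cfg)
  g <- build_segment_graph(sim$labels, max_gap = sim$truth$max_gap)
  tr <- track_myofibrils(g, boundary_distance_map(sim$cell), srt = sim$srt)
  expect_identical(nrow(tr), 9L)
  expect_identical(sum(tr$censored), 1L)
  bs <- branching_statistics(tr)
  expect_identical(bs$n_myofibrils, 8L)
  expect_identical(bs$n_censored, 1L)
})

test_that("branching_statistics matches the hand-enumerated example", {
  # 5 tracks x 10 sarcomeres; track 1 one single event, track 2 one multi
  # (1 -> 3): 40% myofibrils branched, 4% sarcomeres, 0.6 branches per 10
  mk <- data.frame(
    seed_label = 1:5, censored = FALSE, sarcomeres = 10L,
    branching_sarcomeres = c(1L, 1L, 0L, 0L, 0L),
    branching_single = c(1L, 0L, 0L, 0L, 0L),
    branching_multi = c(0L, 1L, 0L, 0L, 0L),
    n_events = c(1L, 1L, 0L, 0L, 0L),
    total_branch_count = c(1L, 2L, 0L, 0L, 0L),
    mean_boundary_distance = 0)
  class(mk) <- c("myofibril_tracks", "data.frame")
  bs <- branching_statistics(mk)
  expect_equal(bs$pct_myofibrils_branched, 40)
  expect_equal(bs$pct_sarcomeres_branched, 4)
  expect_equal(bs$branches_per_10, 0.6)
  expect_equal(bs$pct_single, 2)   # 1 single-branching sarcomere / 50
  expect_equal(bs$pct_multi, 2)    # 1 multi-branching sarcomere / 50
  # zero-event input
  mk0 <- mk; mk0[, 4:8] <- 0L
  class(mk0) <- c("myofibril_tracks", "data.frame")
  bs0 <- branching_statistics(mk0)
  expect_equal(bs0$pct_myofibrils_branched, 0)
  expect_equal(bs0$branches_per_10, 0)
  # all-censored input errors
  mkc <- mk; mkc$censored <- TRUE
  class(mkc) <- c("myofibril_tracks", "data.frame")
  expect_error(branching_statistics(mkc), "uncensored")
})

test_that("split/merge duality and conservation hold on generated volumes", {
  cfg <- small_config(p_single = 0.15, p_multi = 0.1, seed = 13)
  sim <- generate_muscle_volume(cfg)
  g <- build_segment_graph(sim$labels, max_gap = sim$truth$max_gap)
  # conservation: sum branch_count == sum(max(|parents|,|children|) - 1)
  mx <- pmax(lengths(g$events$parents), lengths(g$events$children))
  expect_identical(sum(g$events$branch_count), sum(mx - 1L))
  # reversing the longitudinal axis maps splits to merges with identical
  # branch counts
  rl <- labeled_volume(sim$labels$data[dim(sim$labels$data)[1]:1, , ],
                       sim$labels$voxel_size)
  rs <- mask_volume(sim$srt$data[dim(sim$srt$data)[1]:1, , ],
                    sim$srt$voxel_size, "srt")
  rc <- mask_volume(sim$cell$data[dim(sim$cell$data)[1]:1, , ],
                    sim$cell$voxel_size, "cell")
  g2 <- build_segment_graph(rl, max_gap = sim$truth$max_gap)
  expect_identical(sum(g$events$type == "split"),
                   sum(g2$events$type == "merge"))
  expect_identical(sum(g$events$type == "merge"),
                   sum(g2$events$type == "split"))
  expect_identical(sort(g$events$branch_count), sort(g2$events$branch_count))
  # branching statistics are invariant under the reversal
  b1 <- branching_statistics(track_myofibrils(
    g, boundary_distance_map(sim$cell), srt = sim$srt))
  b2 <- branching_statistics(track_myofibrils(
    g2, boundary_distance_map(rc), srt = rs))
  expect_equal(b1$branches_per_10, b2$branches_per_10)
  expect_equal(b1$pct_myofibrils_branched, b2$pct_myofibrils_branched)
  expect_equal(b1$pct_sarcomeres_branched, b2$pct_sarcomeres_branched)
  # pooled identities: single + multi == branched (<= 1 event/sarcomere)
  t <- b1
  pooled_pct <- 100 * sum(
    track_myofibrils(g, boundary_distance_map(sim$cell),
                     srt = sim$srt)$branching_sarcomeres) / t$n_sarcomeres
  expect_equal(t$pct_single + t$pct_multi, pooled_pct)
  expect_gte(t$branches_per_10, pooled_pct / 10)
})
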