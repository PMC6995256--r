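# build a stat_map directly from a t array (unit fixture, no GLM needed)
fake_map <- function(values, df = 100, voxel_mm = 3, center = c(0, 0, 0)) {
  d <- dim(values)
  structure(list(values = values, effect = values,
                 affine = grid_affine(d, voxel_mm, center), df = df,
                 contrast_name = "fake",
                 zero_variance = array(FALSE, dim = d)),
            class = "stat_map")
}

test_that("height thresholds follow the analytic formulas", {
  d <- c(10, 10, 10)
  set.seed(1)
  map <- fake_map(array(rnorm(1000), dim = d), df = 40)
  mask <- array(TRUE, dim = d)

  vt <- voxel_threshold(map, threshold_spec("fwe_05"), mask)
  expect_equal(vt$threshold, qt(1 - 0.05 / 1000, 40))  # alpha / N per voxel
  expect_equal(vt$n_search, 1000)

  vt001 <- voxel_threshold(map, threshold_spec("unc_001"), mask)
  expect_equal(vt001$threshold, qt(0.999, 40))

  # monotonicity: scaling the map up grows the surviving set
  vt05 <- voxel_threshold(map, threshold_spec("unc_05"), mask)
  map2 <- map; map2$values <- 2 * map$values
  vt05b <- voxel_threshold(map2, threshold_spec("unc_05"), mask)
  expect_true(all(vt05$mask[vt05$mask] <= vt05b$mask[vt05$mask]))
  expect_true(all(which(vt05$mask) %in% which(vt05b$mask)))

  expect_error(voxel_threshold(map, threshold_spec("fwe_05"),
                               array(FALSE, dim = d)), "empty")
  expect_error(voxel_threshold(map, threshold_spec("fwe_05",
                                                   fwe_method = "permutation_maxT"),
                               mask), "maxt_null")
})

test_that("null maps survive the uncorrected threshold at the nominal rate", {
  set.seed(2)
  d <- c(12, 12, 12)
  fracs <- replicate(40, {
    map <- fake_map(array(rt(prod(d), df = 60), dim = d), df = 60)
    sum(voxel_threshold(map, threshold_spec("unc_05"),
                        array(TRUE, dim = d))$mask) / prod(d)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.01)
})

test_that("max-T permutation thresholds behave sensibly", {
  set.seed(3)
  con <- matrix(rnorm(12 * 200), 12, 200)
  null_dist <- maxt_threshold(con, n_perm = 300, seed = 4L)
  expect_length(null_dist, 300)
  thr <- quantile(null_dist, 0.95)
  expect_gt(thr, qt(0.95, 11))  # max over voxels exceeds a single-voxel t
  map <- fake_map(array(c(rep(0, 990), rep(thr + 5, 10)), dim = c(10, 10, 10)),
                  df = 11)
  vt <- voxel_threshold(map, threshold_spec("fwe_05",
                                            fwe_method = "permutation_maxT"),
                        array(TRUE, dim = c(10, 10, 10)),
                        maxt_null = null_dist)
  expect_equal(sum(vt$mask), 10)
})

test_that("cluster extent filtering matches an independent labeling oracle", {
  # deterministic case: 9-voxel and 12-voxel clusters, extent 10
  b <- array(FALSE, dim = c(10, 10, 10))
  b[1:9, 1, 1] <- TRUE                       # size 9, a line
  b[1:4, 5:7, 5] <- TRUE                     # size 12 block
  cf <- cluster_filter(b, extent_min = 10)
  expect_equal(unname(cf$sizes), 12L)
  expect_equal(sum(cf$mask), 12)
  expect_false(any(cf$mask[1:9, 1, 1]))

  cf0 <- cluster_filter(b, extent_min = 0)
  expect_equal(cf0$mask, b)
  expect_equal(sort(unname(cf0$sizes)), c(9L, 12L))

  skip_if_not_installed("igraph")
  igraph_sizes <- function(bin, conn) {
    idx <- which(bin)
    if (!length(idx)) return(integer(0))
    d <- dim(bin)
    offs <- dynbodyloc:::connectivity_offsets(conn)
    pos <- dynbodyloc:::linear_to_ijk(idx, d)
    key <- match(idx, idx)
    edges <- NULL
    for (r in seq_len(nrow(offs))) {
      nb <- sweep(pos, 2, as.numeric(offs[r, ]), `+`)
      ok <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
            nb[, 3] >= 0 & nb[, 3] < d[3]
      nb_lin <- dynbodyloc:::ijk_to_linear(nb[ok, , drop = FALSE], d)
      hit <- match(nb_lin, idx)
      keep <- !is.na(hit)
      edges <- rbind(edges, cbind(which(ok)[keep], hit[keep]))
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    sort(as.integer(igraph::components(g)$csize))
  }
  set.seed(5)
  for (conn in c(6, 26)) {
    bin <- array(runif(1000) < 0.2, dim = c(10, 10, 10))
    cf <- cluster_filter(bin, extent_min = 0, connectivity = conn)
    expect_equal(sort(unname(cf$sizes)), igraph_sizes(bin, conn))
  }
})

test_that("ROI peaks are found inside the seed sphere with argmax ties", {
  d <- c(21, 21, 21)
  vals <- array(0, dim = d)
  map <- fake_map(vals, df = 50)
  seed <- list(name = "ctr", x = 0, y = 0, z = 0, radius_mm = 10)

  # empty sphere -> absent, not an error
  surv <- array(FALSE, dim = d)
  pk <- find_roi_peak(map, seed, surv)
  expect_false(pk$present)
  expect_equal(pk$n_voxels, 0L)

  # two survivors: peak is the larger t
  v1 <- dynbodyloc:::mm_to_voxel(c(0, 0, 0), map$affine) + 1
  v2 <- dynbodyloc:::mm_to_voxel(c(3, 0, 0), map$affine) + 1
  map$values[v1[1], v1[2], v1[3]] <- 5
  map$values[v2[1], v2[2], v2[3]] <- 7
  surv[v1[1], v1[2], v1[3]] <- TRUE
  surv[v2[1], v2[2], v2[3]] <- TRUE
  pk <- find_roi_peak(map, seed, surv)
  expect_true(pk$present)
  expect_equal(pk$n_voxels, 2L)
  expect_equal(pk$peak_t, 7)
  expect_equal(unname(pk$peak_xyz), c(3, 0, 0))

  # a survivor just outside the 10-mm sphere is not counted
  v3 <- dynbodyloc:::mm_to_voxel(c(12, 0, 0), map$affine) + 1
  map$values[v3[1], v3[2], v3[3]] <- 9
  surv[v3[1], v3[2], v3[3]] <- TRUE
  expect_equal(find_roi_peak(map, seed, surv)$peak_t, 7)

  expect_error(find_roi_peak(map, list(name = "far", x = 500, y = 0, z = 0,
                                       radius_mm = 10), surv),
               "outside the grid")
})

test_that("surviving sets are nested across the three thresholds", {
  set.seed(6)
  d <- c(12, 12, 12)
  mask <- array(TRUE, dim = d)
  for (i in 1:5) {
    vals <- array(rt(prod(d), df = 80), dim = d)
    vals[1:3, 1:3, 1:3] <- vals[1:3, 1:3, 1:3] + 6   # a real cluster
    map <- fake_map(vals, df = 80)
    m_fwe <- voxel_threshold(map, threshold_spec("fwe_05"), mask)$mask
    m_001 <- voxel_threshold(map, threshold_spec("unc_001"), mask)$mask
    m_05 <- voxel_threshold(map, threshold_spec("unc_05"), mask)$mask
    expect_true(all(!m_fwe | m_001))
    expect_true(all(!m_001 | m_05))
  }
})

test_that("subject tallies count presence with monotone thresholds", {
  d <- c(15, 15, 15)
  seeds <- data.frame(name = "ctr", x = 0, y = 0, z = 0, radius_mm = 10)
  specs <- list(threshold_spec("fwe_05"), threshold_spec("unc_001"),
                threshold_spec("unc_05"))
  make_subject_map <- function(has_effect, seed) {
    set.seed(seed)
    vals <- array(rt(prod(d), df = 100), dim = d)
    if (has_effect) {
      ctr <- dynbodyloc:::voxels_in_sphere(c(0, 0, 0), 6, d,
                                           grid_affine(d, 3))
      vals[dynbodyloc:::ijk_to_linear(ctr, d)] <- 12
    }
    fake_map(vals, df = 100)
  }
  # cohort of 10, effect planted in 8
  reports <- lapply(1:10, function(s) {
    roi_report(make_subject_map(s <= 8, 100 + s), seeds, specs)
  })
  tally <- subject_tally(reports)
  t001 <- tally[tally$threshold == "unc_001", ]
  expect_equal(t001$n_present, 8)
  expect_equal(t001$frac_present, 0.8)
  # nested thresholds give monotone counts
  n_by <- setNames(tally$n_present, tally$threshold)
  expect_lte(n_by["fwe_05"], n_by["unc_001"])
  expect_lte(n_by["unc_001"], n_by["unc_05"])

  # single subject present everywhere -> all counts 1
  one <- subject_tally(reports[1])
  expect_true(all(one$n_present == 1))
  expect_equal(one$mean_x[one$threshold == "unc_001"],
               reports[[1]]$peak_x[reports[[1]]$threshold == "unc_001"])
})

test_that("reference-coordinate distances are Euclidean and symmetric", {
  est <- default_roi_seeds()[, c("name", "x", "y", "z")]
  expect_equal(compare_to_reference(est, est)$distance_mm, rep(0, 7))

  a <- data.frame(name = "rFBA", x = 42, y = -44, z = -19)
  b <- data.frame(name = "rFBA", x = 42, y = -44, z = -24)
  expect_equal(compare_to_reference(a, b)$distance_mm, 5)
  expect_equal(compare_to_reference(b, a)$distance_mm,
               compare_to_reference(a, b)$distance_mm)
  expect_error(compare_to_reference(data.frame(name = "xyz", x = 0, y = 0,
                                               z = 0), b), "missing")
})
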