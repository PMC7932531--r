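test_that("cell classification reproduces the t-test decision rules", {
  cfg <- rroi_config()  # not_significantly_below, 200 kPa, alpha 0.05

  # mean at/above threshold is always retained
  expect_true(classify_cells(250, 40, 24, cfg))
  # t = (170-200)/(30/sqrt(24)) = -4.899 < -t_crit(0.95, 23) = -1.714: excluded
  expect_false(classify_cells(170, 30, 24, cfg))
  expect_equal((170 - 200) / (30 / sqrt(24)), -4.89898, tolerance = 1e-5)
  # but within one critical SD it is retained by the dispersion-band rule
  expect_true(classify_cells(170, 30, 24, rroi_config(rule = "dispersion_band")))
  expect_true(30 <= qt(0.95, 23) * 30)
  # an unloaded cell is never at risk
  for (rule in c("not_significantly_below", "significantly_above",
                 "direct_threshold", "dispersion_band")) {
    expect_false(classify_cells(0, 0, 24, rroi_config(rule = rule)))
  }

  # significantly_above needs t > +t_crit
  cfg_above <- rroi_config(rule = "significantly_above")
  expect_true(classify_cells(230, 50, 24, cfg_above))   # t = 2.94
  expect_false(classify_cells(210, 50, 24, cfg_above))  # t = 0.98
  # zero-variance cells decided by direct comparison
  expect_true(classify_cells(200, 0, 24, cfg_above))
  expect_false(classify_cells(199.9, 0, 24, cfg))

  expect_error(classify_cells(100, 10, 1, cfg), "n >= 2",
               class = "qsf_rroi_error")
  expect_true(classify_cells(200, 10, 1, rroi_config(rule = "direct_threshold")))
})

test_that("direct-threshold masks are subsets of the default-rule masks", {
  set.seed(99)
  cfg_d <- rroi_config(rule = "direct_threshold")
  cfg_n <- rroi_config()
  for (i in 1:200) {
    mean <- matrix(runif(30, 0, 400), 5, 6)
    sd <- matrix(runif(30, 0, 80), 5, 6)
    m_direct <- classify_cells(mean, sd, 24, cfg_d)
    m_default <- classify_cells(mean, sd, 24, cfg_n)
    expect_true(all(m_default[m_direct]))
  }
})

test_that("masks are monotone in alpha and threshold", {
  set.seed(7)
  mean <- matrix(runif(40, 100, 300), 5, 8)
  sd <- matrix(runif(40, 1, 60), 5, 8)
  m_05 <- classify_cells(mean, sd, 24, rroi_config(alpha = 0.05))
  m_01 <- classify_cells(mean, sd, 24, rroi_config(alpha = 0.01))
  expect_true(all(m_01[m_05]))  # smaller alpha never shrinks the default mask
  for (rule in c("not_significantly_below", "significantly_above",
                 "direct_threshold", "dispersion_band")) {
    lo <- classify_cells(mean, sd, 24, rroi_config(threshold_kpa = 180, rule = rule))
    hi <- classify_cells(mean, sd, 24, rroi_config(threshold_kpa = 260, rule = rule))
    expect_true(all(lo[hi]))    # higher threshold never grows the mask
  }
})

test_that("build_rroi labels clusters and computes areas", {
  z <- matrix(0, 6, 6)
  expect_equal(build_rroi(mppm_from_matrices(z, z, 24))$total_area_cm2, 0)

  # 82 risk cells at 5 mm -> 20.5 cm^2
  mean <- matrix(0, 10, 10); mean[1:82] <- 300
  r <- build_rroi(mppm_from_matrices(mean, mean * 0 + 10, 24))
  expect_equal(sum(r$in_rroi), 82L)
  expect_equal(r$total_area_cm2, 20.5)

  # diagonal-touching blobs merge under 8-connectivity, split under 4
  mean2 <- matrix(0, 4, 4)
  mean2[1, 1] <- 300; mean2[2, 2] <- 300; mean2[2, 3] <- 300
  mp <- mppm_from_matrices(mean2, mean2 * 0, 24)
  expect_equal(build_rroi(mp, rroi_config(connectivity = 8))$n_clusters, 1L)
  expect_equal(build_rroi(mp, rroi_config(connectivity = 4))$n_clusters, 2L)
})

test_that("cluster labelling agrees with igraph connected components", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (conn in c(4, 8)) {
    for (i in 1:20) {
      mask <- matrix(runif(100) < 0.35, 10, 10)
      lab <- qsfoot:::label_components(mask, conn)
      # oracle: graph of adjacent TRUE cells
      idx <- which(mask, arr.ind = TRUE)
      if (nrow(idx) == 0) { expect_equal(max(lab), 0L); next }
      id <- seq_len(nrow(idx))
      edges <- c()
      for (a in id) for (b in id) {
        if (a < b) {
          dr <- abs(idx[a, 1] - idx[b, 1]); dc <- abs(idx[a, 2] - idx[b, 2])
          touch <- if (conn == 8) max(dr, dc) == 1 else dr + dc == 1
          if (touch) edges <- c(edges, a, b)
        }
      }
      gr <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
      if (length(edges)) gr <- igraph::add_edges(gr, edges)
      comp <- igraph::components(gr)
      expect_equal(max(lab), comp$no)
      # same partition: labels constant on each oracle component
      got <- lab[idx]
      expect_true(all(tapply(got, comp$membership,
                             function(v) length(unique(v))) == 1))
    }
  }
})

test_that("total area is additive over clusters", {
  set.seed(10)
  mean <- matrix(ifelse(runif(64) < 0.3, 300, 0), 8, 8)
  r <- build_rroi(mppm_from_matrices(mean, mean * 0, 24))
  expect_equal(r$total_area_cm2, sum(mean > 0) * 0.25)
  per_cluster <- tapply(rep(0.25, sum(r$in_rroi)),
                        r$cluster_labels[r$in_rroi], sum)
  if (r$n_clusters > 0) expect_equal(sum(per_cluster), r$total_area_cm2)
})

test_that("redistribution maps flag exactly the altered cells", {
  set.seed(5)
  base <- replicate(24, matrix(runif(16, 150, 350), 4, 4), simplify = FALSE)
  peaks_ref <- lapply(seq_along(base), function(i) peak_from_matrix(base[[i]], i))
  rroi_ref <- build_rroi(mean_peak_map(peaks_ref))

  # identical conditions: nothing significant
  rd_same <- redistribution_map(peaks_ref, peaks_ref, rroi_ref)
  expect_equal(sum(rd_same$category %in% c("sig_decrease", "sig_increase")), 0L)
  expect_true(all(rd_same$category[rroi_ref$in_rroi] == "rroi_unchanged"))
  expect_true(all(rd_same$category[!rroi_ref$in_rroi] == "unchanged"))

  # lower one cell by 100 kPa on every step: exactly that cell decreases
  # (identical shifts are the zero-variance limit of the paired t)
  alt <- lapply(base, function(m) { m[2, 3] <- m[2, 3] - 100; m })
  peaks_alt <- lapply(seq_along(alt), function(i) peak_from_matrix(alt[[i]], i))
  rd <- redistribution_map(peaks_ref, peaks_alt, rroi_ref)
  expect_equal(as.character(rd$category[2, 3]), "sig_decrease")
  expect_equal(sum(rd$category == "sig_decrease"), 1L)
  expect_equal(sum(rd$category == "sig_increase"), 0L)
  expect_equal(rd$mean_diff[2, 3], -100)
  expect_equal(rd$p[2, 3], 0)

  # a step-varying reduction gives a finite t; p matches stats::t.test
  alt2 <- lapply(seq_along(base), function(i) {
    m <- base[[i]]; m[2, 3] <- m[2, 3] - 100 - 0.5 * i; m
  })
  peaks_alt2 <- lapply(seq_along(alt2), function(i) peak_from_matrix(alt2[[i]], i))
  rd2 <- redistribution_map(peaks_ref, peaks_alt2, rroi_ref)
  d <- vapply(seq_along(base), function(i) alt2[[i]][2, 3] - base[[i]][2, 3], 0)
  expect_equal(rd2$p[2, 3], t.test(d)$p.value)
  expect_equal(as.character(rd2$category[2, 3]), "sig_decrease")

  # zero-variance identical differences are not significant
  rd0 <- redistribution_map(peaks_ref, peaks_ref, rroi_ref)
  expect_true(all(rd0$p == 1 | rd0$p > 0.05))

  expect_error(redistribution_map(peaks_ref[1:3], peaks_alt, rroi_ref),
               "equal step counts", class = "qsf_redist_error")
})

test_that("cell-wise paired and Welch tests agree with stats::t.test", {
  set.seed(8)
  X <- matrix(rnorm(5 * 10, 200, 30), 5, 10)
  Y <- matrix(rnorm(5 * 10, 190, 25), 5, 10)
  paired <- qsfoot:::cellwise_t(X, Y, paired = TRUE)
  welch <- qsfoot:::cellwise_t(X, Y, paired = FALSE)
  for (i in 1:5) {
    tp <- t.test(Y[i, ], X[i, ], paired = TRUE)
    tw <- t.test(Y[i, ], X[i, ])
    expect_equal(paired$p[i], tp$p.value)
    expect_equal(welch$p[i], tw$p.value)
  }
})

test_that("residual reduction reports follow the bound formula", {
  mean_ref <- matrix(0, 4, 4); mean_ref[1:4] <- 234.2
  ref <- mppm_from_matrices(mean_ref, mean_ref * 0 + 10, 24)
  rroi_ref <- build_rroi(ref)
  expect_equal(rroi_ref$total_area_cm2, 1)

  # optimal: alternative mask empty; bound still reported
  empty <- build_rroi(mppm_from_matrices(matrix(0, 4, 4), matrix(0, 4, 4), 24))
  rep_opt <- residual_reduction(ref, rroi_ref,
                                mppm_from_matrices(matrix(0, 4, 4),
                                                   matrix(0, 4, 4), 24), empty)
  expect_true(rep_opt$optimal)
  expect_true(is.na(rep_opt$mean_reduction_kpa))
  expect_equal(rep_opt$lower_bound_kpa, 34.2)

  # non-optimal: reduction is the difference of R-ROI means
  mean_alt <- matrix(0, 4, 4); mean_alt[1:2] <- 210
  alt <- mppm_from_matrices(mean_alt, mean_alt * 0 + 8, 24)
  rroi_alt <- build_rroi(alt)
  rep2 <- residual_reduction(ref, rroi_ref, alt, rroi_alt)
  expect_false(rep2$optimal)
  expect_equal(rep2$mean_reduction_kpa, 234.2 - 210)
  expect_equal(rep2$mean_reduction_pct, 100 * (234.2 - 210) / 234.2)

  # boundary: reference mean exactly at threshold -> zero bound
  at_thr <- mppm_from_matrices(matrix(200, 2, 2), matrix(1, 2, 2), 24)
  r_thr <- build_rroi(at_thr)
  expect_equal(residual_reduction(at_thr, r_thr, at_thr, r_thr)$lower_bound_kpa, 0)

  expect_error(residual_reduction(ref, empty, alt, rroi_alt),
               "no reference risk region", class = "qsf_reduction_error")
})
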