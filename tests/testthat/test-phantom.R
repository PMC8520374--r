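test_that("gamma-variate AIF is zero before onset and peaks near onset + alpha*beta", {
  g <- time_grid(100, 0.1, 0)
  p <- aif_params(amplitude = 1, onset = 4, alpha = 3, beta = 1.5)
  B <- make_aif(p, g)
  tt <- grid_times(g)
  expect_true(all(B[tt <= 4] == 0))
  expect_true(all(is.finite(B)) && all(B >= 0))
  # discrete argmax within one dt of the analytic peak location
  expect_lt(abs(tt[which.max(B)] - (4 + 3 * 1.5)), 0.1 + 1e-12)
  # dense numeric argmax oracle on a 10x finer grid
  gf <- refine_grid(g, 10)
  Bf <- make_aif(p, gf)
  expect_lt(abs(tt[which.max(B)] - grid_times(gf)[which.max(Bf)]), 0.1 + 1e-12)
})

test_that("AIF parameter validation rejects non-finite and non-positive values", {
  expect_error(aif_params(amplitude = NaN), "finite")
  expect_error(aif_params(alpha = -1))
  expect_error(time_grid(3), "n_frames")
  expect_error(time_grid(10, dt = 0), "dt")
})

test_that("box residue matches the piecewise-constant example and is area-exact", {
  g <- time_grid(8, 1, 0)
  G <- make_residue("box", cbf = 2, mtt = 3, delay = 0, g)
  expect_equal(G, c(2, 2, 2, 0, 0, 0, 0, 0))
  expect_equal(sum(G) * 1, 2 * 3)  # Riemann area = cbf * mtt
  # off-grid delay and mtt: overlap fractions keep the area exact
  G2 <- make_residue("box", cbf = 1.5, mtt = 2.7, delay = 0.4, g)
  expect_equal(sum(G2) * 1, 1.5 * 2.7, tolerance = 1e-12)
  expect_equal(max(G2), 1.5)
})

test_that("exponential residue peaks at cbf on the first frame at/after delay", {
  g <- time_grid(20, 2, 0)
  for (delay in c(0, 1.3, 4)) {
    G <- make_residue("exponential", cbf = 1, mtt = 4, delay = delay, g)
    tt <- grid_times(g)
    k0 <- which(tt >= delay)[1]
    expect_equal(max(G), 1)
    expect_equal(which.max(G), k0)
    expect_true(all(diff(G[k0:length(G)]) <= 0))  # monotone decay after peak
  }
})

test_that("exponential residue integrates to cbf*mtt (fine-grid trapezoid oracle)", {
  g <- time_grid(8000, 0.01, 0)
  G <- make_residue("exponential", cbf = 1, mtt = 10, delay = 0, g)
  trap <- 0.01 * (sum(G) - (G[1] + G[length(G)]) / 2)
  expect_lt(abs(trap - 10) / 10, 0.005)
  # coarse grid: within-window Riemann area is exact by construction
  gc <- time_grid(20, 2, 0)
  Gc <- make_residue("exponential", cbf = 2, mtt = 5, delay = 1.2, gc)
  expect_equal(sum(Gc) * 2, 2 * 5, tolerance = 1e-10)
})

test_that("under-resolved residue (mtt < dt) warns and proceeds", {
  g <- time_grid(10, 2, 0)
  expect_warning(G <- make_residue("exponential", 1, 0.5, 0, g), "under-resolved")
  expect_equal(max(G), 1)
})

test_that("residue input validation", {
  g <- time_grid(10, 1)
  expect_error(make_residue("exponential", cbf = -1, mtt = 2, grid = g))
  expect_error(make_residue("exponential", cbf = 1, mtt = 0, grid = g))
  expect_error(make_residue("box", cbf = 1, mtt = 2, delay = -1, grid = g))
})

test_that("phantom ground truth satisfies the central-volume identity and labels partition the brain", {
  ph <- build_phantom(small_phantom_spec())
  m <- ph$masks$brain
  tr <- ph$truth
  expect_lt(max(abs(tr$mtt[m] - 60 * tr$cbv[m] / tr$cbf[m])), 1e-9)
  expect_true(all(tr$cbf[m] > 0), all(tr$cbv[m] > 0))
  # labels: 0 outside brain; >= 1 inside; lesion labels only inside lesions
  expect_true(all(tr$labels[!m] == 0L))
  expect_true(all(tr$labels[m] >= 1L))
  expect_true(all(tr$labels[ph$masks$cia] == 3L))
  expect_true(all(tr$labels[ph$masks$pi] == 2L))
  # lesions disjoint, confined to one hemisphere, mirror voxels normal
  expect_false(any(ph$masks$cia & ph$masks$pi))
  nx <- dim(m)[1]
  for (rn in c("cia", "pi")) {
    mm <- ph$masks[[rn]]
    expect_true(all(slice.index(mm, 1)[mm] <= nx / 2))
    mirror <- mm[rev(seq_len(nx)), , , drop = FALSE]
    expect_true(all(tr$labels[mirror] == 1L))
  }
})

test_that("noiseless series equals the forward model of the true residues exactly", {
  ph <- build_phantom(small_phantom_spec())
  sys <- build_conv_matrix(ph$aif, ph$spec$time$dt)
  expect_lt(max(abs(conv_forward(sys, ph$truth$G_true) - ph$series)), 1e-12)
})

test_that("lesion-free phantom has exactly symmetric maps (all relative values 100)", {
  ph <- build_phantom(phantom_spec(nx = 32, ny = 32, lesions = list()))
  rel <- compute_relative_maps(ph$truth, ph$masks$brain, "left")
  for (p in c("rcbf", "rcbv", "rmtt", "rttp")) {
    v <- rel[[p]][!is.na(rel[[p]])]
    expect_gt(length(v), 0)
    expect_equal(unname(range(v)), c(100, 100))
  }
})

test_that("ground-truth relative maps reproduce the achievable severities within 2%", {
  ph <- build_phantom(phantom_spec())   # default study phantom
  rel <- compute_relative_maps(ph$truth, ph$masks$brain, "left")
  for (rn in c("cia", "pi")) {
    got <- region_means(rel, ph$masks[[rn]])
    want <- ph$meta$severity_achieved[[rn]]
    expect_lt(max(abs(got - want) / want), 0.02, label = rn)
  }
})

test_that("phantom construction is deterministic and noise is seed-reproducible", {
  spec <- small_phantom_spec()
  ph1 <- build_phantom(spec)
  ph2 <- build_phantom(spec)
  expect_identical(ph1$series, ph2$series)
  n1 <- add_noise(ph1$series, 2, seed = 123)
  n2 <- add_noise(ph1$series, 2, seed = 123)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_noise(ph1$series, 2, seed = 124)))
  expect_identical(add_noise(ph1$series, 0, seed = 1), ph1$series)
})

test_that("add_noise has the requested standard deviation and leaves the RNG state alone", {
  vol <- array(0, dim = c(50, 50, 1, 40))  # 1e5 voxels
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  noisy <- add_noise(vol, 2, seed = 7)
  expect_equal(rnorm(1), before)  # global stream untouched
  expect_lt(abs(sd(noisy) - 2) / 2, 0.02)
  expect_lt(abs(mean(noisy)), 0.05)
  expect_error(add_noise(vol, -1, 1), "sigma")
})

test_that("treatment effect moves penumbra severities toward 100 and leaves the core alone", {
  spec <- small_phantom_spec()
  expect_identical(simulate_treatment_effect(spec, 0)$lesions, spec$lesions)
  full <- simulate_treatment_effect(spec, 1)
  expect_equal(unname(full$lesions$pi$severity), rep(100, 4))
  expect_identical(full$lesions$cia, spec$lesions$cia)
  half <- simulate_treatment_effect(spec, 0.5)
  expect_equal(unname(half$lesions$pi$severity["rcbf"]), (18.37 + 100) / 2)
  expect_error(simulate_treatment_effect(spec, 1.2), "recovery_fraction")
  nolesion <- phantom_spec(nx = 32, ny = 32, lesions = list())
  expect_error(simulate_treatment_effect(nolesion, 0.5), "regions")
})

test_that("invalid lesion geometry is rejected", {
  expect_error(build_phantom(phantom_spec(nx = 32, ny = 32, lesions = list(
    cia = lesion_spec(c(20, 16), c(5, 5))))), "mid-sagittal")
  expect_error(build_phantom(phantom_spec(nx = 32, ny = 32, lesions = list(
    a = lesion_spec(c(8, 13), c(3, 3)),
    b = lesion_spec(c(9, 14), c(3, 3))))), "overlap")
  expect_error(phantom_spec(nx = 33), "even")
  expect_error(lesion_spec(c(10, 10), c(3, 3),
                           severity = c(rcbf = 0, rcbv = 50, rmtt = 50, rttp = 50)))
})
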