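test_that("conditioned swarms hit the requested alignment exactly", {
  cfg <- world_config(N = 10)
  set.seed(2)
  expect_equal(alignment(sample_conditioned_swarm(1, cfg)), 1)
  expect_true(all(sample_conditioned_swarm(1, cfg)$heading == 1L))
  sw0 <- sample_conditioned_swarm(0, cfg)
  expect_equal(sum(sw0$heading == 1L), 5)
  for (z in z_grid(10))
    expect_equal(alignment(sample_conditioned_swarm(z, cfg)), z)
  expect_error(sample_conditioned_swarm(0.55, cfg), "grid")
})

test_that("transition kernels are row-stochastic and mirror-symmetric", {
  cfg <- world_config(N = 10)
  k <- estimate_transition_kernel(cfg, make_fixed_disposition(5),
                                  n_samples = 3000L, seed = 14)
  expect_equal(unname(rowSums(k$P)), rep(1, 11), tolerance = 1e-9)
  expect_true(all(k$P >= 0))
  # direction-flip symmetry P(z'|z) = P(-z'|-z) within 4 MC standard errors
  n <- k$counts[1]
  Prev <- k$P[rev(seq_len(11)), rev(seq_len(11))]
  se <- sqrt(k$P * (1 - k$P) / n + Prev * (1 - Prev) / n)
  dev <- abs(k$P - Prev) / pmax(se, 1e-12)
  expect_lt(max(dev[k$P + Prev > 0]), 4)
})

test_that("a neutral policy gives the displaced-binomial kernel and its closed forms", {
  N <- 10L
  cfg <- world_config(N = N)
  k <- estimate_transition_kernel(cfg, make_neutral_memory(),
                                  n_samples = 4000L, seed = 15)
  bin <- dbinom(0:N, N, 0.5)
  # with d = 0 every post-turn heading is uniform, independent of z
  for (i in c(1L, 6L, 11L))
    expect_lt(max(abs(k$P[i, ] - bin)), 4 * sqrt(max(bin * (1 - bin)) / 4000))
  ck <- km_from_kernel(k)
  expect_lt(max(abs(ck$F + ck$z) / ck$se_F), 4)
  expect_lt(max(abs(ck$D - 1 / (2 * N))), 6 * max(ck$se_D))
})

test_that("Kramers-Moyal coefficients of exactly known kernels are recovered", {
  N <- 8L
  ident <- fixture_kernel(diag(N + 1L), N)
  c0 <- km_from_kernel(ident)
  expect_true(all(c0$F == 0))
  expect_true(all(c0$D == 0))
  fp <- find_fixed_points(c0)
  expect_true(attr(fp, "degenerate"))
  expect_equal(nrow(fp), 0)

  # kernel that deterministically moves one grid step towards z = 0
  P <- matrix(0, N + 1L, N + 1L)
  mid <- (N / 2) + 1L
  for (i in seq_len(N + 1L))
    P[i, i + sign(mid - i)] <- 1
  P[mid, mid] <- 1
  ck <- km_from_kernel(fixture_kernel(P, N))
  expect_equal(ck$F[1], 2 / N)      # drift up at z = -1
  expect_equal(ck$F[N + 1L], -2 / N)
  expect_true(all(ck$D == 0))
})

test_that("the mean-field theory reproduces its closed forms and symmetries", {
  for (N in c(10L, 40L)) {
    mf <- meanfield_drift_diffusion(N, 8, make_neutral_memory())
    expect_equal(mf$F, -mf$z, tolerance = 1e-12)
    expect_equal(mf$D, rep(1 / (2 * N), N + 1), tolerance = 1e-12)
  }
  mf <- meanfield_drift_diffusion(40, 8, make_fixed_disposition(5))
  expect_equal(mf$F, -rev(mf$F), tolerance = 1e-12)  # F odd
  expect_equal(mf$D, rev(mf$D), tolerance = 1e-12)   # D even
  expect_true(all(mf$D >= 0))
  expect_equal(mf$F[mf$z == 0], 0, tolerance = 1e-12)
  # high density, high decisiveness: disorder is unstable
  mfH <- meanfield_drift_diffusion(70, 8, make_fixed_disposition(30))
  i0 <- which(mfH$z == 0)
  expect_gt((mfH$F[i0 + 1] - mfH$F[i0 - 1]) / (mfH$z[i0 + 1] - mfH$z[i0 - 1]), 0)
  expect_error(meanfield_drift_diffusion(10.5, 8, make_neutral_memory()),
               "integer")
})

test_that("mean-field and kernel drift agree up to the documented sequential bias", {
  # the mean-field ignores within-sweep feedback (later agents react to
  # earlier flips); the residual is a systematic few-hundredths offset
  for (case in list(list(d = 1, N = 10L), list(d = 5, N = 40L))) {
    k <- estimate_transition_kernel(world_config(N = case$N),
          make_fixed_disposition(case$d), n_samples = 1500L, seed = 16)
    ck <- km_from_kernel(k)
    mf <- meanfield_drift_diffusion(case$N, 8, make_fixed_disposition(case$d))
    expect_lt(max(abs(mf$F - ck$F)), 0.1)
    expect_gt(cor(mf$F, ck$F), 0.98)
  }
})

test_that("empirical Kramers-Moyal estimates match theory where exact", {
  rec <- list(z = rep(0.5, 200))
  e <- empirical_km(rec, burn_in = 0)
  expect_equal(e$F, 0)
  expect_equal(e$D, 0)
  expect_error(empirical_km(list(z = c(0, 1)), burn_in = 5), "burn-in")

  # long d = 0 run: F-hat within 4 SE of -z on trusted bins
  rec0 <- run_simulation(sim_config(N = 10, mode = "fixed", d = 0,
                                    steps = 20000, seed = 41))
  e0 <- empirical_km(rec0, burn_in = 100)
  e0 <- e0[e0$trusted, ]
  expect_gt(nrow(e0), 5)
  expect_lt(max(abs(e0$F + e0$z) / e0$se_F), 4)
})

test_that("empirical and kernel drift agree in shape for a moderate disposition", {
  rec <- run_simulation(sim_config(N = 40, mode = "fixed", d = 5,
                                   steps = 20000, seed = 42))
  e <- empirical_km(rec, burn_in = 500, min_count = 100)
  e <- e[e$trusted, ]
  k <- km_from_kernel(estimate_transition_kernel(world_config(N = 40),
        make_fixed_disposition(5), n_samples = 2000L, seed = 43))
  idx <- match(round(e$z, 9), round(k$z, 9))
  expect_true(all(!is.na(idx)))
  expect_lt(max(abs(e$F - k$F[idx])), 0.1)
  expect_gt(cor(e$F, k$F[idx]), 0.9)
})

test_that("fixed-point finding locates roots and classifies stability", {
  z <- z_grid(40)
  lin <- dd_curves_for_test(z, -z)
  fp <- find_fixed_points(lin)
  expect_equal(fp$z0, 0)
  expect_equal(fp$stability, "stable")
  expect_equal(fp$slope, -1, tolerance = 1e-9)

  cub <- dd_curves_for_test(z, z - z^3)
  fp3 <- find_fixed_points(cub)
  expect_equal(fp3$z0, c(-1, 0, 1))
  expect_equal(fp3$stability, c("stable", "unstable", "stable"))

  # mean-field bifurcation: low density monostable, high density bistable
  fpL <- find_fixed_points(meanfield_drift_diffusion(10, 8,
                                                     make_fixed_disposition(30)))
  expect_equal(nrow(fpL), 1)
  expect_equal(fpL$z0, 0)
  expect_equal(fpL$stability, "stable")
  fpH <- find_fixed_points(meanfield_drift_diffusion(70, 8,
                                                     make_fixed_disposition(30)))
  stab <- fpH[fpH$stability == "stable", ]
  expect_equal(nrow(stab), 2)
  expect_equal(sort(stab$z0), c(-1, 1) * abs(stab$z0[1]))
  expect_gt(abs(stab$z0[1]), 0.8)
  expect_equal(fpH$z0[fpH$stability == "unstable"], 0)

  # increasing decisiveness at fixed density bifurcates the same way
  fpd1 <- find_fixed_points(meanfield_drift_diffusion(70, 8,
                                                      make_fixed_disposition(0.2)))
  expect_equal(nrow(fpd1[fpd1$stability == "stable", ]), 1)
})

test_that("analysis outputs serialise to their documented CSV schemas", {
  k <- estimate_transition_kernel(world_config(N = 6), make_neutral_memory(),
                                  n_samples = 100L, seed = 18)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_kernel(k, p1)
  kt <- read.csv(p1)
  expect_identical(names(kt), c("z", "zprime", "p"))
  expect_equal(nrow(kt), 49)
  ck <- km_from_kernel(k)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dd_curves(ck, p2)
  expect_identical(names(read.csv(p2)),
                   c("z", "F", "D", "se_F", "se_D", "method"))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_fixed_points(find_fixed_points(ck), p3)
  expect_identical(names(read.csv(p3)), c("z0", "slope", "stability"))
})
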