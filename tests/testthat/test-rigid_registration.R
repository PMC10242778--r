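# Rigid transform algebra, the closed-form least-squares fit, and ICP.

test_that("transform algebra: compose/invert round-trips to 1e-9 nm", {
  set.seed(301)
  for (i in 1:20) {
    t1 <- rigid_transform(runif(1, -0.1, 0.1), runif(1, -2000, 2000),
                          runif(1, -2000, 2000))
    pts <- cbind(runif(50, 0, 30000), runif(50, 0, 30000))
    back <- transform_points(invert_transform(t1), transform_points(t1, pts))
    expect_lt(max(abs(back - pts)), 1e-9)
    idc <- compose_transforms(invert_transform(t1), t1)
    expect_lt(abs(idc$theta), 1e-12)
    expect_lt(max(abs(c(idc$tx, idc$ty))), 1e-9)
    expect_equal(det(rotation_matrix(t1)), 1, tolerance = 1e-12)
  }
})

test_that("estimate_rigid returns identity on identical sets", {
  pts <- cbind(c(0, 100, 500, 200), c(0, 300, 100, 800))
  fit <- estimate_rigid(pts, pts)
  expect_equal(fit$theta, 0, tolerance = 1e-12)
  expect_equal(c(fit$tx, fit$ty), c(0, 0), tolerance = 1e-12)
})

test_that("estimate_rigid recovers a known rotation+translation to 1e-9", {
  set.seed(311)
  ref <- cbind(runif(5, 0, 10000), runif(5, 0, 10000))
  true <- rigid_transform(0.01, 500, -300)
  mov <- transform_points(invert_transform(true), ref)
  fit <- estimate_rigid(mov, ref)
  expect_equal(fit$theta, true$theta, tolerance = 1e-9)
  expect_equal(fit$tx, true$tx, tolerance = 1e-6)
  expect_equal(fit$ty, true$ty, tolerance = 1e-6)
  resid <- transform_points(fit, mov) - ref
  expect_lt(sqrt(mean(resid^2)), 1e-9)
})

test_that("noiseless fits are exact over 50 random cases, det(R) = +1", {
  set.seed(321)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    ref <- cbind(runif(n, 0, 30000), runif(n, 0, 30000))
    true <- rigid_transform(runif(1, -0.5, 0.5), runif(1, -3000, 3000),
                            runif(1, -3000, 3000))
    mov <- transform_points(invert_transform(true), ref)
    fit <- estimate_rigid(mov, ref)
    resid <- transform_points(fit, mov) - ref
    expect_lt(sqrt(mean(resid^2)), 1e-9)
    expect_equal(det(rotation_matrix(fit)), 1, tolerance = 1e-12)
  }
})

test_that("a 3-pair fit matches an exhaustive grid search", {
  # independent oracle: coarse-to-fine grid over (theta, tx, ty)
  set.seed(331)
  ref <- cbind(c(0, 1000, 400), c(0, 200, 900))
  true <- rigid_transform(0.004, 120, -80)
  mov <- transform_points(invert_transform(true), ref)
  # for fixed theta the optimal translation has a closed form (centroid
  # difference), so the search reduces to an exhaustive 1-D theta grid
  obj <- function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    t_opt <- colMeans(ref) - R %*% colMeans(mov)
    sum((sweep(mov %*% t(R), 2, -as.vector(t_opt)) - ref)^2)
  }
  th_grid <- seq(-pi, pi, by = 1e-3)
  best <- th_grid[which.min(vapply(th_grid, obj, numeric(1)))]
  for (lev in 1:8) {  # local refinement around the grid minimum
    th_grid <- seq(best - 2e-3 / 4^(lev - 1), best + 2e-3 / 4^(lev - 1),
                   length.out = 41)
    best <- th_grid[which.min(vapply(th_grid, obj, numeric(1)))]
  }
  R_best <- matrix(c(cos(best), sin(best), -sin(best), cos(best)), 2, 2)
  t_best <- colMeans(ref) - R_best %*% colMeans(mov)
  fit <- estimate_rigid(mov, ref)
  expect_equal(fit$theta, best, tolerance = 1e-6)
  expect_equal(fit$tx, t_best[1], tolerance = 1e-3)
  expect_equal(fit$ty, t_best[2], tolerance = 1e-3)
})

test_that("degenerate inputs error", {
  expect_error(estimate_rigid(cbind(1, 1), cbind(2, 2)), "at least 2")
  expect_error(estimate_rigid(cbind(c(1, 2, 3), c(1, 2, 3)),
                              cbind(c(1, 2), c(1, 2))),
               "equal length")
  coincident <- cbind(c(5, 5, 5), c(7, 7, 7))
  expect_error(estimate_rigid(coincident, coincident + 1), "degenerate")
})

test_that("apply_transform maps coordinates only, preserving order", {
  tab <- loc_table(c(3, 1, 2), c(0, 10, 20), c(0, -10, 5),
                   intensity = c(1, 2, 3))
  ident <- apply_transform(tab, rigid_transform(0, 0, 0))
  expect_identical(as.data.frame(ident), as.data.frame(tab))
  shifted <- apply_transform(tab, rigid_transform(0, 100, 0))
  expect_equal(shifted$x, tab$x + 100)
  expect_equal(shifted$y, tab$y)
  expect_identical(shifted$frame, tab$frame)
  expect_identical(shifted$intensity, tab$intensity)
  # inverse-composition oracle on 1e4 random points
  set.seed(341)
  big <- random_table(10000, field = 33280)
  t1 <- rigid_transform(0.02, 800, -400)
  back <- apply_transform(apply_transform(big, t1), invert_transform(t1))
  expect_lt(max(abs(back$x - big$x), abs(back$y - big$y)), 1e-6)
})

test_that("ICP on identical landmark sets is the identity in <= 2 iterations", {
  set.seed(351)
  lm <- cbind(runif(8, 0, 20000), runif(8, 0, 20000))
  res <- icp(lm, lm)
  expect_true(res$converged)
  expect_lte(res$n_iterations, 2L)
  expect_lt(abs(res$transform$theta), 1e-12)
  expect_lt(max(abs(c(res$transform$tx, res$transform$ty))), 1e-9)
  expect_equal(res$final_mean_distance, 0)
})

test_that("ICP recovers a known transform despite spurious landmarks", {
  set.seed(361)
  common <- cbind(runif(10, 2000, 31000), runif(10, 2000, 31000))
  true <- rigid_transform(0.005, 800, -400)
  # spurious landmarks kept clear of true beads so they are genuinely unmatched
  spurious <- matrix(NA_real_, 0, 2)
  while (nrow(spurious) < 3) {
    p <- runif(2, 2000, 31000)
    if (min(sqrt((common[, 1] - p[1])^2 + (common[, 2] - p[2])^2)) > 4000)
      spurious <- rbind(spurious, p)
  }
  mov <- rbind(transform_points(true, common), spurious)
  res <- icp(mov, common)
  expect_true(res$converged)
  aligned <- transform_points(res$transform, transform_points(true, common))
  expect_lt(sqrt(mean((aligned - common)^2)), 1)
  # spurious moving landmarks (rows 11-13) are not inlier pairs at the end
  expect_false(any(res$matched_pairs[, "moving"] > 10))
})

test_that("ICP mean inlier distance decreases monotonically", {
  set.seed(371)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    ref <- cbind(runif(n, 0, 30000), runif(n, 0, 30000))
    true <- rigid_transform(runif(1, -0.02, 0.02), runif(1, -1500, 1500),
                            runif(1, -1500, 1500))
    # noiseless: strictly non-increasing (the least-squares fit can only help)
    res0 <- icp(transform_points(true, ref), ref)
    expect_true(all(diff(res0$mean_distance_history) <= 1e-9))
    expect_true(res0$converged)
    expect_lt(res0$final_mean_distance, 1e-6)
    # with landmark noise re-matching can grow the inlier set and nudge the
    # recorded mean up; the run must still converge and end no worse than
    # it started
    mov <- transform_points(true, ref) + matrix(rnorm(2 * n, 0, 15), n, 2)
    res <- icp(mov, ref)
    expect_true(res$converged)
    expect_lte(res$final_mean_distance, res$mean_distance_history[1])
  }
})

test_that("with per-channel landmark jitter the registration beats the misalignment", {
  set.seed(381)
  n <- 8; sigma <- 20
  truth <- cbind(runif(n, 2000, 31000), runif(n, 2000, 31000))
  ref <- truth + matrix(rnorm(2 * n, 0, sigma), n, 2)
  mov <- transform_points(rigid_transform(0, 1000, 0),
                          truth + matrix(rnorm(2 * n, 0, sigma), n, 2))
  res <- icp(mov, ref)
  after <- transform_points(res$transform, mov)
  tre_after <- mean(sqrt(rowSums((after - truth)^2)))
  expect_lt(tre_after, 5 * sigma * sqrt(2))  # jitter-scale error
  expect_lt(tre_after, 1000)                 # far below the misalignment
})

test_that("ICP input validation and non-convergence warning", {
  expect_error(icp(cbind(1, 1), cbind(c(1, 2), c(1, 2))), "at least 2")
  set.seed(391)
  ref <- cbind(runif(6, 0, 10000), runif(6, 0, 10000))
  mov <- transform_points(rigid_transform(0.01, 500, 200), ref)
  expect_warning(res <- icp(mov, ref, icp_config(convergence_tol = 1e-12,
                                                 max_iterations = 2)),
                 "did not converge")
  expect_false(res$converged)
})
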