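# Registration-quality metrics: snapping, TRE, rendering, NCC, Wilcoxon.

test_that("annotations snap to the nearest localization, ties to lowest index", {
  tab <- loc_table(1:3, c(10, 0, 20), c(0, 20, 0))
  ann <- annotation_set(0, 0)
  sn <- snap_annotations(ann, tab)
  expect_equal(c(sn$x, sn$y), c(10, 0))
  # annotation exactly on a localization stays put
  on <- snap_annotations(annotation_set(0, 20), tab)
  expect_equal(c(on$x, on$y), c(0, 20))
  # equidistant candidates: the earlier row wins
  tie_tab <- loc_table(1:2, c(-5, 5), c(0, 0))
  tie <- snap_annotations(annotation_set(0, 0), tie_tab)
  expect_equal(tie$x, -5)
  # brute-force oracle on random data
  set.seed(501)
  rt <- random_table(500, field = 4000)
  anns <- annotation_set(runif(20, 0, 4000), runif(20, 0, 4000))
  sn2 <- snap_annotations(anns, rt)
  for (i in 1:20) {
    d2 <- (rt$x - anns$x[i])^2 + (rt$y - anns$y[i])^2
    j <- which.min(d2)
    expect_equal(c(sn2$x[i], sn2$y[i]), c(rt$x[j], rt$y[j]))
  }
})

test_that("annotation files read in comma and whitespace dialects", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("# clicked fiducial centres", "100.5, 200.5", "300 400",
               "500,600"), p)
  ann <- read_annotations(p, channel_id = "642")
  expect_equal(ann$x, c(100.5, 300, 500))
  expect_equal(ann$y, c(200.5, 400, 600))
  # a one-line header is tolerated
  p2 <- tempfile(fileext = ".txt")
  writeLines(c("x y", "1 2"), p2)
  expect_equal(read_annotations(p2)$x, 1)
  expect_error(read_annotations(tempfile()), "not found")
})

test_that("TRE: identical sets give 0, a (3,4) offset gives 5 with SD 0", {
  a <- annotation_set(c(0, 100, 200), c(0, 50, 80))
  expect_equal(tre(a, a)$distances, rep(0, 3))
  b <- annotation_set(a$x + 3, a$y + 4)
  s <- tre(b, a)
  expect_equal(s$distances, rep(5, 3))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_error(tre(a, annotation_set(0, 0)), "length")
})

test_that("TRE is symmetric and invariant under a common rigid transform", {
  set.seed(511)
  a <- annotation_set(runif(10, 0, 1000), runif(10, 0, 1000))
  b <- annotation_set(a$x + rnorm(10, 0, 40), a$y + rnorm(10, 0, 40))
  expect_equal(tre(a, b)$distances, tre(b, a)$distances)
  t1 <- rigid_transform(0.3, 500, -200)
  ta <- transform_points(t1, as.matrix(as.data.frame(a)))
  tb <- transform_points(t1, as.matrix(as.data.frame(b)))
  expect_equal(tre(annotation_set(ta[, 1], ta[, 2]),
                   annotation_set(tb[, 1], tb[, 2]))$distances,
               tre(a, b)$distances, tolerance = 1e-9)
  # forward-simulation oracle: apply a known misalignment to one set
  tm <- transform_points(rigid_transform(0.001, 200, -100),
                         as.matrix(as.data.frame(a)))
  expect_equal(tre(annotation_set(tm[, 1], tm[, 2]), a)$mean,
               mean(sqrt(rowSums((tm - as.matrix(as.data.frame(a)))^2))))
})

test_that("rendering conserves localization mass", {
  # sigma = 0: a single nonzero pixel of value 1
  tab1 <- loc_table(1, 55, 75)
  img0 <- render(tab1, pixel_size = 10, sigma = 0,
                 bounds = c(0, 100, 0, 100))
  expect_equal(sum(img0$pixels != 0), 1)
  expect_equal(sum(img0$pixels), 1)
  expect_equal(img0$pixels[8, 6], 1)  # row = y bin, col = x bin
  # interior Gaussian integrates to 1
  img1 <- render(tab1, pixel_size = 10, sigma = 20,
                 bounds = c(-200, 300, -200, 300))
  expect_equal(sum(img1$pixels), 1, tolerance = 1e-6)
  # 100 interior localizations integrate to 100
  set.seed(521)
  tab100 <- loc_table(rep(1, 100), runif(100, 300, 700), runif(100, 300, 700))
  img2 <- render(tab100, pixel_size = 10, sigma = 20,
                 bounds = c(0, 1000, 0, 1000))
  expect_equal(sum(img2$pixels), 100, tolerance = 1e-4)
  expect_error(render(tab1, pixel_size = 10, sigma = 0,
                      bounds = c(5, 5, 0, 10)), "bounds")
})

test_that("NCC identities and independent-formula oracle", {
  set.seed(531)
  tab <- random_table(300, field = 2000)
  img <- render(tab, pixel_size = 50, sigma = 30, bounds = c(0, 2000, 0, 2000))
  expect_equal(ncc(img, img), 1)
  neg <- img
  neg$pixels <- 2 * mean(img$pixels) - img$pixels  # negation about the mean
  expect_equal(ncc(img, neg), -1)
  # random image pair: matches cor() of flattened pixels, and lies in [-1, 1]
  a <- img; b <- img
  a$pixels <- matrix(runif(1600), 40, 40)
  b$pixels <- matrix(runif(1600), 40, 40)
  expect_equal(ncc(a, b), cor(as.vector(a$pixels), as.vector(b$pixels)),
               tolerance = 1e-12)
  expect_gte(ncc(a, b), -1); expect_lte(ncc(a, b), 1)
  # affine intensity rescaling leaves NCC unchanged
  b2 <- b; b2$pixels <- 3.7 * b$pixels + 42
  expect_equal(ncc(a, b2), ncc(a, b), tolerance = 1e-12)
  # zero-variance image is an error
  flat <- a; flat$pixels <- matrix(1, 40, 40)
  expect_error(ncc(a, flat), "zero-variance")
  wrong <- b; wrong$pixels <- matrix(0.5, 10, 10)
  expect_error(ncc(a, wrong), "dimensions")
})

test_that("Wilcoxon: identity gives p = 1, uniform improvement is significant", {
  x <- c(10, 20, 30, 40, 50, 60)
  expect_warning(res <- paired_wilcoxon(x, x), "zero")
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  set.seed(541)
  after <- runif(20, 20, 80)
  res2 <- paired_wilcoxon(after + runif(20, 60, 140), after)
  expect_lt(res2$p_value, 0.05)
  expect_true(res2$significant)
  expect_error(paired_wilcoxon(1:3, 4:6), "at least 5")
  expect_error(paired_wilcoxon(1:6, 1:5), "length")
})

test_that("Wilcoxon p at n = 8 equals exhaustive sign enumeration", {
  before <- c(130, 95, 112, 88, 140, 101, 77, 123)
  after  <- c(60, 104, 70, 51, 62, 88, 81, 49)
  d <- before - after
  # exact two-sided signed-rank distribution by enumerating all 2^8 sign
  # assignments of the ranked |d|
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  w_all <- signs %*% r          # W+ for every assignment
  w_obs <- sum(r[d > 0])
  p_exact <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(paired_wilcoxon(before, after)$p_value, p_exact)
})
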