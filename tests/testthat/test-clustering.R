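# Modified k-means, two-level fitting, CV-based K selection, back-fitting.

test_that("noiseless identifiable clusters reach GEV 1 with sign-blind labels", {
  A <- generateTemplates(12, 3, seed = 1)
  signs <- withr::with_seed(2, sample(c(-1, 1), 90, replace = TRUE))
  maps <- A[rep(1:3, 30), ] * signs
  fit <- modifiedKMeans(maps, 3, restarts = 10, seed = 3)
  expect_equal(gev(fit), 1, tolerance = 1e-9)
  # polarity invariance: negating every map changes nothing material
  fitNeg <- modifiedKMeans(-maps, 3, restarts = 10, seed = 3)
  expect_equal(gev(fitNeg), 1, tolerance = 1e-9)
  M <- abs(templateMaps(fit) %*% t(templateMaps(fitNeg)))
  expect_equal(sort(apply(M, 1, max)), rep(1, 3), tolerance = 1e-9)
})

test_that("templates match the per-cluster eigen-decomposition oracle", {
  # 2 noisy clusters in 3 channels, SNR 10, n = 500
  set.seed(10)
  gen <- generateTemplates(3, 2, seed = 4)
  n <- 500
  cl <- rep(1:2, length.out = n)
  signs <- sample(c(-1, 1), n, replace = TRUE)
  noise <- matrix(rnorm(n * 3, sd = 1 / 10), n, 3)
  maps <- gen[cl, ] * signs + noise
  maps <- maps - rowMeans(maps)
  fit <- modifiedKMeans(maps, 2, restarts = 20, seed = 5)
  # oracle: leading eigenvector of each true cluster's scatter
  oracle <- t(vapply(1:2, function(k) {
    X <- maps[cl == k, ]
    eigen(crossprod(X))$vectors[, 1]
  }, numeric(3)))
  M <- abs(templateMaps(fit) %*% t(oracle))
  expect_true(all(apply(M, 2, max) > 0.99))
  # and each fitted template matches its generator
  Mg <- abs(templateMaps(fit) %*% t(gen))
  expect_true(all(apply(Mg, 2, max) > 0.99))
})

test_that("clustering is invariant to global sign flips and amplitude scaling", {
  A <- generateTemplates(10, 3, seed = 6)
  set.seed(7)
  maps <- A[rep(1:3, 40), ] + matrix(rnorm(1200, sd = 0.05), 120, 10)
  maps <- maps - rowMeans(maps)
  f1 <- modifiedKMeans(maps, 3, restarts = 5, seed = 8)
  f2 <- modifiedKMeans(-4.2 * maps, 3, restarts = 5, seed = 8)
  expect_equal(templateMaps(f1), templateMaps(f2), tolerance = 1e-8)
  expect_equal(gev(f1), gev(f2), tolerance = 1e-10)
})

test_that("GEV at the true K dominates smaller K on identifiable data", {
  A <- generateTemplates(10, 4, seed = 9)
  maps <- A[rep(1:4, 25), ]
  g4 <- gev(modifiedKMeans(maps, 4, restarts = 10, seed = 1))
  g2 <- gev(modifiedKMeans(maps, 2, restarts = 10, seed = 1))
  expect_equal(g4, 1, tolerance = 1e-9)
  expect_gt(g4, g2)
})

test_that("two-level fit: single subject passes through; cohorts recover maps", {
  A <- generateTemplates(14, 4, seed = 10)
  mkSub <- function(s) {
    withr::with_seed(100 + s, {
      m <- A[rep(1:4, 50), ] * sample(c(-1, 1), 200, replace = TRUE) +
        matrix(rnorm(200 * 14, sd = 0.1), 200, 14)
      m - rowMeans(m)
    })
  }
  one <- twoLevelFit(list(mkSub(1)), K = 4, restarts = 5, seed = 11)
  solo <- modifiedKMeans(mkSub(1), K = 4, restarts = 5, seed = 12)
  M1 <- abs(templateMaps(one) %*% t(templateMaps(solo)))
  expect_true(all(apply(M1, 1, max) > 0.999))
  cohort <- twoLevelFit(lapply(1:5, mkSub), K = 4, restarts = 5, seed = 13)
  M <- abs(templateMaps(cohort) %*% t(A))
  expect_gte(mean(apply(M, 2, max)), 0.95)
})

test_that("two disjoint populations are covered by the union-size group fit", {
  A <- generateTemplates(14, 4, seed = 14)
  mkSub <- function(rows, s) withr::with_seed(s, {
    m <- A[rep(rows, 60), ] + matrix(rnorm(120 * 14, sd = 0.05), 120, 14)
    m - rowMeans(m)
  })
  subs <- c(lapply(1:3, function(s) mkSub(1:2, 200 + s)),
            lapply(1:3, function(s) mkSub(3:4, 300 + s)))
  fit <- twoLevelFit(subs, K = 4, restarts = 20, seed = 15)
  # brute-force best assignment over all template permutations
  M <- abs(templateMaps(fit) %*% t(A))
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  best <- max(apply(perms, 1, function(p) min(M[cbind(p, 1:4)])))
  expect_gte(best, 0.9)
})

test_that("two-level fit is reproducible under fixed seeds", {
  A <- generateTemplates(10, 3, seed = 16)
  subs <- lapply(1:3, function(s) withr::with_seed(s, {
    m <- A[rep(1:3, 40), ] + matrix(rnorm(120 * 10, sd = 0.1), 120, 10)
    m - rowMeans(m)
  }))
  f1 <- twoLevelFit(subs, 3, restarts = 5, seed = 17)
  f2 <- twoLevelFit(subs, 3, restarts = 5, seed = 17)
  expect_identical(templateMaps(f1), templateMaps(f2))
})

test_that("selectK: zero residual everywhere ties to the smallest K", {
  A <- generateTemplates(10, 1, seed = 18)
  maps <- A[rep(1, 50), ] * rep(c(1, -1), 25)
  res <- selectK(list(maps), 1:4, restarts = 5, seed = 19)
  expect_equal(res@table$residualNoise, rep(0, 4), tolerance = 1e-12)
  expect_equal(res@selectedK, 1L)
})

test_that("selectK recovers the generator count under moderate noise", {
  A <- generateTemplates(16, 4, seed = 20)
  subs <- lapply(1:4, function(s) withr::with_seed(400 + s, {
    m <- A[rep(1:4, 100), ] * sample(c(-1, 1), 400, replace = TRUE) +
      matrix(rnorm(400 * 16, sd = 0.1), 400, 16)
    m - rowMeans(m)
  }))
  res <- selectK(subs, 2:8, restarts = 5, seed = 21)
  expect_equal(res@selectedK, 4L)
  expect_true(all(res@table$cv > 0))
  expect_true(all(is.finite(res@table$cv)))
})

test_that("selectK skips inadmissible K with a warning", {
  A <- generateTemplates(5, 2, seed = 22)
  maps <- A[rep(1:2, 30), ]
  expect_warning(res <- selectK(list(maps), 2:5, restarts = 3, seed = 23),
                 "CV undefined")
  expect_true(all(res@table$K < 4))
})

test_that("backfit labels by maximum absolute correlation with tie to lowest", {
  A <- generateTemplates(8, 3, seed = 24)
  ts <- new("TemplateSet", maps = A, gev = NA_real_,
            residualNoise = NA_real_, cv = NA_real_, seed = 1L,
            restarts = 1L, channelNames = colnames(A))
  # exact negated template -> its own label (polarity ignored)
  v <- -5 * A[3, ]
  tie <- (A[1, ] + A[2, ])  # equidistant from templates 1 and 2
  rec <- EEGRecording(cbind(v, tie), srate = 100,
                      channelNames = colnames(A))
  sq <- backfitSequence(rec, ts)
  expect_equal(stateLabels(sq)[1], 3L)
  expect_equal(stateLabels(sq)[2], 1L)
  # each template map back-fits to its own label
  recA <- EEGRecording(t(A), srate = 100, channelNames = colnames(A))
  expect_equal(stateLabels(backfitSequence(recA, ts)), 1:3)
})

test_that("backfit reproduces a noiseless rendered label path exactly", {
  A <- generateTemplates(12, 4, seed = 25)
  path <- generateMarkovSequence(800, metastableChain(rep(.25, 4), 0.9),
                                 seed = 26)
  x <- renderEEG(path, A, snr = Inf, seed = 27, srate = 250)
  rec <- EEGRecording(x, srate = 250, channelNames = colnames(A))
  ts <- new("TemplateSet", maps = A, gev = NA_real_,
            residualNoise = NA_real_, cv = NA_real_, seed = 1L,
            restarts = 1L, channelNames = colnames(A))
  expect_equal(stateLabels(backfitSequence(rec, ts)), path)
})

test_that("backfit rejects mismatched channel sets", {
  A <- generateTemplates(8, 2, seed = 28)
  ts <- new("TemplateSet", maps = A, gev = NA_real_,
            residualNoise = NA_real_, cv = NA_real_, seed = 1L,
            restarts = 1L, channelNames = colnames(A))
  rec <- EEGRecording(matrix(rnorm(8 * 10), 8), srate = 100,
                      channelNames = sprintf("x%02d", 1:8))
  expect_error(backfitSequence(rec, ts), class = "msbridgeSchemaError")
})

test_that("modified k-means rejects K >= n", {
  expect_error(modifiedKMeans(matrix(rnorm(20), 4, 5), K = 4),
               class = "msbridgeParameterError")
})
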