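test_that("membership update matches the closed form", {
  V <- rbind(c(0, 0), c(3, 0))
  # point at distance 1 and 2 from the two centroids, m = 2:
  # u1 = 1/(1 + (1/2)^2) = 0.8
  U <- fcmMemberships(rbind(c(1, 0)), V, m = 2)
  expect_equal(unname(U[1, ]), c(0.8, 0.2))

  # coincidence with a centroid: degenerate one-hot convention
  V3 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(unname(fcmMemberships(rbind(c(0, 0)), V3, 2)[1, ]),
               c(1, 0, 0))

  # circumcenter of an equilateral triangle is equidistant from all three
  # centroids: uniform membership
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  eq <- fcmMemberships(rbind(c(0.5, sqrt(3) / 6)), tri, 2)
  expect_equal(unname(eq[1, ]), rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(fcmMemberships(rbind(c(0, 0)), rbind(c(1, 1), c(1, 1)), 2),
               "duplicate centroids")
  expect_error(fcmMemberships(rbind(c(0, 0)), V, m = 1), "exceed 1")
})

test_that("membership rows always sum to 1 and lie in [0, 1]", {
  set.seed(7)
  for (i in 1:10) {
    X <- matrix(runif(40 * 3), 40, 3)
    V <- X[sample(40, 4), ]
    U <- fcmMemberships(X, V, m = runif(1, 1.2, 3))
    expect_true(all(U >= 0 & U <= 1))
    expect_equal(rowSums(U), rep(1, 40), tolerance = 1e-9)
  }
})

test_that("fitting recovers separated clouds; objective decreases; hull holds", {
  set.seed(15)
  means <- rbind(c(0.70, 0.10, 0.14, 0.06),
                 c(0.40, 0.15, 0.33, 0.12),
                 c(0.17, 0.10, 0.20, 0.53))
  X <- rbind(simplexCloud(means[1, ], 60), simplexCloud(means[2, ], 60),
             simplexCloud(means[3, ], 60))
  colnames(X) <- c("delta", "high_theta", "alpha", "beta")
  truth <- rep(1:3, each = 60)
  fit <- fcmFit(X, c = 3, m = 2, tol = 1e-6, seed = 2)

  p <- matchCentroids(means, centroids(fit))
  expect_lt(max(abs(centroids(fit)[p, ] - means)), 0.05)

  U <- fcmMemberships(X, centroids(fit), 2)
  expect_gt(min(vapply(1:3, function(k)
    mean(U[truth == k, p[k]]), 0)), 0.9)

  # J_m non-increasing across iterations of the winning restart
  expect_true(all(diff(fit@objectiveTrace) <= 1e-12))

  # centroids in the convex hull of the data (coordinate-wise bounds +
  # simplex structure)
  expect_true(all(t(centroids(fit)) >= apply(X, 2, min) - 1e-12))
  expect_true(all(t(centroids(fit)) <= apply(X, 2, max) + 1e-12))
  expect_equal(unname(rowSums(centroids(fit))), rep(1, 3), tolerance = 1e-9)
})

test_that("n == c distinct points give a perfect fit", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1))
  fit <- fcmFit(X, c = 3, m = 2, tol = 1e-9, nRestarts = 3, seed = 1)
  p <- matchCentroids(X, centroids(fit))
  expect_lt(max(abs(centroids(fit)[p, ] - X)), 1e-4)
  expect_lt(objectiveValue(fit), 1e-6)
})

test_that("fits are bit-reproducible given the seed", {
  set.seed(99)
  X <- simplexCloud(c(0.4, 0.2, 0.25, 0.15), 50)
  f1 <- fcmFit(X, seed = 12)
  f2 <- fcmFit(X, seed = 12)
  expect_identical(centroids(f1), centroids(f2))
  expect_identical(objectiveValue(f1), objectiveValue(f2))
  expect_error(fcmFit(X[1:2, ]), "at least c")
})

test_that("converged solutions agree with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(31)
  nAgree <- 0L
  for (i in 1:20) {
    n <- sample(20:50, 1)
    X <- rbind(simplexCloud(c(0.7, 0.1, 0.14, 0.06), ceiling(n / 3)),
               simplexCloud(c(0.4, 0.15, 0.33, 0.12), ceiling(n / 3)),
               simplexCloud(c(0.17, 0.1, 0.2, 0.53), ceiling(n / 3)))
    fit <- fcmFit(X, c = 3, m = 2, tol = 1e-10, maxIter = 1000,
                  nRestarts = 5, seed = i)
    ref <- e1071::cmeans(X, centers = centroids(fit), m = 2,
                         iter.max = 1000)
    p <- matchCentroids(centroids(fit), ref$centers)
    expect_lt(max(abs(ref$centers[p, ] - centroids(fit))), 1e-4)
    Umine <- fcmMemberships(X, centroids(fit), 2)
    expect_lt(max(abs(ref$membership[, p] - Umine)), 1e-4)
    nAgree <- nAgree + 1L
  }
  expect_equal(nAgree, 20L)
})

test_that("memberships harden toward nearest centroid as m approaches 1", {
  set.seed(8)
  X <- rbind(simplexCloud(c(0.7, 0.1, 0.14, 0.06), 30),
             simplexCloud(c(0.17, 0.1, 0.2, 0.53), 30))
  V <- rbind(c(0.7, 0.1, 0.14, 0.06), c(0.17, 0.1, 0.2, 0.53))
  U <- fcmMemberships(X, V, m = 1.05)
  nearest <- max.col(-as.matrix(stats::dist(rbind(X, V)))[1:60, 61:62])
  expect_true(all(U[cbind(1:60, nearest)] > 0.99))
})

test_that("centroid labeling follows the delta/beta rule and permutes with order", {
  V <- rbind(c(0.70, 0.10, 0.14, 0.06),   # deep: max delta
             c(0.40, 0.15, 0.33, 0.12),   # proper
             c(0.20, 0.10, 0.20, 0.50))   # slight: max beta
  colnames(V) <- c("delta", "high_theta", "alpha", "beta")
  mk <- function(Vm) new("FCMModel", centroids = Vm, m = 2, tol = 0.005,
                         maxIter = 300L, nRestarts = 1L, seed = 1L,
                         objective = 0, objectiveTrace = numeric(),
                         converged = TRUE,
                         labelMap = rep(NA_character_, nrow(Vm)),
                         featureSpace = "full4d")
  lab <- labelMap(assignDepthLabels(mk(V)))
  expect_equal(lab, c("deep", "proper", "slight"))

  perm <- c(3, 1, 2)
  labP <- labelMap(assignDepthLabels(mk(V[perm, ])))
  expect_equal(labP, lab[perm])

  Vtie <- V; Vtie[2, ] <- Vtie[1, c(1, 3, 2, 4)]  # same delta as row 1
  expect_error(assignDepthLabels(mk(Vtie)), "tie on the delta")
  expect_error(assignDepthLabels(mk(V[1:2, ])), "exactly 3")
})

test_that("applying a model yields consistent hard labels and tie-breaking", {
  V <- rbind(c(0.70, 0.10, 0.14, 0.06),
             c(0.40, 0.15, 0.33, 0.12),
             c(0.20, 0.10, 0.20, 0.50))
  colnames(V) <- c("delta", "high_theta", "alpha", "beta")
  model <- assignDepthLabels(new("FCMModel", centroids = V, m = 2,
    tol = 0.005, maxIter = 300L, nRestarts = 1L, seed = 1L, objective = 0,
    objectiveTrace = numeric(), converged = TRUE,
    labelMap = rep(NA_character_, 3), featureSpace = "full4d"))

  feats <- depthFeatureSet(t(V), c(0, 28, 56))  # epochs at the centroids
  ser <- applyModel(feats, model)
  expect_equal(hardLabels(ser), c("deep", "proper", "slight"))
  expect_equal(confidence(ser), c(1, 1, 1))
  expect_equal(colSums(memberships(ser)), rep(1, 3),
               tolerance = 1e-9, ignore_attr = TRUE)

  # midpoint between proper and deep centroids: exact tie -> proper
  mid <- (V[1, ] + V[2, ]) / 2
  serMid <- applyModel(depthFeatureSet(cbind(mid), 0), model)
  expect_equal(hardLabels(serMid), "proper")

  expect_error(applyModel(matrix(0.5, 1, 2), model), "dimension")
  unlab <- new("FCMModel", centroids = V, m = 2, tol = 0.005,
               maxIter = 300L, nRestarts = 1L, seed = 1L, objective = 0,
               objectiveTrace = numeric(), converged = TRUE,
               labelMap = rep(NA_character_, 3), featureSpace = "full4d")
  expect_error(applyModel(feats, unlab), "unlabeled")
})

test_that("temporal smoothing removes single-epoch flicker and keeps identities", {
  U <- matrix(0, 3, 9, dimnames = list(c("slight", "proper", "deep"), NULL))
  U["proper", ] <- 0.9; U["slight", ] <- 0.05; U["deep", ] <- 0.05
  U[, 5] <- c(0.05, 0.05, 0.9)[c(1, 2, 3)]  # deep flicker at epoch 5
  U[, 5] <- c(slight = 0.05, proper = 0.05, deep = 0.9)
  ser <- membershipSeries(U, seq(0, by = 28, length.out = 9),
                          c(rep("proper", 4), "deep", rep("proper", 4)),
                          apply(U, 2, max))
  expect_identical(smoothLabels(ser, 0L), ser)
  sm <- smoothLabels(ser, 2L)
  expect_equal(hardLabels(sm), rep("proper", 9))
  expect_equal(colSums(memberships(sm)), rep(1, 9), ignore_attr = TRUE)

  # constant series unchanged
  Uc <- matrix(c(0.2, 0.5, 0.3), 3, 6,
               dimnames = list(c("slight", "proper", "deep"), NULL))
  serC <- membershipSeries(Uc, 1:6, rep("proper", 6), rep(0.5, 6))
  expect_equal(memberships(smoothLabels(serC, 2L)), memberships(serC))
})

test_that("model JSON round trip reproduces the model exactly", {
  set.seed(5)
  X <- simplexCloud(c(0.4, 0.2, 0.25, 0.15), 40)
  colnames(X) <- c("delta", "high_theta", "alpha", "beta")
  fit <- assignDepthLabels(fcmFit(rbind(
    simplexCloud(c(0.7, 0.1, 0.14, 0.06), 30),
    simplexCloud(c(0.4, 0.15, 0.33, 0.12), 30),
    simplexCloud(c(0.17, 0.1, 0.2, 0.53), 30)), seed = 4))
  p <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(fit, p)
  back <- readModelJSON(p)
  expect_equal(centroids(back), centroids(fit))
  expect_equal(labelMap(back), labelMap(fit))
  expect_equal(back@m, fit@m)
  expect_equal(back@objective, fit@objective)
})

test_that("partition coefficient spans crisp to uniform", {
  Ucrisp <- matrix(c(1, 0, 0), 3, 5,
                   dimnames = list(c("slight", "proper", "deep"), NULL))
  serCrisp <- membershipSeries(Ucrisp, 1:5, rep("slight", 5), rep(1, 5))
  expect_equal(partitionCoefficient(serCrisp), 1)
  expect_equal(partitionCoefficient(matrix(1 / 3, 10, 3)), 1 / 3)
})
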