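#' @include AllClasses.R features.R
NULL

#' Fuzzy C-Means membership update
#'
#' Standard FCM memberships under Euclidean distance:
#' \deqn{u_{ik} = \Big[\sum_{j=1}^{c} (d_{ik}/d_{jk})^{2/(m-1)}\Big]^{-1}}
#' where \eqn{d_{ik}} is the distance of point k to centroid i. When a point
#' coincides with a centroid the degenerate convention applies: membership 1
#' for that centroid and 0 elsewhere. Every row sums to 1.
#'
#' @param X n x d data matrix.
#' @param V c x d centroid matrix with distinct rows.
#' @param m fuzziness exponent (> 1).
#' @return n x c membership matrix.
#' @examples
#' V <- rbind(c(0, 0), c(1, 0))
#' fcmMemberships(rbind(c(0.2, 0)), V, m = 2)  # (0.8, 0.2): d1=0.2, d2=0.8...
#' @export
fcmMemberships <- function(X, V, m = 2) {
  X <- as.matrix(X); V <- as.matrix(V)
  if (m <= 1) stop("fuzziness exponent m must exceed 1")
  if (anyDuplicated(as.data.frame(V))) stop("duplicate centroids")
  D2 <- distSq(X, V)                       # n x c squared distances
  expo <- 1 / (m - 1)
  U <- 1 / (D2^expo * rowSums((1 / D2)^expo))  # = 1/sum_j (d_ik/d_jk)^(2/(m-1))
  zero <- D2 <= 0
  hit <- rowSums(zero) > 0L | !is.finite(rowSums(U))
  if (any(hit)) {
    U[hit, ] <- 0
    U[cbind(which(hit), max.col(-D2[hit, , drop = FALSE]))] <- 1
  }
  pmin(pmax(U, 0), 1)  # guard against last-ulp overshoot
}

# squared Euclidean distances between rows of X (n x d) and V (c x d)
distSq <- function(X, V) {
  n <- nrow(X); cc <- nrow(V)
  D2 <- matrix(rowSums(X^2), n, cc) +
        matrix(rowSums(V^2), n, cc, byrow = TRUE) - 2 * X %*% t(V)
  pmax(D2, 0)
}

fcmObjective <- function(X, V, U, m) sum(U^m * distSq(X, V))

fcmUpdateCentroids <- function(X, U, m) {
  W <- U^m
  V <- t(W) %*% X / colSums(W)
  V
}

# one seeded run of alternating FCM updates
fcmRunOnce <- function(X, c, m, tol, maxIter) {
  n <- nrow(X)
  V <- X[sample.int(n, c), , drop = FALSE]
  # re-draw (bounded) if the init picked duplicate rows
  tries <- 0L
  while (anyDuplicated(as.data.frame(V)) && tries < 50L) {
    V <- X[sample.int(n, c), , drop = FALSE]
    tries <- tries + 1L
  }
  if (anyDuplicated(as.data.frame(V)))
    stop("could not draw ", c, " distinct initial centroids from the data")
  U <- fcmMemberships(X, V, m)
  trace <- numeric()
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    V <- fcmUpdateCentroids(X, U, m)
    Unew <- fcmMemberships(X, V, m)
    trace <- c(trace, fcmObjective(X, V, Unew, m))
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta <= tol) { converged <- TRUE; break }
  }
  list(V = V, U = U, J = trace[length(trace)], trace = trace,
       converged = converged, iters = length(trace))
}

#' Fit a global Fuzzy C-Means model
#'
#' Alternates the membership and centroid updates
#' \eqn{v_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m}
#' from a seeded random initialization (centroids drawn as data rows) until
#' the maximum absolute change of the membership matrix falls to `tol`, or
#' `maxIter` is reached. Over `nRestarts` restarts the model with the lowest
#' objective \eqn{J_m = \sum_i\sum_k u_{ik}^m d_{ik}^2} wins. Deterministic
#' given `seed`.
#'
#' The "global" model of the depth pipeline is fitted once on the pooled
#' feature matrix of all recordings; per-subject application
#' ([applyModel()]) never refits.
#'
#' @param X n x d feature matrix (or a [DepthFeatureSet-class]).
#' @param c number of clusters (default 3: slight / proper / deep).
#' @param m fuzziness exponent (default 2).
#' @param tol convergence threshold on the membership change (default 0.005).
#' @param maxIter iteration cap per restart.
#' @param nRestarts random restarts (default 10).
#' @param seed RNG seed; the fit is bit-reproducible given the same data and
#'   seed.
#' @param featureSpace `"full4d"` or `"paper2d"`, recorded on the model.
#' @return An [FCMModel-class] (unlabeled; see [assignDepthLabels()]). When
#'   no restart reached `tol` the model carries `converged = FALSE` with a
#'   warning.
#' @export
fcmFit <- function(X, c = 3, m = 2, tol = 0.005, maxIter = 300L,
                   nRestarts = 10L, seed = 1L,
                   featureSpace = c("full4d", "paper2d")) {
  featureSpace <- match.arg(featureSpace)
  if (is(X, "DepthFeatureSet")) X <- featureMatrix(X, featureSpace)
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("feature matrix must be finite")
  if (c < 2) stop("need c >= 2 clusters")
  if (nrow(X) < c) stop("need at least c = ", c, " data rows, got ", nrow(X))
  if (m <= 1) stop("fuzziness exponent m must exceed 1")
  if (tol <= 0) stop("tol must be positive")

  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nRestarts)) {
      run <- fcmRunOnce(X, c, m, tol, as.integer(maxIter))
      if (is.null(best) || run$J < best$J) best <- run
    }
  })
  if (!best$converged)
    warning("FCM did not reach tol = ", tol, " within ", maxIter,
            " iterations")
  V <- best$V
  if (is.null(colnames(X))) {
    if (featureSpace == "full4d" && ncol(X) == 4L)
      colnames(V) <- DEPTH_BAND_NAMES
    else if (featureSpace == "paper2d" && ncol(X) == 2L)
      colnames(V) <- c("delta", "alpha_high_theta")
  } else colnames(V) <- colnames(X)
  new("FCMModel", centroids = V, m = as.numeric(m), tol = as.numeric(tol),
      maxIter = as.integer(maxIter), nRestarts = as.integer(nRestarts),
      seed = as.integer(seed), objective = best$J,
      objectiveTrace = best$trace, converged = best$converged,
      labelMap = rep(NA_character_, c), featureSpace = featureSpace)
}

#' Label centroids as slight / proper / deep
#'
#' Post hoc physiological labeling of a 3-cluster model from centroid
#' spectral character: the centroid with the greatest delta ratio is `deep`
#' (delta dominance marks cortical suppression); among the remaining two, the
#' centroid with the greatest beta ratio (in the 2-D view: the smallest
#' delta + alpha + high-theta sum, i.e. the largest implied beta) is `slight`
#' (beta-rich light hypnosis); the remainder is `proper`.
#'
#' @param model a fitted [FCMModel-class] with `c == 3`.
#' @return The model with a bijective `labelMap`.
#' @section Errors: when two centroids tie on a deciding coordinate within
#'   1e-9 the labeling is ambiguous and an error is raised (refit with
#'   another seed).
#' @export
assignDepthLabels <- function(model) {
  V <- centroids(model)
  if (nrow(V) != 3L) stop("depth labeling requires exactly 3 clusters")
  if (model@featureSpace == "full4d") {
    deltaV <- V[, "delta"]; betaV <- V[, "beta"]
  } else {
    deltaV <- V[, "delta"]; betaV <- 1 - rowSums(V)
  }
  ord <- order(deltaV, decreasing = TRUE)
  if (deltaV[ord[1]] - deltaV[ord[2]] < 1e-9)
    stop("labeling ambiguous: two centroids tie on the delta ratio")
  deep <- ord[1]
  rest <- setdiff(seq_len(3L), deep)
  if (abs(betaV[rest[1]] - betaV[rest[2]]) < 1e-9)
    stop("labeling ambiguous: remaining centroids tie on the beta ratio")
  slight <- rest[which.max(betaV[rest])]
  proper <- setdiff(rest, slight)
  lm <- character(3L)
  lm[deep] <- "deep"; lm[slight] <- "slight"; lm[proper] <- "proper"
  model@labelMap <- lm
  validObject(model)
  model
}

#' Apply fixed global centroids to a recording's features
#'
#' Computes fuzzy memberships of every epoch against the model's fixed
#' centroids (no refitting) and the simplified hard track: the label of the
#' maximal membership, with ties broken toward `proper`, then `deep` (the
#' clinically conservative middle state first).
#'
#' @param features a [DepthFeatureSet-class] (or a plain matrix in the
#'   model's feature space).
#' @param model a labeled [FCMModel-class].
#' @return A [MembershipSeries-class]; assay rows are named by depth label.
#' @export
applyModel <- function(features, model) {
  if (anyNA(labelMap(model)))
    stop("model is unlabeled: run assignDepthLabels() first")
  times <- NULL
  subj <- "anonymous"
  if (is(features, "DepthFeatureSet")) {
    times <- epochTimes(features)
    subj <- S4Vectors::metadata(features)$subjectId
    X <- featureMatrix(features, model@featureSpace)
  } else {
    X <- as.matrix(features)
    times <- seq_len(nrow(X)) - 1
  }
  if (ncol(X) != ncol(centroids(model)))
    stop("feature dimension (", ncol(X), ") does not match the model (",
         ncol(centroids(model)), ")")
  U <- fcmMemberships(X, centroids(model), model@m)
  colnames(U) <- labelMap(model)
  # argmax with tie preference proper > deep > slight
  pref <- c(proper = 3L, deep = 2L, slight = 1L)
  hard <- apply(U, 1, function(u) {
    top <- which(u >= max(u) - 1e-12)
    names(u)[top][which.max(pref[names(u)[top]])]
  })
  membershipSeries(t(U)[DEPTH_LABELS, , drop = FALSE], times,
                   hard, apply(U, 1, max), subjectId = subj)
}

#' Temporal smoothing of membership traces
#'
#' Optional post hoc stabilizer for frame-by-frame "flicker": each epoch's
#' membership vector is replaced by the mean over a window of
#' `2 * halfWidth + 1` epochs (truncated at the ends), renormalized, and the
#' hard labels recomputed under the same tie rule. `halfWidth = 0` is the
#' identity. Off by default in the pipeline; exposed but not clinically
#' validated.
#'
#' @param series a [MembershipSeries-class].
#' @param halfWidth window half-width in epochs (>= 0).
#' @return A smoothed [MembershipSeries-class].
#' @export
smoothLabels <- function(series, halfWidth = 0L) {
  stopifnot(halfWidth >= 0)
  if (halfWidth == 0L) return(series)
  U <- memberships(series)            # clusters x epochs
  n <- ncol(U)
  S <- U
  for (k in seq_len(n)) {
    a <- max(1L, k - halfWidth); b <- min(n, k + halfWidth)
    S[, k] <- rowMeans(U[, a:b, drop = FALSE])
  }
  S <- sweep(S, 2, colSums(S), "/")
  pref <- c(proper = 3L, deep = 2L, slight = 1L)
  hard <- apply(S, 2, function(u) {
    top <- which(u >= max(u) - 1e-12)
    rownames(S)[top][which.max(pref[rownames(S)[top]])]
  })
  membershipSeries(S, epochTimes(series), hard, apply(S, 2, max),
                   subjectId = S4Vectors::metadata(series)$subjectId)
}

#' Fuzzy partition coefficient
#'
#' Diagnostic cluster-validity index \eqn{F_c = \frac1n \sum_k \sum_i
#' u_{ik}^2}; 1 for a crisp partition, \eqn{1/c} for the uniform one.
#'
#' @param series a [MembershipSeries-class] (or membership matrix, epochs in
#'   rows).
#' @return Scalar in `[1/c, 1]`.
#' @export
partitionCoefficient <- function(series) {
  U <- if (is(series, "MembershipSeries")) t(memberships(series)) else series
  mean(rowSums(U^2))
}

#' Persist / load a fitted model as JSON
#'
#' The JSON document carries `c`, `m`, `tol`, the centroid matrix with its
#' column names, the feature space, label map, seed and final objective, so a
#' fit is fully reproducible and portable.
#'
#' @param model a [FCMModel-class].
#' @param path JSON file path.
#' @export
writeModelJSON <- function(model, path) {
  doc <- list(
    c = nrow(centroids(model)), m = model@m, tol = model@tol,
    max_iter = model@maxIter, n_restarts = model@nRestarts,
    seed = model@seed, objective = model@objective,
    converged = model@converged, feature_space = model@featureSpace,
    feature_names = colnames(centroids(model)),
    centroids = unname(apply(centroids(model), 1, as.numeric,
                             simplify = FALSE)),
    label_map = as.list(labelMap(model))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- doc$centroids
  if (is.list(V)) V <- do.call(rbind, lapply(V, as.numeric))
  V <- as.matrix(V)
  colnames(V) <- unlist(doc$feature_names)
  lm <- unlist(doc$label_map)
  lm[lm == "NA" | is.na(lm)] <- NA_character_
  new("FCMModel", centroids = V, m = doc$m, tol = doc$tol,
      maxIter = as.integer(doc$max_iter), nRestarts = as.integer(doc$n_restarts),
      seed = as.integer(doc$seed), objective = doc$objective,
      objectiveTrace = numeric(), converged = doc$converged,
      labelMap = lm, featureSpace = doc$feature_space)
}

#' Export a membership series as CSV
#'
#' Columns `t_start_s, u_slight, u_proper, u_deep, hard_label, confidence`.
#'
#' @param series a [MembershipSeries-class].
#' @param path CSV path.
#' @export
writeMembershipCSV <- function(series, path) {
  U <- memberships(series)
  df <- data.frame(t_start_s = epochTimes(series),
                   u_slight = U["slight", ], u_proper = U["proper", ],
                   u_deep = U["deep", ], hard_label = hardLabels(series),
                   confidence = confidence(series))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
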