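#' @include AllClasses.R fcm.R pipeline.R
NULL

depthPalette <- c(slight = "#2ca02c", proper = "#1f77b4", deep = "#d62728")

#' Cluster scatter in the 2-D feature view
#'
#' Scatter of all epochs with the delta ratio on x and the alpha + high-theta
#' ratio on y, colored by hard depth label and shaded by membership
#' confidence; centroids (projected if the model is 4-D) overplotted.
#'
#' @param pooled pooled full4d or paper2d feature matrix (e.g.
#'   `runFit()$pooled`).
#' @param model a labeled [FCMModel-class].
#' @return A ggplot object.
#' @export
plotClusterScatter <- function(pooled, model) {
  proj <- function(M) {
    if (ncol(M) == 4L) cbind(M[, "delta"], M[, "alpha"] + M[, "high_theta"])
    else M
  }
  U <- fcmMemberships(pooled, centroids(model), model@m)
  colnames(U) <- labelMap(model)
  P <- proj(pooled)
  df <- data.frame(x = P[, 1], y = P[, 2],
                   label = labelMap(model)[max.col(U)],
                   conf = apply(U, 1, max))
  Vc <- proj(centroids(model))
  cent <- data.frame(x = Vc[, 1], y = Vc[, 2], label = labelMap(model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$label,
                                     alpha = .data$conf), size = 0.8) +
    ggplot2::geom_point(data = cent, shape = 4, size = 4, stroke = 2) +
    ggplot2::scale_color_manual(values = depthPalette, name = "depth") +
    ggplot2::scale_alpha(range = c(0.25, 1), guide = "none") +
    ggplot2::labs(x = "delta power ratio",
                  y = "alpha + high-theta power ratio") +
    ggplot2::theme_minimal()
}

#' Four-panel synchronized depth report
#'
#' The per-recording report: (A) depth-index trace when available, (B) fuzzy
#' membership traces of the three clusters, (C) the simplified hard-label
#' track, (D) the DSA time-frequency image — all sharing one time axis in
#' minutes.
#'
#' @param result output of [runApply()].
#' @return A patchwork object (stack of ggplots).
#' @export
plotDepthPanels <- function(result) {
  tmin <- function(s) s / 60
  series <- result$membership
  U <- memberships(series)
  times <- tmin(epochTimes(series))
  xlim <- range(times)

  memDf <- data.frame(
    t = rep(times, each = nrow(U)),
    label = rep(rownames(U), ncol(U)),
    u = as.vector(U))
  pB <- ggplot2::ggplot(memDf, ggplot2::aes(x = .data$t, y = .data$u,
                                            color = .data$label)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_color_manual(values = depthPalette, name = NULL) +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(y = "membership", x = NULL) +
    ggplot2::theme_minimal()

  hardDf <- data.frame(t = times, label = hardLabels(series))
  pC <- ggplot2::ggplot(hardDf, ggplot2::aes(x = .data$t,
                                             y = .data$label,
                                             color = .data$label)) +
    ggplot2::geom_point(shape = 15, size = 1.6, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = depthPalette) +
    ggplot2::scale_y_discrete(limits = c("deep", "proper", "slight")) +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(y = "depth", x = NULL) +
    ggplot2::theme_minimal()

  dsa <- result$dsa
  dsaDf <- expand.grid(t = tmin(epochTimes(dsa)), f = freqGrid(dsa))
  dsaDf$db <- as.vector(powerDb(dsa))
  pD <- ggplot2::ggplot(dsaDf, ggplot2::aes(x = .data$t, y = .data$f,
                                            fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::coord_cartesian(xlim = xlim, expand = FALSE) +
    ggplot2::labs(y = "frequency (Hz)", x = "time (min)") +
    ggplot2::theme_minimal()

  panels <- list(pB, pC, pD)
  if (!is.null(result$psi)) {
    psiDf <- data.frame(t = tmin(result$psi@times), v = result$psi@values)
    pA <- ggplot2::ggplot(psiDf, ggplot2::aes(x = .data$t, y = .data$v)) +
      ggplot2::geom_line(color = "grey30") +
      ggplot2::coord_cartesian(xlim = xlim, ylim = c(0, 100)) +
      ggplot2::labs(y = "depth index", x = NULL) +
      ggplot2::theme_minimal()
    panels <- c(list(pA), panels)
  }
  patchwork::wrap_plots(panels, ncol = 1)
}
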