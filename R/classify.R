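#' Classify SNc units by spike duration
#'
#' Nigral units with a spike duration (spike onset to first positive peak of
#' the averaged waveform) shorter than 800 microseconds are putative
#' GABAergic cells; wider spikes are putative dopamine neurons. The
#' comparison is strict, so exactly 800 us classifies as dopaminergic.
#'
#' @param duration_us Spike duration(s), microseconds; must be positive.
#' @param threshold_us Classification threshold; default 800.
#' @return Character vector, `"putative_GABA"` or `"putative_DAN"`.
#' @export
snc_classify <- function(duration_us, threshold_us = 800) {
  if (any(!is.finite(duration_us)) || any(duration_us <= 0)) {
    stop("duration_us must be positive and finite")
  }
  ifelse(duration_us < threshold_us, "putative_GABA", "putative_DAN")
}

#' Mediolateral recording-site split
#'
#' Recording positions are assigned to the medial (0.8--1.8 mm lateral from
#' bregma) or lateral (1.8--2.4 mm) division; the 1.8 mm boundary belongs to
#' the lateral interval.
#'
#' @param ml_position_mm Lateral coordinate(s), mm from bregma.
#' @return Character vector, `"medial"` or `"lateral"`.
#' @export
mediolateral_split <- function(ml_position_mm) {
  if (any(!is.finite(ml_position_mm)) ||
      any(ml_position_mm < 0.8) || any(ml_position_mm > 2.4)) {
    stop("ml_position_mm outside the recorded range [0.8, 2.4] mm")
  }
  ifelse(ml_position_mm < 1.8, "medial", "lateral")
}

#' K-means classification of striatal units
#'
#' Clusters units on three standardized features --- ongoing spike rate,
#' spike (peak-to-valley) duration, and the coefficient of variation of the
#' inter-spike interval --- and names the clusters by centroid physiology:
#' the narrowest-waveform cluster is the fast-spiking interneurons (FSI), the
#' higher-rate cluster of the remaining two the tonically active neurons
#' (TAN), and the last the projection neurons (SPN). Cluster separation is
#' summarised by the mean silhouette value.
#'
#' @param features Data frame with numeric columns `ongoing_rate` (Hz),
#'   `spike_duration_us`, `cv_isi`.
#' @param k Number of clusters; default 3.
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of random restarts; default 50.
#' @return Object of class `striatal_kmeans`: `labels` (character
#'   `"SPN"`/`"TAN"`/`"FSI"` per unit, `NA` when degenerate),
#'   `silhouette` (mean), `centers` (feature-space centroids),
#'   `cluster` (raw k-means cluster indices), `flagged`.
#' @export
striatal_kmeans <- function(features, k = 3L, seed = 1L, nstart = 50L) {
  need <- c("ongoing_rate", "spike_duration_us", "cv_isi")
  if (!all(need %in% names(features))) {
    stop("features must contain columns: ", paste(need, collapse = ", "))
  }
  X <- as.matrix(features[, need])
  if (any(!is.finite(X))) stop("features must be finite")
  n <- nrow(X)
  if (n < k) stop("need at least k = ", k, " units, got ", n)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0) || nrow(unique(X)) < k) {
    return(structure(list(labels = rep(NA_character_, n),
                          silhouette = NA_real_, centers = NULL,
                          cluster = rep(NA_integer_, n), flagged = TRUE),
                     class = "striatal_kmeans"))
  }
  Z <- scale(X)
  km <- withr::with_seed(seed, stats::kmeans(Z, centers = k, nstart = nstart,
                                             iter.max = 100L))
  sil <- cluster::silhouette(km$cluster, stats::dist(Z))
  centers_raw <- t(vapply(seq_len(k), function(j) {
    colMeans(X[km$cluster == j, , drop = FALSE])
  }, numeric(3)))
  colnames(centers_raw) <- need
  name <- rep(NA_character_, k)
  if (k == 3L) {
    fsi <- which.min(centers_raw[, "spike_duration_us"])
    rest <- setdiff(seq_len(3L), fsi)
    tan <- rest[which.max(centers_raw[rest, "ongoing_rate"])]
    spn <- setdiff(rest, tan)
    name[fsi] <- "FSI"; name[tan] <- "TAN"; name[spn] <- "SPN"
  } else {
    name <- paste0("cluster", seq_len(k))
  }
  rownames(centers_raw) <- name
  structure(list(labels = name[km$cluster],
                 silhouette = mean(sil[, "sil_width"]),
                 centers = centers_raw, cluster = km$cluster,
                 flagged = FALSE),
            class = "striatal_kmeans")
}

#' @export
print.striatal_kmeans <- function(x, ...) {
  if (x$flagged) {
    cat("Striatal k-means: degenerate input, no clustering performed\n")
    return(invisible(x))
  }
  cat("Striatal k-means classification\n")
  print(round(x$centers, 2))
  cat(sprintf("  counts: %s\n",
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  mean silhouette %.3f\n", x$silhouette))
  invisible(x)
}
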