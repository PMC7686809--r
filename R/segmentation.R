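# Microstate segmentation: GFP peak extraction, polarity-invariant AAHC over
# peak topographies, cross-validation model selection, global explained
# variance.

#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the scalp map at time t,
#' `sqrt(mean((v_i - vbar)^2))` over channels — the per-sample strength of the
#' topography. It is invariant to reference shifts (which only move the
#' spatial mean).
#'
#' @param maps Channels x samples numeric matrix (or an [eeg_recording()]).
#' @return Numeric vector of nonnegative GFP values, one per sample.
#' @export
compute_gfp <- function(maps) {
  if (inherits(maps, "eeg_recording")) maps <- maps$data
  if (nrow(maps) < 2L) stopf("GFP needs at least 2 channels")
  centered <- sweep(maps, 2L, colMeans(maps), "-")
  sqrt(colMeans(centered^2))
}

#' Locate local maxima of a GFP series
#'
#' An interior sample is a peak if it is strictly greater than its neighbors;
#' a plateau of equal values bounded by smaller neighbors contributes its
#' first sample. Endpoints are never peaks.
#'
#' @param gfp Numeric vector (length >= 3).
#' @return Integer vector of (1-based) peak indices; may be empty.
#' @export
find_gfp_peaks <- function(gfp) {
  n <- length(gfp)
  if (n < 3L) stopf("series too short to have interior peaks")
  # Collapse plateaus to single runs, find runs higher than both neighbors.
  r <- rle(gfp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  if (m < 3L) return(integer(0))
  interior <- 2:(m - 1L)
  is_peak <- r$values[interior] > r$values[interior - 1L] &
    r$values[interior] > r$values[interior + 1L]
  starts[interior][is_peak]
}

#' Spatial correlation and global map dissimilarity between two maps
#'
#' Both maps are mean-removed and GFP-normalized; C is their Pearson spatial
#' correlation and GMD the root-mean-square difference of the normalized maps,
#' related by `GMD^2 = 2 (1 - C)`. With `polarity_invariant = TRUE` the sign
#' minimizing GMD is taken, so C = |C| and GMD is the smaller of the two.
#'
#' @param u,v Numeric channel vectors (same length, >= 2 channels, nonflat).
#' @param polarity_invariant Disregard map polarity (default `TRUE`).
#' @return A list with elements `C` and `gmd`.
#' @export
spatial_similarity <- function(u, v, polarity_invariant = TRUE) {
  if (length(u) != length(v)) stopf("maps must have the same number of channels")
  u0 <- u - mean(u); v0 <- v - mean(v)
  nu <- sqrt(mean(u0^2)); nv <- sqrt(mean(v0^2))
  if (nu == 0 || nv == 0) stopf("flat map (GFP = 0): similarity undefined")
  C <- mean((u0 / nu) * (v0 / nv))
  C <- max(-1, min(1, C))
  if (polarity_invariant) C <- abs(C)
  list(C = C, gmd = sqrt(max(0, 2 * (1 - C))))
}

#' Extract normalized topographies at GFP peaks
#'
#' Computes the GFP within each kept epoch, finds its peaks (epoch endpoints
#' excluded), and returns the mean-removed, unit-norm peak maps together with
#' their GFP values. An optional cap subsamples peaks uniformly (seeded) to
#' bound the cost of clustering.
#'
#' @param epochs An `eeg_epochs` object (or an [eeg_recording()], treated as
#'   one epoch).
#' @param max_maps Maximum number of peak maps to keep (default 5000);
#'   `Inf` keeps all.
#' @param seed Seed for the subsampling draw.
#' @return A list with `maps` (channels x M, zero-mean unit-norm), `gfp`
#'   (length M), `epoch` and `sample` index vectors.
#' @export
extract_peak_maps <- function(epochs, max_maps = 5000, seed = 1L) {
  if (inherits(epochs, "eeg_recording")) epochs <- as_single_epoch(epochs)
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  maps <- list(); gfps <- list(); eidx <- list(); sidx <- list()
  for (e in seq_len(d[1])) {
    X <- matrix(epochs$data[e, , ], nrow = d[2])
    g <- compute_gfp(X)
    pk <- find_gfp_peaks(g)
    if (length(pk) == 0L) next
    maps[[length(maps) + 1L]] <- X[, pk, drop = FALSE]
    gfps[[length(gfps) + 1L]] <- g[pk]
    eidx[[length(eidx) + 1L]] <- rep(epochs$kept_epoch_indices[e], length(pk))
    sidx[[length(sidx) + 1L]] <- pk
  }
  if (length(maps) == 0L) stopf("no GFP peaks found")
  M <- do.call(cbind, maps)
  g <- unlist(gfps); ei <- unlist(eidx); si <- unlist(sidx)
  if (is.finite(max_maps) && ncol(M) > max_maps) {
    keep <- with_seed(seed, sort(sample.int(ncol(M), max_maps)))
    M <- M[, keep, drop = FALSE]; g <- g[keep]; ei <- ei[keep]; si <- si[keep]
  }
  flat <- g <= 0
  if (any(flat)) {
    M <- M[, !flat, drop = FALSE]; g <- g[!flat]; ei <- ei[!flat]; si <- si[!flat]
  }
  V <- unit_norm_cols(remove_map_means(M))
  list(maps = V, gfp = g, epoch = ei, sample = si)
}

new_template_set <- function(maps, gev = NA_real_, cv_value = NA_real_,
                             source = "subject") {
  structure(list(maps = maps, k = ncol(maps), gev = gev, cv_value = cv_value,
                 source = source),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> k = %d (%s), GEV = %s, CV = %s\n",
              x$k, x$source,
              ifelse(is.na(x$gev), "NA", sprintf("%.4f", x$gev)),
              ifelse(is.na(x$cv_value), "NA", sprintf("%.5g", x$cv_value))))
  invisible(x)
}

# GEV and CV of a template set evaluated on normalized peak maps V with GFP
# weights g. Labels by best |C|; sigma2 on the original (mean-removed) maps.
evaluate_template_set <- function(maps, V, g) {
  N <- nrow(V); K <- ncol(maps)
  C <- abs(crossprod(maps, V))              # K x M
  best <- apply(C, 2L, max)
  gev <- sum((g * best)^2) / sum(g^2)
  cv <- if (K < N - 1L) {
    sigma2 <- sum(N * g^2 * (1 - best^2)) / (length(g) * (N - 1))
    sigma2 * ((N - 1) / (N - 1 - K))^2
  } else {
    NA_real_
  }
  list(gev = gev, cv = cv)
}

#' Atomize-agglomerate hierarchical clustering of peak topographies
#'
#' Classic AAHC with polarity disregarded. Every map starts as its own
#' cluster; the cluster contributing least to the global explained variance
#' (sum over members of `(GFP * |C to own template|)^2`) is dissolved, and
#' each orphaned map is reassigned to the surviving cluster whose template it
#' matches best in absolute spatial correlation. A cluster's template is the
#' dominant eigenvector of the outer-product sum of its member maps (the
#' polarity-invariant mean), with the sign fixed so the largest-|value|
#' channel is positive. A template set is recorded at every `k` in `k_range`
#' on the way down. Deterministic given the input order; all ties go to the
#' lowest index.
#'
#' @param maps Channels x M matrix of maps (normalized internally), or the
#'   list returned by [extract_peak_maps()].
#' @param k_range Integer vector of cluster counts to record (all between 1
#'   and M).
#' @param gfp Optional GFP weights (length M); computed from `maps` if absent.
#' @return Named list of `template_set` objects, one per `k` (names are the k
#'   values), each with GEV and CV evaluated on the peak maps.
#' @export
aahc_cluster <- function(maps, k_range, gfp = NULL) {
  if (is.list(maps) && !is.matrix(maps)) {
    if (is.null(gfp)) gfp <- maps$gfp
    maps <- maps$maps
  }
  maps <- as.matrix(maps)
  M <- ncol(maps); N <- nrow(maps)
  if (is.null(gfp)) gfp <- compute_gfp(maps)
  k_range <- sort(unique(as.integer(k_range)), decreasing = TRUE)
  if (any(k_range < 1L) || any(k_range > M)) {
    stopf("k_range must lie within 1..%d (number of maps)", M)
  }
  V <- unit_norm_cols(remove_map_means(maps))
  g <- gfp
  # State: assignment of maps to clusters, per-cluster outer-product sums,
  # templates, GEV contributions.
  assign_of <- seq_len(M)
  alive <- rep(TRUE, M)
  templates <- V
  S <- vector("list", M)          # outer-product sums, built lazily
  contrib <- (g^2)                # singleton: |C| = 1
  members_of <- as.list(seq_len(M))
  results <- list()
  k_now <- M
  min_k <- min(k_range)
  repeat {
    if (k_now %in% k_range) {
      idx <- which(alive)
      ord <- idx[order(contrib[idx], decreasing = TRUE)]
      Tset <- vapply(ord, function(cl) fix_map_sign(templates[, cl]), numeric(N))
      if (!is.matrix(Tset)) Tset <- matrix(Tset, nrow = N)
      ev <- evaluate_template_set(Tset, V, g)
      results[[as.character(k_now)]] <-
        new_template_set(Tset, gev = ev$gev, cv_value = ev$cv)
    }
    if (k_now <= min_k) break
    idx <- which(alive)
    worst <- idx[which.min(contrib[idx])]
    orphans <- members_of[[worst]]
    alive[worst] <- FALSE
    members_of[worst] <- list(NULL)
    surv <- which(alive)
    Csim <- abs(crossprod(templates[, surv, drop = FALSE],
                          V[, orphans, drop = FALSE]))   # surv x orphans
    dest <- surv[apply(Csim, 2L, which.max)]
    gained <- unique(dest)
    for (j in seq_along(orphans)) {
      c_to <- dest[j]
      members_of[[c_to]] <- c(members_of[[c_to]], orphans[j])
      assign_of[orphans[j]] <- c_to
    }
    for (cl in gained) {
      mem <- members_of[[cl]]
      if (is.null(S[[cl]])) S[[cl]] <- tcrossprod(V[, cl])  # was singleton
      add <- orphans[dest == cl]
      S[[cl]] <- S[[cl]] + tcrossprod(V[, add, drop = FALSE])
      templates[, cl] <- eigen(S[[cl]], symmetric = TRUE)$vectors[, 1L]
      cc <- abs(crossprod(templates[, cl], V[, mem, drop = FALSE]))
      contrib[cl] <- sum((g[mem] * as.vector(cc))^2)
    }
    k_now <- k_now - 1L
  }
  results[order(as.integer(names(results)))]
}

#' Cross-validation criterion for a template set
#'
#' The classical microstate model-selection statistic
#' `CV = sigma_hat^2 * ((N - 1) / (N - 1 - K))^2`, where `sigma_hat^2` is the
#' mean residual variance of the peak maps after removing each map's
#' projection on its best-matching template. Lower is better; the penalty
#' term makes CV rise again once extra templates stop reducing the residual.
#'
#' @param peak_maps Channels x M matrix of maps, or an [extract_peak_maps()]
#'   result.
#' @param template_set A `template_set`.
#' @param gfp Optional GFP weights (recomputed if absent).
#' @return The CV criterion value (positive scalar).
#' @export
cv_criterion <- function(peak_maps, template_set, gfp = NULL) {
  if (is.list(peak_maps) && !is.matrix(peak_maps)) {
    if (is.null(gfp)) gfp <- peak_maps$gfp
    peak_maps <- peak_maps$maps
  }
  N <- nrow(peak_maps); K <- template_set$k
  if (K >= N - 1L) stopf("CV undefined for K (%d) >= N - 1 (%d)", K, N - 1L)
  if (is.null(gfp)) gfp <- compute_gfp(peak_maps)
  V <- unit_norm_cols(remove_map_means(as.matrix(peak_maps)))
  sigma2 <- sum(N * gfp^2 * (1 - apply(abs(crossprod(template_set$maps, V)), 2L, max)^2)) /
    (length(gfp) * (N - 1))
  sigma2 * ((N - 1) / (N - 1 - K))^2
}

#' Pick the number of templates minimizing the CV criterion
#'
#' @param template_sets Named list of `template_set`s as returned by
#'   [aahc_cluster()] (each carrying its `cv_value`).
#' @return The optimal k (integer); ties go to the smaller k.
#' @export
select_optimal_k <- function(template_sets) {
  cvs <- vapply(template_sets, function(ts) ts$cv_value, numeric(1))
  ks <- as.integer(names(template_sets))
  ok <- !is.na(cvs)
  if (!any(ok)) stopf("no template set has a defined CV value")
  ks_ok <- ks[ok]; cvs_ok <- cvs[ok]
  ord <- order(cvs_ok, ks_ok)
  ks_ok[ord[1L]]
}

#' Global explained variance of a labeled segmentation
#'
#' `GEV = sum_t (GFP(t) * C(v_t, T_label(t)))^2 / sum_t GFP(t)^2`, the
#' GFP-squared-weighted share of topographic variance captured by the assigned
#' templates; lies in [0, 1].
#'
#' @param maps Channels x M matrix of maps.
#' @param gfp GFP values (length M); recomputed if `NULL`.
#' @param template_set A `template_set`.
#' @param labels Integer template assignment per map (1..k).
#' @return GEV in [0, 1].
#' @export
compute_gev <- function(maps, gfp = NULL, template_set, labels) {
  maps <- as.matrix(maps)
  if (is.null(gfp)) gfp <- compute_gfp(maps)
  if (all(gfp == 0)) stopf("all maps flat: GEV undefined")
  if (length(labels) != ncol(maps)) stopf("one label per map required")
  V <- unit_norm_cols(remove_map_means(maps))
  C <- abs(crossprod(template_set$maps, V))  # k x M
  cl <- C[cbind(labels, seq_len(ncol(V)))]
  sum((gfp * cl)^2) / sum(gfp^2)
}

#' Group-level clustering of subject template sets
#'
#' Pools the template maps of all subjects and runs AAHC down to `k` group
#' maps (each pooled map enters with unit weight). With identical subject
#' sets, or a single subject, the group maps equal the inputs up to sign and
#' permutation.
#'
#' @param subject_sets List of `template_set`s.
#' @param k Number of group templates.
#' @return A `template_set` with `source = "group"`.
#' @export
group_cluster <- function(subject_sets, k) {
  pooled <- do.call(cbind, lapply(subject_sets, function(ts) ts$maps))
  if (ncol(pooled) < k) stopf("fewer pooled maps (%d) than k (%d)", ncol(pooled), k)
  res <- aahc_cluster(pooled, k_range = k, gfp = rep(1, ncol(pooled)))[[1L]]
  res$source <- "group"
  res
}
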