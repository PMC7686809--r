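# Backfitting templates to every sample and deriving the temporal microstate
# parameters: duration, occurrence, contribution, transition probabilities.

#' Label every sample with its best-matching template
#'
#' Each sample's topography is assigned to the template of highest absolute
#' spatial correlation (equivalently, lowest polarity-invariant global map
#' dissimilarity). Ties go to the lowest template index; flat samples
#' (GFP = 0) get label 1 with correlation 0. Labeling is per epoch — no
#' information crosses epoch boundaries — and is invariant to global sign
#' flips and rescaling of the data.
#'
#' @param epochs An `eeg_epochs` object, or an [eeg_recording()] (treated as a
#'   single epoch).
#' @param templates A `template_set` (channel count must match the data).
#' @return An object of class `ms_labels` with `labels`, `best_correlation`
#'   and `gfp` (epochs x samples matrices), `k`, and `sampling_rate`.
#' @export
backfit_labels <- function(epochs, templates) {
  if (inherits(epochs, "eeg_recording")) epochs <- as_single_epoch(epochs)
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(templates, "template_set"))
  d <- dim(epochs$data)
  if (d[2] != nrow(templates$maps)) {
    stopf("channel mismatch: data has %d channels, templates %d",
          d[2], nrow(templates$maps))
  }
  labels <- matrix(NA_integer_, d[1], d[3])
  bestc <- matrix(NA_real_, d[1], d[3])
  gfps <- matrix(NA_real_, d[1], d[3])
  for (e in seq_len(d[1])) {
    X <- matrix(epochs$data[e, , ], nrow = d[2])
    g <- compute_gfp(X)
    V <- unit_norm_cols(remove_map_means(X))
    C <- abs(crossprod(templates$maps, V))   # k x samples
    lab <- max.col(t(C), ties.method = "first")
    flat <- g <= 0
    lab[flat] <- 1L
    bc <- C[cbind(lab, seq_len(d[3]))]
    bc[flat] <- 0
    labels[e, ] <- lab
    bestc[e, ] <- pmin(bc, 1)
    gfps[e, ] <- g
  }
  structure(list(labels = labels, best_correlation = bestc, gfp = gfps,
                 k = templates$k, sampling_rate = epochs$sampling_rate,
                 state_names = colnames(templates$maps)),
            class = "ms_labels")
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d epochs x %d samples, k = %d, mean |C| = %.3f\n",
              nrow(x$labels), ncol(x$labels), x$k, mean(x$best_correlation)))
  invisible(x)
}

# Maximal same-label runs within each epoch row; returns a data frame with
# epoch, state, length (samples).
label_runs <- function(labels) {
  out <- lapply(seq_len(nrow(labels)), function(e) {
    r <- rle(labels[e, ])
    data.frame(epoch = e, state = r$values, length = r$lengths)
  })
  do.call(rbind, out)
}

#' Temporal microstate statistics
#'
#' Runs are maximal same-label segments within an epoch (segments truncated by
#' the epoch edge are counted). For each state k: duration `d_k` is the mean
#' run length in ms, occurrence `o_k` the number of runs per analyzed second,
#' and contribution `c_k` the fraction of samples labeled k. Counting
#' truncated runs preserves the identity `c_k = o_k * d_k / 1000` exactly, and
#' the contributions always sum to 1. States never observed get 0 for all
#' three.
#'
#' @param labels An `ms_labels` object (or an integer matrix of labels, one
#'   epoch per row, in which case `sampling_rate` and `k` must be given).
#' @param sampling_rate Hz; taken from `labels` when it is an `ms_labels`.
#' @param k Number of states; taken from `labels` when available.
#' @return An object of class `ms_stats` with fields `duration`, `occurrence`,
#'   `contribution` (length-k vectors), `transitions` and `transition_counts`
#'   (k x k matrices), and `n_epochs_used`.
#' @export
temporal_statistics <- function(labels, sampling_rate = NULL, k = NULL) {
  if (inherits(labels, "ms_labels")) {
    sampling_rate <- labels$sampling_rate
    if (is.null(k)) k <- labels$k
    lab_mat <- labels$labels
  } else {
    lab_mat <- as.matrix(labels)
    if (is.null(sampling_rate)) stopf("sampling_rate required for raw label matrices")
    if (is.null(k)) k <- max(lab_mat)
  }
  if (length(lab_mat) == 0L) stopf("empty label sequence")
  runs <- label_runs(lab_mat)
  total_samples <- length(lab_mat)
  total_sec <- total_samples / sampling_rate
  duration <- occurrence <- contribution <- numeric(k)
  for (s in seq_len(k)) {
    rs <- runs$length[runs$state == s]
    if (length(rs) > 0L) {
      duration[s] <- mean(rs) * 1000 / sampling_rate
      occurrence[s] <- length(rs) / total_sec
      contribution[s] <- sum(rs) / total_samples
    }
  }
  tr <- transition_probabilities(lab_mat, k = k)
  nm <- sprintf("MS%d", seq_len(k))
  structure(list(duration = stats::setNames(duration, nm),
                 occurrence = stats::setNames(occurrence, nm),
                 contribution = stats::setNames(contribution, nm),
                 transitions = tr$probabilities,
                 transition_counts = tr$counts,
                 n_epochs_used = nrow(lab_mat)),
            class = "ms_stats")
}

#' @export
print.ms_stats <- function(x, ...) {
  df <- data.frame(duration_ms = round(x$duration, 1),
                   occurrence_per_s = round(x$occurrence, 2),
                   contribution = round(x$contribution, 3))
  cat(sprintf("<ms_stats> %d epochs\n", x$n_epochs_used))
  print(df)
  invisible(x)
}

#' First-order transition probabilities between microstates
#'
#' Counts directed run-to-run changes i -> j (i != j) within epochs only —
#' nothing is counted across an epoch boundary — and row-normalizes over
#' observed departures, so each row with at least one outgoing transition sums
#' to 1 and the diagonal is zero. Rows with no departures are all zero.
#'
#' @param labels An `ms_labels` object or an integer label matrix (one epoch
#'   per row).
#' @param k Number of states (inferred if absent).
#' @return A list with `probabilities` and `counts` (k x k matrices).
#' @export
transition_probabilities <- function(labels, k = NULL) {
  if (inherits(labels, "ms_labels")) {
    if (is.null(k)) k <- labels$k
    lab_mat <- labels$labels
  } else {
    lab_mat <- as.matrix(labels)
    if (is.null(k)) k <- max(lab_mat)
  }
  counts <- matrix(0, k, k)
  for (e in seq_len(nrow(lab_mat))) {
    st <- rle(lab_mat[e, ])$values
    if (length(st) < 2L) next
    from <- st[-length(st)]; to <- st[-1L]
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  probs <- counts
  rs <- rowSums(counts)
  nz <- rs > 0
  probs[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  nm <- sprintf("MS%d", seq_len(k))
  dimnames(probs) <- dimnames(counts) <- list(from = nm, to = nm)
  list(probabilities = probs, counts = counts)
}

#' Order a four-template set against the canonical archetypes
#'
#' Assigns names MS1..MS4 by solving the 4 x 4 assignment problem exactly on
#' absolute spatial correlations between the group maps and the built-in
#' canonical archetype maps (diagonal, mirrored diagonal, anterior-posterior,
#' fronto-central). For `k != 4` the set is returned unchanged with a warning.
#'
#' @param ts A `template_set` with k = 4.
#' @param archetypes Optional channels x 4 archetype matrix (defaults to
#'   [canonical_archetypes()] for the set's channel count).
#' @return The permuted `template_set` with columns named MS1..MS4 and
#'   attributes `similarity` (the 4 x 4 |C| matrix) and `permutation`.
#' @export
order_templates_canonically <- function(ts, archetypes = NULL) {
  stopifnot(inherits(ts, "template_set"))
  if (ts$k != 4L) {
    warning("canonical MS1..MS4 naming needs k = 4; returning the set unchanged")
    return(ts)
  }
  if (is.null(archetypes)) archetypes <- canonical_archetypes(nrow(ts$maps))
  S <- abs(crossprod(archetypes, ts$maps))   # archetype x map |C|
  sigma <- solve_assignment(S)               # sigma[i] = map assigned to MS i
  out <- ts
  out$maps <- ts$maps[, sigma, drop = FALSE]
  colnames(out$maps) <- sprintf("MS%d", 1:4)
  attr(out, "similarity") <- S
  attr(out, "permutation") <- sigma
  out
}

#' Flatten per-subject statistics to the 24-parameter row
#'
#' One row per subject in the order used for reporting: 4 durations, 4
#' occurrences, 4 contributions, then the 12 directed transition
#' probabilities.
#'
#' @param stats An `ms_stats` object (k = 4).
#' @param subject_id Optional subject identifier.
#' @return A one-row tibble with `subject_id` and the 24 parameter columns.
#' @export
stats_row <- function(stats, subject_id = NA_character_) {
  stopifnot(inherits(stats, "ms_stats"))
  k <- length(stats$duration)
  vals <- c(stats$duration, stats$occurrence, stats$contribution,
            unlist(lapply(seq_len(k), function(i) {
              stats$transitions[i, setdiff(seq_len(k), i)]
            })))
  names(vals) <- microstate_parameter_names(k)
  tibble::as_tibble(c(list(subject_id = subject_id), as.list(vals)))
}
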