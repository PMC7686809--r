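# Synthetic microstate-structured EEG and behavioral cohorts.
#
# The simulator is the ground-truth oracle for the whole pipeline: it plants
# known template topographies, a semi-Markov state sequence with gamma dwell
# times, rectified-alpha amplitude modulation (so GFP peaks occur at roughly
# twice the alpha frequency), and a behavioral cohort in which a chosen
# microstate parameter predicts the creativity score with a self-esteem
# moderated interaction.

#' Simulation configuration for one synthetic EEG recording
#'
#' Defaults reflect a typical resting-state acquisition: 64 channels sampled at
#' 500 Hz for 6 minutes, four microstate classes with ~80 ms mean dwell time,
#' 10 Hz alpha-band amplitude modulation, and a signal-to-noise ratio (RMS of
#' the template-locked signal over RMS of spatially white sensor noise) of 3.
#'
#' @param n_channels Number of scalp channels (>= 2).
#' @param n_states Number of microstate classes K (>= 1).
#' @param sampling_rate Sampling rate in Hz.
#' @param record_duration Recording length in seconds; `record_duration *
#'   sampling_rate` must be a whole number of samples.
#' @param mean_dwell Mean microstate dwell time in ms. Either a scalar or a
#'   length-K vector (per-state means).
#' @param dwell_shape Gamma shape parameter of the dwell-time distribution;
#'   shape 2 gives unimodal durations with a mode above zero.
#' @param transition_weights K x K nonnegative matrix with zero diagonal giving
#'   relative probabilities of the next state; rows are normalized internally.
#'   Default: uniform over the other states.
#' @param alpha_freq Frequency (Hz) of the rectified oscillation that modulates
#'   map amplitude.
#' @param snr Signal-to-noise ratio (RMS ratio); `Inf` disables sensor noise.
#' @param signal_rms Target RMS amplitude of the template-locked signal in
#'   microvolts (sets the overall scale of the recording).
#' @param seed Integer seed; every draw in [simulate_subject_eeg()] is a
#'   deterministic function of `(config, seed)`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 64, n_states = 4, sampling_rate = 500,
                       record_duration = 360, mean_dwell = 80, dwell_shape = 2,
                       transition_weights = NULL, alpha_freq = 10, snr = 3,
                       signal_rms = 10, seed = 1L) {
  if (n_states < 1L) stopf("n_states must be >= 1")
  if (n_channels < 2L) stopf("n_channels must be >= 2")
  n_samples <- record_duration * sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stopf("record_duration x sampling_rate must be an integer sample count")
  }
  if (is.null(transition_weights)) {
    transition_weights <- matrix(1, n_states, n_states) - diag(n_states)
    if (n_states == 1L) transition_weights <- matrix(0, 1, 1)
  }
  transition_weights <- as.matrix(transition_weights)
  if (!all(dim(transition_weights) == c(n_states, n_states))) {
    stopf("transition_weights must be %d x %d", n_states, n_states)
  }
  if (any(transition_weights < 0) || any(diag(transition_weights) != 0)) {
    stopf("transition_weights must be nonnegative with a zero diagonal")
  }
  if (n_states > 1L && any(rowSums(transition_weights) <= 0)) {
    stopf("every transition_weights row needs at least one positive off-diagonal entry")
  }
  mean_dwell <- rep_len(mean_dwell, n_states)
  if (any(mean_dwell <= 0)) stopf("mean_dwell must be positive")
  structure(
    list(n_channels = as.integer(n_channels), n_states = as.integer(n_states),
         sampling_rate = sampling_rate, record_duration = record_duration,
         mean_dwell = mean_dwell, dwell_shape = dwell_shape,
         transition_weights = transition_weights, alpha_freq = alpha_freq,
         snr = snr, signal_rms = signal_rms, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Deterministic 2-D electrode layout
#'
#' Places `n_channels` points on the unit disc along a sunflower (Fibonacci)
#' spiral. The layout is an abstract scalp: `y > 0` is anterior (frontal),
#' `x > 0` is right. It is used to build spatially smooth template maps; it is
#' not a fitted montage.
#'
#' @param n_channels Number of electrodes.
#' @return A two-column matrix of (x, y) positions.
#' @export
electrode_layout <- function(n_channels) {
  i <- seq_len(n_channels)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n_channels)
  theta <- i * golden
  cbind(x = r * cos(theta), y = r * sin(theta))
}

gaussian_bump <- function(layout, center, sigma = 0.55) {
  d2 <- (layout[, 1] - center[1])^2 + (layout[, 2] - center[2])^2
  exp(-d2 / (2 * sigma^2))
}

#' Canonical four-class archetype topographies
#'
#' Smooth, zero-mean, unit-norm maps over the internal layout mimicking the
#' four classical microstate orientations: MS1 a left-posterior to
#' right-anterior diagonal, MS2 the mirrored diagonal, MS3 a midline-symmetric
#' anterior-posterior gradient, and MS4 a fronto-central focal map.
#'
#' @param n_channels Number of channels.
#' @return Channels x 4 matrix with columns `MS1`..`MS4`.
#' @export
canonical_archetypes <- function(n_channels) {
  L <- electrode_layout(n_channels)
  maps <- cbind(
    MS1 = gaussian_bump(L, c(0.55, 0.55)) - gaussian_bump(L, c(-0.55, -0.55)),
    MS2 = gaussian_bump(L, c(-0.55, 0.55)) - gaussian_bump(L, c(0.55, -0.55)),
    MS3 = gaussian_bump(L, c(0, 0.75)) - gaussian_bump(L, c(0, -0.75)),
    MS4 = gaussian_bump(L, c(0, 0.35), sigma = 0.4)
  )
  maps <- unit_norm_cols(remove_map_means(maps))
  apply(maps, 2L, fix_map_sign)
}

#' Generate planted template topographies
#'
#' The first four states use the canonical archetypes; additional states are
#' random smooth maps (mixtures of Gaussian bumps on the layout), rejection
#' sampled so that every pair of templates has absolute spatial correlation at
#' most 0.7. Maps are zero-mean and unit-norm; the result is deterministic
#' given `seed`.
#'
#' @param n_channels Number of channels (>= 2).
#' @param n_states Number of templates; must satisfy
#'   `n_states <= n_channels - 1` (zero-mean maps span an (N-1)-dim space).
#' @param seed Integer seed.
#' @param max_abs_cor Pairwise absolute-correlation ceiling (default 0.7).
#' @return Channels x n_states matrix of templates.
#' @export
generate_templates <- function(n_channels, n_states, seed = 1L,
                               max_abs_cor = 0.7) {
  if (n_states < 1L) stopf("n_states must be >= 1")
  if (n_channels < 2L) stopf("n_channels must be >= 2")
  if (n_states > n_channels - 1L) {
    stopf("n_states (%d) must be <= n_channels - 1 (%d)", n_states, n_channels - 1L)
  }
  L <- electrode_layout(n_channels)
  base <- canonical_archetypes(n_channels)
  maps <- base[, seq_len(min(4L, n_states)), drop = FALSE]
  if (n_states > 4L) {
    with_seed(seed, {
      while (ncol(maps) < n_states) {
        cand <- rowSums(vapply(seq_len(3), function(j) {
          s <- sample(c(-1, 1), 1)
          ctr <- stats::runif(2, -0.7, 0.7)
          s * gaussian_bump(L, ctr, sigma = stats::runif(1, 0.35, 0.6))
        }, numeric(n_channels)))
        cand <- cand - mean(cand)
        if (sqrt(sum(cand^2)) < 1e-8) next
        cand <- cand / sqrt(sum(cand^2))
        if (all(abs(crossprod(maps, cand)) <= max_abs_cor)) {
          maps <- cbind(maps, fix_map_sign(cand))
        }
      }
    })
  }
  cors <- abs(crossprod(maps))
  diag(cors) <- 0
  if (any(cors > max_abs_cor + 1e-12)) {
    stopf("template construction violated the pairwise |correlation| <= %g contract", max_abs_cor)
  }
  colnames(maps) <- if (n_states <= 4L) colnames(base)[seq_len(n_states)] else {
    c(colnames(base), sprintf("S%d", 5:n_states))[seq_len(n_states)]
  }
  maps
}

# Draw a semi-Markov run list: gamma dwell times (per-state mean, common
# shape), next state from the row-normalized transition weights. Runs tile
# exactly `n_samples` samples; consecutive runs have distinct states.
draw_state_runs <- function(cfg, n_samples) {
  K <- cfg$n_states
  P <- cfg$transition_weights
  if (K > 1L) P <- P / rowSums(P)
  fs <- cfg$sampling_rate
  state <- sample.int(K, 1L)
  onsets <- integer(0); offsets <- integer(0); states <- integer(0)
  pos <- 1L
  while (pos <= n_samples) {
    dwell_ms <- stats::rgamma(1L, shape = cfg$dwell_shape,
                              scale = cfg$mean_dwell[state] / cfg$dwell_shape)
    len <- max(1L, as.integer(round(dwell_ms * fs / 1000)))
    end <- min(pos + len - 1L, n_samples)
    states <- c(states, state)
    onsets <- c(onsets, pos)
    offsets <- c(offsets, end)
    pos <- end + 1L
    if (K > 1L) state <- sample.int(K, 1L, prob = P[state, ])
  }
  data.frame(state = states, onset = onsets, offset = offsets)
}

#' Simulate one subject's microstate-structured EEG recording
#'
#' The state sequence is a semi-Markov chain (gamma dwell times, next state
#' from the transition-weight row). Within each run the scalp signal is
#' `envelope(t) * sin(2 pi alpha_freq t + phi_run) * template(state)`: the
#' topography is quasi-stable while its signed strength oscillates at the
#' alpha frequency, so GFP peaks occur at about twice the alpha frequency and
#' the map polarity alternates every half-cycle — downstream clustering must
#' disregard polarity to recover the templates. The signed (rather than
#' rectified) oscillation keeps the signal's spectrum at the alpha frequency,
#' inside the standard 2-20 Hz preprocessing band, so band-pass filtering does
#' not distort the planted topographies. The phase is redrawn per run.
#' Spatially white Gaussian noise is added to reach the configured SNR.
#'
#' @param cfg A [sim_config()].
#' @param templates Optional channels x K template matrix; defaults to
#'   [generate_templates()] with the config's seed.
#' @return A list with `recording` (an [eeg_recording()]) and `ground_truth`
#'   (templates, the run list, and the row-normalized transition matrix).
#' @export
simulate_subject_eeg <- function(cfg, templates = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(templates)) {
    templates <- generate_templates(cfg$n_channels, cfg$n_states, seed = cfg$seed)
  }
  n_samples <- as.integer(round(cfg$record_duration * cfg$sampling_rate))
  fs <- cfg$sampling_rate
  out <- with_seed(cfg$seed, {
    runs <- draw_state_runs(cfg, n_samples)
    t_sec <- (seq_len(n_samples) - 1L) / fs
    env_phase <- stats::runif(1L, 0, 2 * pi)
    envelope <- 1 + 0.3 * sin(2 * pi * 0.3 * t_sec + env_phase)
    amp <- numeric(n_samples)
    state_of <- integer(n_samples)
    for (r in seq_len(nrow(runs))) {
      idx <- runs$onset[r]:runs$offset[r]
      phi <- stats::runif(1L, 0, 2 * pi)
      amp[idx] <- envelope[idx] * sin(2 * pi * cfg$alpha_freq * t_sec[idx] + phi)
      state_of[idx] <- runs$state[r]
    }
    signal <- templates[, state_of, drop = FALSE] *
      matrix(amp, nrow = cfg$n_channels, ncol = n_samples, byrow = TRUE)
    rms_s <- sqrt(mean(signal^2))
    scale <- cfg$signal_rms / rms_s
    signal <- signal * scale
    if (is.finite(cfg$snr)) {
      noise_sd <- cfg$signal_rms / cfg$snr
      signal <- signal + matrix(stats::rnorm(length(signal), sd = noise_sd),
                                nrow = cfg$n_channels)
    }
    list(signal = signal, runs = runs)
  })
  rec <- eeg_recording(out$signal, sampling_rate = fs, reference = "simulated")
  P <- cfg$transition_weights
  if (cfg$n_states > 1L) P <- P / rowSums(P)
  gt <- list(templates = templates, state_runs = out$runs,
             transition_matrix = P, config = cfg)
  list(recording = rec, ground_truth = gt)
}

#' Expand a ground-truth run list into a per-sample state sequence
#'
#' @param runs Data frame with `state`, `onset`, `offset` (1-based, inclusive).
#' @return Integer vector of per-sample states.
#' @export
runs_to_labels <- function(runs) {
  n <- runs$offset[nrow(runs)]
  lab <- integer(n)
  for (r in seq_len(nrow(runs))) lab[runs$onset[r]:runs$offset[r]] <- runs$state[r]
  lab
}

#' Canonical names of the 24 microstate parameters
#'
#' Four durations, four occurrences, four contributions and the twelve directed
#' transition probabilities, in the conventional reporting order.
#'
#' @param k Number of states (default 4).
#' @return Character vector of parameter names.
#' @export
microstate_parameter_names <- function(k = 4L) {
  st <- sprintf("MS%d", seq_len(k))
  trans <- unlist(lapply(seq_len(k), function(i) {
    vapply(setdiff(seq_len(k), i), function(j) sprintf("transition_%s_%s", st[i], st[j]), "")
  }))
  c(paste0("duration_", st), paste0("occurrence_", st), paste0("contribution_", st), trans)
}

#' Closed-form microstate parameters of a simulation configuration
#'
#' For the semi-Markov generator the expected parameters have closed forms:
#' durations are the configured mean dwells, the embedded-chain stationary
#' distribution pi gives occurrence `pi_k / sum_j(pi_j * m_j)` (runs per
#' second, `m_j` mean dwell in s), contribution `pi_k m_k / sum_j(pi_j m_j)`,
#' and the transition probabilities are the row-normalized weights.
#'
#' @param cfg A [sim_config()].
#' @return Named numeric vector over [microstate_parameter_names()].
#' @export
microstate_params <- function(cfg) {
  K <- cfg$n_states
  P <- cfg$transition_weights
  if (K > 1L) P <- P / rowSums(P)
  pi_emb <- if (K > 1L) stationary_distribution(P) else 1
  m_s <- cfg$mean_dwell / 1000
  denom <- sum(pi_emb * m_s)
  vals <- c(cfg$mean_dwell,
            pi_emb / denom,
            pi_emb * m_s / denom,
            unlist(lapply(seq_len(K), function(i) P[i, setdiff(seq_len(K), i)])))
  stats::setNames(vals, microstate_parameter_names(K))
}

#' Behavioral cohort configuration
#'
#' Defaults describe an undergraduate cohort: 72% male, age 18.3 +/- 0.84
#' years, self-esteem (RSES, range 10-40) mean 28.37 sd 2.81. The creativity
#' total (WCTS, 50 three-point items, range 50-150) is generated from the
#' planted effect map plus Gaussian noise and truncated to its legal range by
#' resampling the noise (never clipping).
#'
#' @param n_subjects Cohort size.
#' @param rses_mean,rses_sd Self-esteem total mean and sd (scale points).
#' @param male_prob Probability of sex code 1 (male).
#' @param age_mean,age_sd Age distribution (years).
#' @param effect_map List of planted effects, each a list with `parameter` (one
#'   of [microstate_parameter_names()]), and coefficients `b1` (predictor),
#'   `b2` (moderator), `b3` (interaction). Coefficients apply to mean-centered
#'   predictor and moderator.
#' @param intercept WCTS intercept (default 100, mid-scale).
#' @param noise_sd Residual sd of the WCTS total (default 10 scale points).
#' @param b_sex,b_age Covariate effects on WCTS (default 0).
#' @param subject_jitter_sd SD of the log-normal multipliers applied per
#'   subject to dwell means and transition weights (default 0.2); this is what
#'   makes the true microstate parameters vary across subjects.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, rses_mean = 28.37, rses_sd = 2.81,
                          male_prob = 0.72, age_mean = 18.3, age_sd = 0.84,
                          effect_map = list(), intercept = 100, noise_sd = 10,
                          b_sex = 0, b_age = 0, subject_jitter_sd = 0.2,
                          seed = 1L) {
  if (male_prob < 0 || male_prob > 1) stopf("male_prob must be in [0, 1]")
  if (n_subjects < 1L) stopf("n_subjects must be >= 1")
  structure(
    list(n_subjects = as.integer(n_subjects), rses_mean = rses_mean,
         rses_sd = rses_sd, male_prob = male_prob, age_mean = age_mean,
         age_sd = age_sd, effect_map = effect_map, intercept = intercept,
         noise_sd = noise_sd, b_sex = b_sex, b_age = b_age,
         subject_jitter_sd = subject_jitter_sd, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Truncated-normal draws by resampling (avoids point masses at the bounds).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stopf("truncation bounds are unreachable for the given mean/sd")
  }
  x
}

#' Simulate a behavioral cohort with planted moderation effects
#'
#' Each subject gets a perturbed copy of `sim_cfg` (log-normal multipliers on
#' the per-state mean dwells and transition weights), from which the subject's
#' true microstate parameters are computed in closed form
#' ([microstate_params()]). The creativity total is then
#' `intercept + sum over effects of (b1*Xc + b2*Wc + b3*Xc*Wc) + b_sex*sex +
#' b_age*(age - mean age) + noise`, with `Xc` the mean-centered true parameter
#' and `Wc` the mean-centered self-esteem score. Totals are truncated to their
#' legal scale ranges by resampling the noise. Subscale scores split the total
#' in proportion to item counts with a small Dirichlet-like jitter.
#'
#' @param sim_cfg Base [sim_config()] shared by the cohort.
#' @param cohort_cfg A [cohort_config()].
#' @param simulate_eeg If `TRUE`, also simulate each subject's EEG recording
#'   (expensive); if `FALSE` (default) only the behavioral table and true
#'   parameters are produced.
#' @return A list with `behavior` (tibble), `true_params` (subjects x 24
#'   matrix), `subject_configs`, `ground_truth` (planted coefficients), and —
#'   when `simulate_eeg` — `recordings` and `run_lists`.
#' @export
simulate_cohort <- function(sim_cfg, cohort_cfg, simulate_eeg = FALSE) {
  stopifnot(inherits(sim_cfg, "sim_config"), inherits(cohort_cfg, "cohort_config"))
  valid <- microstate_parameter_names(sim_cfg$n_states)
  for (eff in cohort_cfg$effect_map) {
    if (!eff$parameter %in% valid) {
      stopf("unknown microstate parameter in effect_map: %s", eff$parameter)
    }
  }
  n <- cohort_cfg$n_subjects
  K <- sim_cfg$n_states
  with_seed(cohort_cfg$seed, {
    jit <- cohort_cfg$subject_jitter_sd
    subject_cfgs <- vector("list", n)
    tp <- matrix(NA_real_, n, length(valid), dimnames = list(NULL, valid))
    dwell_mults <- matrix(stats::rlnorm(n * K, 0, jit), n, K)
    w_mults <- array(stats::rlnorm(n * K * K, 0, jit), c(K, K, n))
    # row-wise off-diagonal linear indices, i -> j order matching the names
    off_idx <- unlist(lapply(seq_len(K), function(i) i + (setdiff(seq_len(K), i) - 1L) * K))
    ones <- matrix(1, K, K)
    for (s in seq_len(n)) {
      W <- sim_cfg$transition_weights * w_mults[, , s]
      diag(W) <- 0
      md <- sim_cfg$mean_dwell * dwell_mults[s, ]
      P <- if (K > 1L) W / rowSums(W) else matrix(0, 1, 1)
      pi_emb <- if (K > 1L) solve(t(diag(K) - P + ones), rep(1, K)) else 1
      m_s <- md / 1000
      denom <- sum(pi_emb * m_s)
      tp[s, ] <- c(md, pi_emb / denom, pi_emb * m_s / denom, P[off_idx])
      cfg_s <- sim_cfg
      cfg_s$mean_dwell <- md
      cfg_s$transition_weights <- W
      cfg_s$seed <- sim_cfg$seed + s
      subject_cfgs[[s]] <- cfg_s
    }
    rses <- round(rnorm_trunc(n, cohort_cfg$rses_mean, cohort_cfg$rses_sd, 10, 40))
    sex <- stats::rbinom(n, 1L, cohort_cfg$male_prob)
    age <- stats::rnorm(n, cohort_cfg$age_mean, cohort_cfg$age_sd)
    wc <- cohort_cfg$rses_sd # centering scale only for interpretability
    lin <- rep(cohort_cfg$intercept, n) +
      cohort_cfg$b_sex * sex + cohort_cfg$b_age * (age - mean(age))
    Wc <- rses - mean(rses)
    for (eff in cohort_cfg$effect_map) {
      Xc <- tp[, eff$parameter] - mean(tp[, eff$parameter])
      lin <- lin + eff$b1 * Xc + eff$b2 * Wc + eff$b3 * Xc * Wc
    }
    noise <- stats::rnorm(n, 0, cohort_cfg$noise_sd)
    wcts <- lin + noise
    bad <- which(wcts < 50 | wcts > 150)
    guard <- 0L
    while (length(bad) > 0L) {
      wcts[bad] <- lin[bad] + stats::rnorm(length(bad), 0, cohort_cfg$noise_sd)
      bad <- bad[wcts[bad] < 50 | wcts[bad] > 150]
      guard <- guard + 1L
      if (guard > 10000L) stopf("WCTS truncation unreachable; check intercept/noise_sd")
    }
    wcts <- round(wcts)
    # Subscales: split the total in proportion to item counts (13/13/12/12 of
    # 50) with mild jitter; adjust the last so the four sum to the total.
    prop <- c(risk_taking = 12, curiosity = 13, imagination = 13, challenge = 12) / 50
    sub <- t(vapply(seq_len(n), function(s) {
      p <- prop * stats::rlnorm(4, 0, 0.08)
      p <- p / sum(p)
      v <- round(wcts[s] * p)
      v[4] <- wcts[s] - sum(v[1:3])
      v
    }, numeric(4)))
    colnames(sub) <- names(prop)
    behavior <- tibble::tibble(
      subject_id = sprintf("sub%03d", seq_len(n)),
      wcts_total = wcts,
      risk_taking = sub[, "risk_taking"], curiosity = sub[, "curiosity"],
      imagination = sub[, "imagination"], challenge = sub[, "challenge"],
      rses_total = rses, sex = sex, age = age
    )
    res <- list(behavior = behavior, true_params = tp,
                subject_configs = subject_cfgs,
                ground_truth = list(effect_map = cohort_cfg$effect_map,
                                    intercept = cohort_cfg$intercept))
    if (simulate_eeg) {
      templates <- generate_templates(sim_cfg$n_channels, K, seed = sim_cfg$seed)
      sims <- lapply(subject_cfgs, simulate_subject_eeg, templates = templates)
      res$recordings <- lapply(sims, `[[`, "recording")
      res$run_lists <- lapply(sims, function(x) x$ground_truth$state_runs)
      res$templates <- templates
    }
    res
  })
}

#' Write a ground-truth sidecar as JSON
#'
#' Stores the planted templates, the run list and the transition matrix of a
#' simulated recording so external tools can score recovery.
#'
#' @param gt The `ground_truth` element returned by [simulate_subject_eeg()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(
    list(templates = unname(apply(gt$templates, 2L, identity, simplify = FALSE)),
         state_runs = gt$state_runs,
         transition_matrix = gt$transition_matrix),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
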