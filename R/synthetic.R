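#' Describe one ERP-like evoked component
#'
#' A component is a spatial topography over channels times a Gaussian
#' temporal bump, with a class-specific amplitude.  Class-discriminative
#' components (an N170-like face response, say) carry different amplitudes
#' per class; a shared visual component carries equal ones.
#'
#' @param topography Numeric vector over channels; normalized to unit norm.
#' @param latency Peak latency in raw samples (0-based, `< n_timepoints`).
#' @param width Temporal standard deviation of the bump in raw samples.
#' @param amplitude_per_class Numeric vector of peak amplitudes (microvolts),
#'   one per class.
#' @return An object of class `erp_component`.
#' @export
erp_component <- function(topography, latency, width, amplitude_per_class) {
  nrm <- sqrt(sum(topography^2))
  if (nrm == 0) stop_invalid("topography must be non-zero")
  if (width < 1) stop_invalid("width must be >= 1 sample")
  if (latency < 0) stop_invalid("latency must be >= 0")
  structure(list(topography = topography / nrm,
                 latency = latency, width = width,
                 amplitude_per_class = amplitude_per_class),
            class = "erp_component")
}

# Smooth deterministic unit-norm topography peaked at a channel.
gaussian_topography <- function(n_channels, center, spread) {
  v <- exp(-((seq_len(n_channels) - center)^2) / (2 * spread^2))
  v / sqrt(sum(v^2))
}

#' Default evoked components for the three-class face/scene/word problem
#'
#' Four components: an early shared visual response common to all classes
#' (non-discriminative structure), plus one discriminative component per
#' class at N170-, P2- and N400-like latencies, each with its own scalp
#' topography.  Amplitudes are in microvolts at a 250 Hz raw sampling rate.
#'
#' @param n_channels Number of channels (default 31).
#' @return List of [erp_component()]s.
#' @export
default_components <- function(n_channels = 31) {
  list(
    # shared visual onset response, identical across classes
    erp_component(gaussian_topography(n_channels, n_channels * 0.85, 4),
                  latency = 25, width = 8,
                  amplitude_per_class = c(9, 9, 9)),
    # face-selective, N170-like occipitotemporal negativity
    erp_component(gaussian_topography(n_channels, n_channels * 0.7, 5),
                  latency = 42, width = 12,
                  amplitude_per_class = c(-12, -3, -1.5)),
    # scene-selective mid-latency positivity
    erp_component(gaussian_topography(n_channels, n_channels * 0.45, 6),
                  latency = 60, width = 16,
                  amplitude_per_class = c(-1.5, 9, 1.5)),
    # word-selective later left-lateralized negativity
    erp_component(gaussian_topography(n_channels, n_channels * 0.25, 5),
                  latency = 100, width = 24,
                  amplitude_per_class = c(1.5, 3, -10.5))
  )
}

#' Configuration of the synthetic EEG generator
#'
#' Defaults emulate the study conditions the package targets: 37 subjects,
#' 60-70 artifact-free trials per class over 3 classes, 31 channels at
#' 250 Hz with 370-sample epochs that bin down to 37 x 40 ms, amplitudes in
#' tens of microvolts.  Subject variability enters as a multiplicative gain,
#' a per-subject latency shift and a perturbed topography; trial variability
#' as latency jitter, AR(1) channel noise, and attentional lapses in which
#' the class signal is absent while the label is kept.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_class Inclusive integer range from which each
#'   subject x class trial count is drawn.
#' @param n_channels,n_timepoints,sampling_rate Raw epoch geometry.
#' @param classes Class label set.
#' @param components List of [erp_component()]s; amplitudes must cover
#'   `length(classes)`.
#' @param noise_sd AR(1) innovation standard deviation in microvolts; the
#'   stationary noise variance is `noise_sd^2 / (1 - noise_autocorr^2)`.
#' @param noise_autocorr AR(1) coefficient in `[0, 1)`.
#' @param lapse_prob Probability a trial carries no class signal.
#' @param subject_gain_sd SD of the per-subject log-normal gain.
#' @param subject_latency_sd SD (samples) of the per-subject latency shift.
#' @param trial_jitter_sd SD (samples) of the per-trial latency jitter.
#' @param topography_rotation_sd SD of the per-subject topography
#'   perturbation (added Gaussian noise, re-normalized).
#' @param seed Integer seed; fixed seed gives identical datasets.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 37,
                             trials_per_class = c(60, 70),
                             n_channels = 31,
                             n_timepoints = 370,
                             sampling_rate = 250,
                             classes = c("face", "scene", "word"),
                             components = default_components(n_channels),
                             noise_sd = 6,
                             noise_autocorr = 0.6,
                             lapse_prob = 0.1,
                             subject_gain_sd = 0.2,
                             subject_latency_sd = 3,
                             trial_jitter_sd = 2,
                             topography_rotation_sd = 0.1,
                             seed = 1L) {
  if (n_subjects < 1 || n_channels < 1 || n_timepoints < 1) {
    stop_invalid("subject, channel and timepoint counts must be positive")
  }
  if (length(classes) < 1) stop_invalid("at least one class is required")
  if (noise_autocorr < 0 || noise_autocorr >= 1) {
    stop_invalid("noise_autocorr must be in [0, 1)")
  }
  if (lapse_prob < 0 || lapse_prob > 1) {
    stop_invalid("lapse_prob must be in [0, 1]")
  }
  for (cmp in components) {
    if (length(cmp$amplitude_per_class) < length(classes)) {
      stop_invalid("every component needs an amplitude for each class")
    }
    if (length(cmp$topography) != n_channels) {
      stop_invalid("component topography length must equal n_channels")
    }
    if (cmp$latency >= n_timepoints) {
      stop_invalid("component latency must be < n_timepoints")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_class = as.integer(trials_per_class),
                 n_channels = as.integer(n_channels),
                 n_timepoints = as.integer(n_timepoints),
                 sampling_rate = sampling_rate,
                 classes = classes,
                 components = components,
                 noise_sd = noise_sd,
                 noise_autocorr = noise_autocorr,
                 lapse_prob = lapse_prob,
                 subject_gain_sd = subject_gain_sd,
                 subject_latency_sd = subject_latency_sd,
                 trial_jitter_sd = trial_jitter_sd,
                 topography_rotation_sd = topography_rotation_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Per-subject effects, deterministic given cfg$seed.
subject_effects <- function(cfg) {
  with_seed_if(derive_seed(cfg$seed, 101L), {
    lapply(seq_len(cfg$n_subjects), function(s) {
      topo <- lapply(cfg$components, function(cmp) {
        t2 <- cmp$topography +
          rnorm(length(cmp$topography), 0, cfg$topography_rotation_sd)
        t2 / sqrt(sum(t2^2))
      })
      list(gain = exp(rnorm(1, 0, cfg$subject_gain_sd)),
           latency_shift = round(rnorm(1, 0, cfg$subject_latency_sd)),
           topographies = topo)
    })
  })
}

# channels x timepoints deterministic signal for (class, subject effects);
# extra per-trial jitter shifts every component jointly.
template_matrix <- function(cfg, class_k, eff, jitter = 0) {
  tt <- seq_len(cfg$n_timepoints) - 1
  sig <- matrix(0, cfg$n_channels, cfg$n_timepoints)
  for (j in seq_along(cfg$components)) {
    cmp <- cfg$components[[j]]
    lat <- cmp$latency + eff$latency_shift + jitter
    kern <- exp(-((tt - lat)^2) / (2 * cmp$width^2))
    amp <- eff$gain * cmp$amplitude_per_class[class_k]
    sig <- sig + amp * (eff$topographies[[j]] %o% kern)
  }
  sig
}

#' Noiseless class template for one subject
#'
#' Exposes the ground-truth evoked signal (sum of components with the
#' subject's gain, latency shift and topography, no trial jitter, no noise)
#' so tests can correlate generated trials against truth.
#'
#' @param cfg A [synthetic_config()].
#' @param class_k Class index (1-based) or class label.
#' @param subject Subject index (1-based).
#' @return A channels x timepoints matrix in microvolts.
#' @export
class_template <- function(cfg, class_k, subject) {
  if (is.character(class_k)) class_k <- match(class_k, cfg$classes)
  if (is.na(class_k) || class_k < 1 || class_k > length(cfg$classes)) {
    stop_invalid("class out of range")
  }
  if (subject < 1 || subject > cfg$n_subjects) {
    stop_invalid("subject out of range")
  }
  effs <- subject_effects(cfg)
  template_matrix(cfg, class_k, effs[[subject]])
}

#' Generate a synthetic multi-subject epoch dataset
#'
#' Each trial is the subject- and class-specific template (with per-trial
#' latency jitter) plus stationary AR(1) Gaussian noise per channel; with
#' probability `lapse_prob` the signal is omitted entirely while the label
#' is kept, emulating attentional lapses that make some trials
#' unclassifiable.  Deterministic under a fixed `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A raw-sampling-rate [epoch_dataset()]; the metadata carries an
#'   extra logical `lapse` column recording the ground truth.
#' @export
generate_dataset <- function(cfg) {
  K <- length(cfg$classes)
  effs <- subject_effects(cfg)
  with_seed_if(derive_seed(cfg$seed, 202L), {
    count_range <- seq(cfg$trials_per_class[1], cfg$trials_per_class[2])
    counts <- matrix(
      count_range[sample.int(length(count_range), cfg$n_subjects * K,
                             replace = TRUE)],
      cfg$n_subjects, K)
    n_tot <- sum(counts)
    data <- array(0, c(n_tot, cfg$n_channels, cfg$n_timepoints))
    subject_id <- character(n_tot)
    trial_id <- integer(n_tot)
    class_label <- character(n_tot)
    lapse <- logical(n_tot)
    i <- 0L
    for (s in seq_len(cfg$n_subjects)) {
      tid <- 0L
      for (k in seq_len(K)) {
        n_r <- counts[s, k]
        is_lapse <- runif(n_r) < cfg$lapse_prob
        jit <- round(rnorm(n_r, 0, cfg$trial_jitter_sd))
        noise <- ar1_noise(cfg$n_channels * n_r, cfg$n_timepoints,
                           cfg$noise_sd, cfg$noise_autocorr)
        dim(noise) <- c(cfg$n_channels, n_r, cfg$n_timepoints)
        # templates differ across trials only through the integer jitter
        tpl <- lapply(unique(jit[!is_lapse]), function(j) {
          template_matrix(cfg, k, effs[[s]], j)
        })
        names(tpl) <- as.character(unique(jit[!is_lapse]))
        for (r in seq_len(n_r)) {
          i <- i + 1L; tid <- tid + 1L
          sig <- if (is_lapse[r]) 0 else tpl[[as.character(jit[r])]]
          data[i, , ] <- sig + noise[, r, ]
          subject_id[i] <- sprintf("S%02d", s)
          trial_id[i] <- tid
          class_label[i] <- cfg$classes[k]
          lapse[i] <- is_lapse[r]
        }
      }
    }
    epoch_dataset(data,
                  tibble(subject_id = subject_id, trial_id = trial_id,
                         class_label = class_label, lapse = lapse),
                  sampling_rate = cfg$sampling_rate, labels = cfg$classes)
  })
}

# Stationary AR(1) noise, one independent series per channel:
# x_t = phi x_{t-1} + e_t, e ~ N(0, sd), x_0 from the stationary law,
# so Var(x) = sd^2 / (1 - phi^2).
ar1_noise <- function(n_channels, n_timepoints, sd, phi) {
  e <- matrix(rnorm(n_channels * n_timepoints, 0, sd),
              n_channels, n_timepoints)
  if (phi == 0) return(e)
  x <- e
  x[, 1] <- rnorm(n_channels, 0, sd / sqrt(1 - phi^2))
  for (t in 2:n_timepoints) x[, t] <- phi * x[, t - 1] + e[, t]
  x
}

#' Read a synthetic generator configuration from YAML or JSON
#'
#' The file mirrors the [synthetic_config()] arguments; components are given
#' as a list of `{topography, latency, width, amplitude_per_class}` entries,
#' or omitted to use [default_components()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$components)) {
    raw$components <- lapply(raw$components, function(cmp) {
      erp_component(unlist(cmp$topography), cmp$latency, cmp$width,
                    unlist(cmp$amplitude_per_class))
    })
  }
  do.call(synthetic_config, raw)
}
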