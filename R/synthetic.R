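#' Band-limited oscillatory source
#'
#' Band-passed Gaussian white noise, standardized to unit variance. Using
#' filtered noise rather than sinusoids keeps the instantaneous phase
#' non-degenerate, so surrogate nulls behave as they would on resting-state
#' recordings.
#'
#' @param band A [band_spec()].
#' @param duration Length in seconds; must allow >= 10 cycles of `band$f_lo`.
#' @param rate Sampling rate in Hz; must exceed `2 * band$f_hi`.
#' @param seed Optional integer seed (reproducible output for a fixed seed).
#' @return Numeric vector of length `round(duration * rate)`.
#' @export
gen_oscillatory_source <- function(band, duration, rate, seed = NULL) {
  if (rate < 2 * band$f_hi) stop("rate below twice the band's upper edge", call. = FALSE)
  n <- round(duration * rate)
  if (n == 0) stop("empty series: duration is zero", call. = FALSE)
  if (duration * band$f_lo < 10) {
    stop("duration holds fewer than 10 cycles of the band's lower edge", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- bandpass(rnorm(n), band, rate)
  x / sd(x)
}

# 1/f-shaped ("pink") Gaussian noise, unit variance
pink_noise <- function(n, rate, f_ref = 1) {
  white <- rnorm(n)
  X <- stats::fft(white)
  f <- c(1e-12, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)  # two-sided
  g <- 1 / sqrt(pmax(f, f_ref))
  g[1] <- 0  # no DC
  x <- Re(stats::fft(X * g, inverse = TRUE) / n)
  x / sd(x)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Plant within-frequency phase coupling
#'
#' Builds a series whose band-limited phase equals `x`'s band phase plus `lag`
#' plus `(1 - strength)`-scaled phase noise, sharing `x`'s band envelope. At
#' `strength = 1` the output is the exact `lag`-rotated analytic signal of
#' `x`'s band component, so the pair's iPLV approaches `|sin(lag)|`; at
#' `strength = 0` the phase is that of an independent oscillation.
#'
#' @param x Source series.
#' @param band A [band_spec()].
#' @param rate Sampling rate (Hz).
#' @param lag Phase lag in radians. `lag = 0` with `strength = 1` is flagged
#'   as a degenerate design (imaginary phase locking is blind to zero lag).
#' @param strength Coupling strength in `[0, 1]`.
#' @param seed Optional seed for the phase-noise source.
#' @return Numeric vector, same length as `x`.
#' @export
plant_phase_coupling <- function(x, band, rate, lag = pi / 2, strength = 1,
                                 seed = NULL) {
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]", call. = FALSE)
  if (lag == 0 && strength == 1) {
    warning("zero-lag coupling at full strength: imaginary phase locking cannot detect it",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ax <- analytic_signal(bandpass(x, band, rate))
  phi <- Arg(ax)
  noise <- if (strength < 1) {
    ind <- gen_oscillatory_source(band, length(x) / rate, rate)
    wrap_angle(Arg(analytic_signal(ind)) - phi)
  } else 0
  Re(Mod(ax) * exp(1i * (phi + lag + (1 - strength) * noise)))
}

#' Plant phase-to-amplitude coupling
#'
#' Builds a high-frequency series whose amplitude envelope is
#' `(1 + depth * cos(phi_low(x) - lag)) / (1 + depth)`-modulated. The carrier
#' is constant-modulus (a cosine of a band-limited random phase), so the
#' planted modulation is not masked by intrinsic carrier-envelope
#' fluctuations. The default quarter-cycle `lag` makes the modulation visible
#' to the imaginary-part phase-locking stage of the [pac()] estimator.
#'
#' @param x Modulating (low-frequency phase-bearing) series.
#' @param f_low,f_high [band_spec()]s, `f_low$f_hi < f_high$f_lo`.
#' @param rate Sampling rate (Hz).
#' @param depth Modulation depth in `[0, 1]`.
#' @param lag Modulation phase lag (radians).
#' @param carrier Optional series whose `f_high` phase drives the carrier; an
#'   independent oscillation when NULL.
#' @param seed Optional seed.
#' @return Numeric vector, same length as `x`, unit variance.
#' @export
plant_pac <- function(x, f_low, f_high, rate, depth = 0.9, lag = pi / 2,
                      carrier = NULL, seed = NULL) {
  if (depth < 0 || depth > 1) stop("depth must be in [0, 1]", call. = FALSE)
  if (f_low$f_hi > f_high$f_lo) {
    stop("f_low must lie strictly below f_high", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  phi_low <- Arg(analytic_signal(bandpass(x, f_low, rate)))
  car <- if (is.null(carrier)) {
    gen_oscillatory_source(f_high, length(x) / rate, rate)
  } else carrier
  phi_c <- Arg(analytic_signal(bandpass(car, f_high, rate)))
  y <- cos(phi_c) * (1 + depth * cos(phi_low - lag)) / (1 + depth)
  y / sd(y)
}

#' Coupling plan: the identity-bearing generative schedule of one subject
#'
#' A plan assigns to each driven (ordered) region pair a set of intended
#' dominant coupling modes and a Markov transition matrix over them; the mode
#' in force switches at regular ticks according to the chain, so dwell times
#' are geometric. The plan — not any session realization — carries subject
#' identity: both sessions of a subject are realized from the same plan with
#' different seeds.
#'
#' @param n_rois Number of regions.
#' @param edges Integer matrix, k x 2 (source ROI drives target ROI).
#' @param edge_modes List of k integer vectors (mode indices 1-36; see
#'   [coupling_modes()]).
#' @param trans List of k row-stochastic transition matrices, one per edge,
#'   dimension `length(edge_modes[[k]])` squared.
#' @param strength Within-frequency planted coupling strength in `[0, 1]`.
#' @param depth Cross-frequency planted modulation depth in `[0, 1]`.
#' @param snr Planted-component amplitude relative to the target region's own
#'   band amplitude.
#' @param tick_s Markov tick length in seconds (dwell-time resolution).
#' @return A `coupling_plan` object.
#' @export
coupling_plan <- function(n_rois, edges, edge_modes, trans,
                          strength = 0.9, depth = 0.9, snr = 4, tick_s = 0.5) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0 && max(edges) > n_rois) {
    stop("plan references an ROI index beyond n_rois", call. = FALSE)
  }
  stopifnot(length(edge_modes) == nrow(edges), length(trans) == nrow(edges))
  for (k in seq_along(trans)) {
    tm <- trans[[k]]
    if (any(abs(rowSums(tm) - 1) > 1e-8)) {
      stop("transition-matrix rows must sum to 1", call. = FALSE)
    }
    if (any(edge_modes[[k]] < 0 | edge_modes[[k]] > 36)) {
      stop("mode indices must be in 0..36", call. = FALSE)
    }
  }
  structure(list(n_rois = n_rois, edges = edges, edge_modes = edge_modes,
                 trans = trans, strength = strength, depth = depth,
                 snr = snr, tick_s = tick_s),
            class = "coupling_plan")
}

#' Random coupling plan
#'
#' Samples per-edge mode sets (by default two modes per edge, drawn from
#' within- and cross-frequency modes whose slow band is theta or above, so
#' every planted mode is resolvable in 1-s windows) and random sticky Markov
#' dynamics (stay probability drawn in `[0.6, 0.9]`).
#'
#' @inheritParams coupling_plan
#' @param n_modes_per_edge Number of intended dominant modes per edge.
#' @param seed Optional seed.
#' @return A `coupling_plan`.
#' @export
random_coupling_plan <- function(n_rois, edges, n_modes_per_edge = 2,
                                 strength = 0.9, depth = 0.9, snr = 4,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mt <- coupling_modes()
  # exclude modes whose slow band is delta; keep target bands distinct per edge
  eligible <- mt[mt$low >= 2, ]
  edges <- matrix(as.integer(edges), ncol = 2)
  edge_modes <- list(); trans <- list()
  for (k in seq_len(nrow(edges))) {
    repeat {
      rows <- eligible[sample(nrow(eligible), n_modes_per_edge), ]
      if (length(unique(rows$high)) == n_modes_per_edge) break
    }
    edge_modes[[k]] <- sort(rows$mode)
    m <- n_modes_per_edge
    stay <- runif(1, 0.6, 0.9)
    tm <- matrix((1 - stay) / max(1, m - 1), m, m)
    diag(tm) <- if (m > 1) stay else 1
    trans[[k]] <- tm
  }
  coupling_plan(n_rois, edges, edge_modes, trans,
                strength = strength, depth = depth, snr = snr)
}

# Markov mode schedule over ticks -> per-sample state index vector
schedule_states <- function(trans, n_ticks) {
  m <- nrow(trans)
  s <- integer(n_ticks)
  s[1] <- sample(m, 1)
  if (n_ticks > 1) {
    for (t in 2:n_ticks) s[t] <- sample(m, 1, prob = trans[s[t - 1], ])
  }
  s
}

# raised-cosine on/off mask for a tick-state sequence, per mode
state_mask <- function(states, target, tick_n, n, ramp_n) {
  on <- rep(states == target, each = tick_n)[seq_len(n)]
  g <- as.numeric(on)
  if (ramp_n > 1) {
    kern <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / (ramp_n + 1))
    kern <- c(kern, rev(kern)) / sum(c(kern, rev(kern)))
    g <- as.numeric(stats::filter(c(rep(g[1], ramp_n), g, rep(g[n], ramp_n)),
                                  kern, sides = 2))
    g <- g[(ramp_n + 1):(ramp_n + n)]
    g[is.na(g)] <- 0
  }
  g
}

#' Generate one subject (multi-session recordings from one plan)
#'
#' Each region is a sum of eight band-limited components with a 1/f-like
#' amplitude profile plus 1/f background noise. For every driven edge the plan
#' schedules its modes over time; during a mode's segments the target region's
#' corresponding band component is cross-faded toward a coupled component
#' (phase-locked copy for within-frequency modes, phase-modulated
#' constant-modulus carrier for cross-frequency modes) at `snr` times the band
#' amplitude, with the region's own component attenuated underneath. Sessions
#' share the plan and differ only in realization seeds.
#'
#' @param plan A [coupling_plan()].
#' @param duration Session length in seconds.
#' @param rate Sampling rate (Hz).
#' @param noise_level SD of the 1/f background noise relative to the unit-SD
#'   oscillatory mixture.
#' @param seed Integer seed; session k uses `seed + k`.
#' @param n_sessions Number of sessions to realize (default 2).
#' @param bands Band definitions.
#' @return A `docm_subject` object: list with `sessions` (list of samples x
#'   ROI matrices), `rate`, and `duration`.
#' @export
gen_subject <- function(plan, duration, rate = 600, noise_level = 0.2,
                        seed = 1, n_sessions = 2, bands = canonical_bands()) {
  stopifnot(inherits(plan, "coupling_plan"))
  n <- round(duration * rate)
  R <- plan$n_rois
  fc <- vapply(bands, function(b) (b$f_lo + b$f_hi) / 2, 0)
  amp <- 1 / fc^0.25
  amp <- amp / sqrt(sum(amp^2))
  tick_n <- round(plan$tick_s * rate)
  n_ticks <- ceiling(n / tick_n)
  ramp_n <- round(0.05 * rate)
  mt <- coupling_modes(bands)

  sessions <- lapply(seq_len(n_sessions), function(sess) {
    set.seed(seed + sess)
    comp <- lapply(seq_len(R), function(r) {
      lapply(bands, function(b) gen_oscillatory_source(b, duration, rate))
    })
    base <- comp  # un-modified sources used to derive coupled components
    for (k in seq_len(nrow(plan$edges))) {
      i <- plan$edges[k, 1]; j <- plan$edges[k, 2]
      modes <- plan$edge_modes[[k]]
      states <- schedule_states(plan$trans[[k]], n_ticks)
      for (mi in seq_along(modes)) {
        m <- modes[mi]
        if (m == 0) next
        g <- state_mask(states, mi, tick_n, n, ramp_n)
        lo <- mt$low[m]; hi <- mt$high[m]
        if (mt$type[m] == "iplv") {
          src <- Re(analytic_signal(base[[i]][[lo]]) * exp(1i * pi / 2))
          coupled <- plan$strength * src +
            (1 - plan$strength) * gen_oscillatory_source(bands[[lo]], duration, rate)
          tgt <- lo
        } else {
          phi_low <- Arg(analytic_signal(base[[i]][[lo]]))
          phi_c <- Arg(analytic_signal(base[[j]][[hi]]))
          coupled <- cos(phi_c) * (1 + plan$depth * cos(phi_low - pi / 2)) /
            (1 + plan$depth)
          tgt <- hi
        }
        coupled <- coupled / sd(coupled)
        # coupling episodes are coherent bursts: the target band component is
        # cross-faded to the coupled burst and the source band component is
        # amplified by the same factor, so both phases ride well above the
        # in-band background during driven segments
        comp[[j]][[tgt]] <- comp[[j]][[tgt]] * (1 - 0.9 * g) +
          plan$snr * g * coupled
        comp[[i]][[lo]] <- comp[[i]][[lo]] * (1 + (plan$snr - 1) * g)
      }
    }
    x <- vapply(seq_len(R), function(r) {
      s <- Reduce(`+`, Map(`*`, comp[[r]], amp))
      s + noise_level * pink_noise(n, rate)
    }, numeric(n))
    x
  })
  structure(list(sessions = sessions, rate = rate, duration = duration),
            class = "docm_subject")
}

#' Generate a synthetic cohort
#'
#' All subjects share one driven edge set (regions that carry identity
#' information are common across individuals); each subject's identity lives
#' in the per-edge mode sets and Markov dynamics of their private
#' [coupling_plan()]. Ground truth (the plans) is stored separately from the
#' pipeline-visible recordings.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois Number of regions (default 20).
#' @param duration Session length in seconds (default 60).
#' @param rate Sampling rate in Hz (default 600).
#' @param n_driven Number of driven edges (default 6); edges are disjoint ROI
#'   pairs.
#' @param n_sessions Sessions per subject (default 2).
#' @param noise_level 1/f background level (see [gen_subject()]).
#' @param seed Master seed.
#' @param edges Optional preset edge matrix (k x 2); sampled when NULL.
#' @param plans Optional preset list of plans (used when regenerating subjects
#'   for a second cohort).
#' @return A `docm_cohort` object: list with `subjects` (list of
#'   `docm_subject`), `rate`, `duration`, `n_rois`, `edges`, and ground-truth
#'   `plans`.
#' @export
gen_cohort <- function(n_subjects, n_rois = 20, duration = 60, rate = 600,
                       n_driven = 6, n_sessions = 2, noise_level = 0.2,
                       seed = 1, edges = NULL, plans = NULL) {
  set.seed(seed)
  if (is.null(edges)) {
    stopifnot(2 * n_driven <= n_rois)
    rois <- sample(n_rois, 2 * n_driven)
    edges <- matrix(rois, ncol = 2, byrow = TRUE)
  }
  if (is.null(plans)) {
    plans <- lapply(seq_len(n_subjects), function(s) {
      random_coupling_plan(n_rois, edges, seed = seed * 1000L + s)
    })
  }
  subjects <- lapply(seq_len(n_subjects), function(s) {
    gen_subject(plans[[s]], duration, rate, noise_level,
                seed = seed * 10000L + s * 10L, n_sessions = n_sessions)
  })
  structure(list(subjects = subjects, rate = rate, duration = duration,
                 n_rois = n_rois, edges = edges, plans = plans),
            class = "docm_cohort")
}

#' @export
print.docm_cohort <- function(x, ...) {
  cat(sprintf("<docm_cohort> %d subjects x %d session(s), %d ROIs, %g s at %g Hz\n",
              length(x$subjects), length(x$subjects[[1]]$sessions),
              x$n_rois, x$duration, x$rate))
  invisible(x)
}

#' Generate two cohorts with a hidden subject overlap
#'
#' Cohort 1 is a test-retest cohort (two sessions per subject). Cohort 2 is a
#' single-session population cohort; `n_overlap` of its subjects are
#' regenerated from cohort-1 plans with fresh seeds (same identity, new
#' recording), the rest from new plans. The true correspondence is returned as
#' a manifest that the identification pipeline never sees.
#'
#' @param n1,n2 Cohort sizes.
#' @param n_overlap Number of cohort-1 subjects also present in cohort 2.
#' @param seed Master seed.
#' @param ... Passed to [gen_cohort()] (`n_rois`, `duration`, `rate`, ...).
#' @return A list with `cohort1`, `cohort2` (both `docm_cohort`), and
#'   `manifest` (tibble with `cohort1_id`, `cohort2_id`).
#' @export
gen_two_cohorts <- function(n1, n2, n_overlap, seed = 1, ...) {
  if (n1 < 0 || n2 < 0 || n_overlap < 0) stop("negative counts", call. = FALSE)
  if (n_overlap > min(n1, n2)) stop("n_overlap exceeds a cohort size", call. = FALSE)
  cohort1 <- gen_cohort(n1, seed = seed, ...)
  set.seed(seed + 777L)
  overlap_ids <- sort(sample(n1, n_overlap))
  positions <- sample(n2, n_overlap)
  plans2 <- lapply(seq_len(n2), function(s) {
    hit <- match(s, positions)
    if (!is.na(hit)) {
      cohort1$plans[[overlap_ids[hit]]]
    } else {
      random_coupling_plan(cohort1$n_rois, cohort1$edges,
                           seed = (seed + 500L) * 1000L + s)
    }
  })
  cohort2 <- gen_cohort(n2, seed = seed + 999L, n_sessions = 1,
                        edges = cohort1$edges, plans = plans2, ...)
  manifest <- tibble(cohort1_id = overlap_ids, cohort2_id = positions)
  list(cohort1 = cohort1, cohort2 = cohort2, manifest = manifest)
}

#' Voxel-level expansion of an ROI signal
#'
#' Fixture generator for the functional-interpolation representative: voxel k
#' is `w_k * roi_signal + noise_k`.
#'
#' @param roi_signal Numeric vector.
#' @param n_voxels Number of voxels (>= 1).
#' @param weight_profile Numeric vector of voxel weights (recycled/validated
#'   to `n_voxels`); all-zero is an error.
#' @param noise SD of additive white noise per voxel.
#' @param seed Optional seed.
#' @return Numeric matrix voxels x samples with attribute `weights`.
#' @export
gen_voxel_rois <- function(roi_signal, n_voxels, weight_profile = NULL,
                           noise = 0.1, seed = NULL) {
  if (n_voxels < 1) stop("need at least one voxel", call. = FALSE)
  if (is.null(weight_profile)) weight_profile <- rep(1, n_voxels)
  stopifnot(length(weight_profile) == n_voxels)
  if (all(weight_profile == 0)) stop("all-zero weights", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  v <- t(vapply(seq_len(n_voxels), function(k) {
    weight_profile[k] * roi_signal + noise * rnorm(length(roi_signal))
  }, numeric(length(roi_signal))))
  attr(v, "weights") <- weight_profile
  v
}
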