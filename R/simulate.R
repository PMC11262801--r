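#' Kinematic parameters of the simulated actions
#'
#' The simulator is a kinematic cartoon of dorsal-view larval midline
#' behaviour: its job is to produce distinguishable, ground-truth-labelled
#' examples of the archetypal actions with controllable difficulty, not a
#' biomechanical model. Crawling is a travelling longitudinal compression
#' wave with net head-first displacement; backing reverses both; bending
#' swings the anterior body about a pivot; hunching is a rapid uniform
#' contraction whose head-retraction speed exceeds the crawl wave speed by
#' construction (so the contrast survives a global slow-down of the
#' phenotype); rolling is approximated in midline terms as alternating-sign
#' curvature with lateral drift; stopping is a frozen posture. A global
#' `speed_mult` emulates slow/fast phenotype lines, and additive Gaussian
#' coordinate noise emulates tracking noise.
#'
#' @param body_length Resting body length (mm).
#' @param n_points Number of simulated spine points (head first).
#' @param frame_rate Frames per second.
#' @param noise_sd Tracking-noise standard deviation (mm), applied last.
#' @param speed_mult Phenotype speed multiplier applied to all rates.
#' @param crawl_freq Peristaltic frequency (Hz).
#' @param crawl_stride Stride length per cycle (body lengths).
#' @param crawl_wave_amp Relative amplitude of the compression wave.
#' @param crawl_wavenumber Wavelengths of the compression wave per body.
#' @param bend_amp Head-sweep amplitude (rad).
#' @param bend_period Head-sweep period (s).
#' @param hunch_contraction Fraction of body length lost in a hunch.
#' @param hunch_rate Contraction completed per second (1/s); the default
#'   makes head retraction several times faster than the crawl advance.
#' @param hunch_hold Seconds the contracted posture is held before release.
#' @param hunch_rest Seconds of straight posture between repeated hunches.
#' @param back_speed_frac Backward speed as a fraction of crawl speed.
#' @param roll_freq Curvature alternation frequency (Hz).
#' @param roll_curv Peak midline curvature (per body length).
#' @param roll_lat_amp Lateral drift amplitude (body lengths).
#' @param stop_jitter Multiplier on `noise_sd` for stop frames.
#' @return An object of class `action_params`.
#' @export
action_params <- function(body_length = 4, n_points = 11L, frame_rate = 10,
                          noise_sd = 0.05, speed_mult = 1,
                          crawl_freq = 1.2, crawl_stride = 0.15,
                          crawl_wave_amp = 0.15, crawl_wavenumber = 0.5,
                          bend_amp = 1.2, bend_period = 2,
                          hunch_contraction = 0.3, hunch_rate = 5,
                          hunch_hold = 0.3, hunch_rest = 0.4,
                          back_speed_frac = 0.6,
                          roll_freq = 1, roll_curv = 0.6, roll_lat_amp = 0.15,
                          stop_jitter = 1) {
  stopifnot(body_length > 0, n_points >= 3L, frame_rate > 0, noise_sd >= 0,
            speed_mult > 0, crawl_freq > 0, bend_period > 0, hunch_rate > 0,
            hunch_contraction > 0, hunch_contraction < 1)
  structure(as.list(environment()), class = "action_params")
}

sim_actions <- c("crawl", "bend", "back", "hunch", "roll", "stop")

#' Simulation script
#'
#' An ordered list of (action, duration) segments plus kinematic parameters
#' and a seed; [simulate_track()] runs it into a track with ground-truth
#' labels. Frames on a segment boundary belong to the later segment.
#'
#' @param actions Character vector of action names (see `sim_actions`:
#'   crawl, bend, back, hunch, roll, stop).
#' @param durations Numeric vector of segment durations in seconds.
#' @param params An [action_params()].
#' @param seed Integer seed for the track's noise.
#' @return An object of class `sim_script`.
#' @export
sim_script <- function(actions, durations, params = action_params(),
                       seed = 0L) {
  if (length(actions) != length(durations) || !length(actions))
    stop("actions and durations must be non-empty and equal length")
  unknown <- setdiff(actions, sim_actions)
  if (length(unknown))
    stop(sprintf("unknown action name(s): %s", paste(unknown, collapse = ", ")))
  if (any(durations <= 0)) stop("durations must be > 0")
  structure(list(actions = actions, durations = as.numeric(durations),
                 params = params, seed = as.integer(seed)),
            class = "sim_script")
}

# Midline of one frame, in world coordinates. `anchor` is the tail
# position at segment start, `theta` the heading (direction of the head),
# `tau` the time since segment start.
sim_frame <- function(action, tau, anchor, theta, par) {
  S <- par$n_points
  s <- seq(0, 1, length.out = S)          # arc position, head = 0
  L0 <- par$body_length
  u <- c(cos(theta), sin(theta))
  perp <- c(-sin(theta), cos(theta))
  mult <- par$speed_mult

  straight <- function(tail, len) {
    d <- (1 - s) * len                    # distance from tail to each point
    cbind(tail[1] + u[1] * d, tail[2] + u[2] * d)
  }

  if (action == "crawl" || action == "back") {
    f <- par$crawl_freq * mult
    v <- par$crawl_stride * L0 * f
    sgn <- if (action == "crawl") 1 else -1
    if (action == "back") v <- v * par$back_speed_frac
    # modulated segment lengths, tail to head
    smid <- (s[-1] + s[-S]) / 2
    seg <- (1 / (S - 1)) * L0 *
      (1 + par$crawl_wave_amp * sin(2 * pi * (f * tau - sgn * par$crawl_wavenumber * smid)))
    tail_pos <- anchor + sgn * v * tau * u
    d <- c(0, cumsum(rev(seg)))           # distances from tail
    dd <- rev(d)                          # per spine point, head first
    cbind(tail_pos[1] + u[1] * dd, tail_pos[2] + u[2] * dd)
  } else if (action == "bend") {
    pts <- straight(anchor, L0)
    phi <- par$bend_amp * sin(2 * pi * tau * mult / par$bend_period)
    pivot_s <- 0.4
    pivot <- anchor + u * (1 - pivot_s) * L0
    wgt <- pmax(0, (pivot_s - s) / pivot_s)   # head bends most
    for (j in seq_len(S)) {
      if (wgt[j] <= 0) next
      a <- phi * wgt[j]
      rel <- pts[j, ] - pivot
      pts[j, ] <- pivot + c(cos(a) * rel[1] - sin(a) * rel[2],
                            sin(a) * rel[1] + cos(a) * rel[2])
    }
    pts
  } else if (action == "hunch") {
    # retract fast / hold / release / rest, repeating: the hunch is a
    # transient retraction event, not a held posture
    t_r <- 1 / par$hunch_rate
    t_rel <- 2 * t_r
    cycle <- t_r + par$hunch_hold + t_rel + par$hunch_rest
    ph <- (tau * mult) %% cycle
    frac <- if (ph < t_r) ph / t_r
            else if (ph < t_r + par$hunch_hold) 1
            else if (ph < t_r + par$hunch_hold + t_rel)
              1 - (ph - t_r - par$hunch_hold) / t_rel
            else 0
    straight(anchor, L0 * (1 - par$hunch_contraction * frac))
  } else if (action == "roll") {
    f <- par$roll_freq * mult
    kappa <- par$roll_curv / L0 * sin(2 * pi * f * tau)
    arc <- (1 - s) * L0                   # arc length from tail
    if (abs(kappa) < 1e-9) {
      pts <- straight(anchor, L0)
    } else {
      ang <- theta + kappa * arc
      x <- anchor[1] + (sin(ang) - sin(theta)) / kappa
      y <- anchor[2] - (cos(ang) - cos(theta)) / kappa
      pts <- cbind(x, y)
    }
    off <- par$roll_lat_amp * L0 * sin(2 * pi * f * tau)
    pts + matrix(off * perp, nrow = S, ncol = 2L, byrow = TRUE)
  } else if (action == "stop") {
    straight(anchor, L0)
  } else stop(sprintf("unknown action name: %s", action))
}

#' Simulate one larva track from a script
#'
#' Runs a [sim_script()] at its frame rate and returns the track together
#' with a ground-truth [label_set()] aligning every timestep with its
#' scripted action. Gaussian coordinate noise (`noise_sd`, scaled by
#' `stop_jitter` during stops) is applied last.
#'
#' @param script A [sim_script()].
#' @param larva_id Integer id for the generated track.
#' @param origin Numeric length-2 start position of the tail (mm).
#' @param heading Initial heading angle (rad).
#' @param dictionary Action dictionary for the ground-truth labels.
#' @param assay Assay metadata attached to the track.
#' @return List with elements `track` and `labels`.
#' @export
simulate_track <- function(script, larva_id = 1L, origin = c(0, 0),
                           heading = 0, dictionary = action_dictionary(),
                           assay = assay_metadata()) {
  par <- script$params
  fr <- par$frame_rate
  total <- sum(script$durations)
  Tn <- floor(total * fr + 1e-9)
  t <- (seq_len(Tn) - 1L) / fr
  starts <- cumsum(c(0, script$durations))
  seg_of <- findInterval(t, starts, rightmost.closed = FALSE)
  seg_of[seg_of > length(script$actions)] <- length(script$actions)

  S <- par$n_points
  spine <- array(NA_real_, c(Tn, S, 2L))
  anchor <- as.numeric(origin)
  cur_seg <- 0L
  for (i in seq_len(Tn)) {
    sg <- seg_of[i]
    if (sg != cur_seg) {
      if (cur_seg > 0L) {
        # advance the anchor to the outgoing segment's final tail position
        end_tau <- starts[sg] - starts[cur_seg]
        last <- sim_frame(script$actions[cur_seg], end_tau, anchor, heading, par)
        anchor <- last[S, ]
      }
      cur_seg <- sg
    }
    spine[i, , ] <- sim_frame(script$actions[sg], t[i] - starts[sg],
                              anchor, heading, par)
  }
  noise_scale <- ifelse(script$actions[seg_of] == "stop", par$stop_jitter, 1)
  spine <- spine + withr::with_seed(script$seed,
    array(stats::rnorm(length(spine), sd = par$noise_sd), dim(spine)) *
      array(rep(noise_scale, S * 2L), dim(spine)))

  track <- larva_track(larva_id, t, spine, assay = assay)
  idx <- match(script$actions[seg_of], dictionary$name)
  labels <- label_set(
    dictionary,
    assignments = stats::setNames(list(lapply(idx, identity)),
                                  as.character(larva_id)),
    t = stats::setNames(list(t), as.character(larva_id)),
    provenance = stats::setNames("imported", as.character(larva_id)))
  list(track = track, labels = labels)
}

#' Sample per-larva kinematic parameters
#'
#' Draws a phenotype-varied copy of a base [action_params()]: the speed
#' multiplier is log-normal (slow and fast lines), and the main rates and
#' amplitudes get independent relative jitter. This emulates the
#' between-line and between-animal variability of real screens, where the
#' same action is performed at different speeds and amplitudes.
#'
#' @param base Base [action_params()].
#' @param cv Coefficient of variation of the per-parameter jitter.
#' @param speed_sdlog Log-sd of the phenotype speed multiplier.
#' @return An [action_params()] with perturbed values.
#' @export
sample_action_params <- function(base = action_params(), cv = 0.2,
                                 speed_sdlog = 0.25) {
  jit <- function(x) x * exp(stats::rnorm(1, 0, cv))
  base$speed_mult <- base$speed_mult * stats::rlnorm(1, 0, speed_sdlog)
  for (f in c("crawl_freq", "crawl_stride", "crawl_wave_amp", "bend_amp",
              "bend_period", "hunch_contraction", "roll_curv",
              "roll_lat_amp", "back_speed_frac"))
    base[[f]] <- jit(base[[f]])
  base$hunch_contraction <- min(base$hunch_contraction, 0.6)
  base
}

#' Generate labelled posture windows from simulated larvae
#'
#' The workhorse behind the learning experiments: simulates larvae running
#' random multi-action scripts with per-larva phenotype variation
#' ([sample_action_params()]), extracts posture windows, labels each window
#' with the ground-truth action at its centre timestep, and accumulates a
#' balanced pool of `n_per_class` windows per action. Windows are thinned
#' by `thin` frames so windows of one larva are not near-duplicates.
#'
#' @param n_per_class Windows per action class.
#' @param actions Character vector of actions to include.
#' @param cfg A [windowing_config()].
#' @param base_params Base [action_params()].
#' @param vary Apply per-larva parameter sampling.
#' @param thin Keep every `thin`-th window of a track.
#' @param duration_range Segment-duration range of the random scripts (s).
#' @param seed Integer seed.
#' @return List with `windows` (list of `posture_window`) and `classes`
#'   (character vector of ground-truth actions).
#' @export
simulate_labelled_windows <- function(n_per_class,
                                      actions = c("crawl", "bend", "back",
                                                  "hunch", "roll", "stop"),
                                      cfg = windowing_config(),
                                      base_params = action_params(),
                                      vary = TRUE, thin = 3L,
                                      duration_range = c(1.2, 3),
                                      seed = 0L) {
  withr::with_seed(seed, {
    need <- stats::setNames(rep(n_per_class, length(actions)), actions)
    wins <- list(); cls <- character(0)
    i <- 0L
    while (any(need > 0L) && i < 10000L) {
      i <- i + 1L
      par <- if (vary) sample_action_params(base_params) else base_params
      nseg <- 6L
      script <- sim_script(sample(actions, nseg, replace = TRUE),
                           stats::runif(nseg, duration_range[1],
                                        duration_range[2]),
                           params = par, seed = seed + 104729L * i)
      sim <- simulate_track(script, larva_id = i)
      w <- extract_windows(sim$track, cfg)
      if (length(w) < 2L * thin) next
      keep <- seq(1L, length(w), by = thin)
      w <- w[keep]
      lab <- window_labels(w, sim$labels)
      for (k in seq_along(w)) {
        a <- lab[k]
        if (is.na(a) || is.na(need[a]) || need[a] <= 0L) next
        wins[[length(wins) + 1L]] <- w[[k]]
        cls <- c(cls, a)
        need[a] <- need[a] - 1L
      }
    }
    list(windows = wins, classes = cls)
  })
}

#' Simulate a stimulus assay over a population of larvae
#'
#' Emulates the screen protocol: every larva behaves according to a
#' pre-stimulus action mixture, then switches — exactly at stimulus onset —
#' to actions drawn from the post-stimulus mixture. Segment durations are
#' drawn uniformly from `duration_range`, whose lower bound exceeds 1 s so
#' the 1-s analysis window right after onset reflects the post mixture.
#' Population action frequencies converge to the mixtures as the number of
#' larvae grows.
#'
#' @param n_larvae Number of larvae.
#' @param stimulus_onset Onset of the stimulus (s).
#' @param pre_mixture,post_mixture Named probability vectors over action
#'   names (must be non-negative and sum to 1 within 1e-6).
#' @param total_seconds Assay duration (s).
#' @param stimulus_duration Stimulus duration recorded in the metadata (s).
#' @param params An [action_params()].
#' @param duration_range Range segment durations are drawn from (s).
#' @param dictionary Action dictionary for ground-truth labels.
#' @param seed Integer seed; fixed seed gives a bit-identical assay.
#' @return List with `tracks` (list of tracks), `labels` (one merged
#'   [label_set()]) and `metadata` ([assay_metadata()]).
#' @export
simulate_assay <- function(n_larvae, stimulus_onset = 45,
                           pre_mixture = c(crawl = 0.6, bend = 0.3, stop = 0.1),
                           post_mixture = c(crawl = 0.3, hunch = 0.3,
                                            back = 0.2, stop = 0.2),
                           total_seconds = stimulus_onset + 10,
                           stimulus_duration = 38,
                           params = action_params(),
                           duration_range = c(1.2, 3),
                           dictionary = action_dictionary(), seed = 0L) {
  check_mixture <- function(m, what) {
    if (any(m < 0) || abs(sum(m) - 1) > 1e-6)
      stop(sprintf("%s mixture must be non-negative and sum to 1", what))
    if (!length(names(m)) || !all(names(m) %in% sim_actions))
      stop(sprintf("%s mixture must be named by valid actions", what))
  }
  check_mixture(pre_mixture, "pre")
  check_mixture(post_mixture, "post")
  stopifnot(n_larvae >= 1L, stimulus_onset > 0,
            total_seconds > stimulus_onset, duration_range[1] > 0)

  meta <- assay_metadata(assay_id = sprintf("sim-%d", seed),
                         stimulus_onset = stimulus_onset,
                         stimulus_duration = stimulus_duration,
                         frame_rate_hint = params$frame_rate)
  draw_phase <- function(mix, span) {
    acts <- character(0); durs <- numeric(0); acc <- 0
    while (acc < span - 1e-9) {
      d <- stats::runif(1, duration_range[1], duration_range[2])
      d <- min(d, span - acc)
      acts <- c(acts, sample(names(mix), 1L, prob = mix))
      durs <- c(durs, d)
      acc <- acc + d
    }
    list(actions = acts, durations = durs)
  }

  withr::with_seed(seed, {
    tracks <- vector("list", n_larvae)
    assignments <- list(); tvecs <- list(); prov <- character()
    for (i in seq_len(n_larvae)) {
      pre <- draw_phase(pre_mixture, stimulus_onset)
      post <- draw_phase(post_mixture, total_seconds - stimulus_onset)
      script <- sim_script(c(pre$actions, post$actions),
                           c(pre$durations, post$durations),
                           params = params,
                           seed = seed + 7919L * i)
      sim <- simulate_track(script, larva_id = i,
                            origin = stats::runif(2, 0, 100),
                            heading = stats::runif(1, 0, 2 * pi),
                            dictionary = dictionary, assay = meta)
      tracks[[i]] <- sim$track
      id <- as.character(i)
      assignments[[id]] <- sim$labels$assignments[[id]]
      tvecs[[id]] <- sim$labels$t[[id]]
      prov[id] <- "imported"
    }
    list(tracks = tracks,
         labels = label_set(dictionary, assignments, tvecs, prov),
         metadata = meta)
  })
}
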