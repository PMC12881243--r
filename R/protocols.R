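#' Generate word-learning stimulus patterns
#'
#' Creates the stimulus triplets used for word learning: each pattern
#' consists of 20 excitatory cells sampled uniformly without replacement
#' in each of three primary areas.  Object words populate the auditory,
#' articulatory and visual primary areas (A1, M1i, V1); action words
#' populate A1, M1i and the lateral motor area (M1L).  Cells are drawn
#' independently across words, so overlaps between words are permitted.
#' Each pattern engages 20/625 = 3.2% of a primary area.
#'
#' @param n_object,n_action Number of object and action words (default
#'   6 + 6 = 12 patterns).
#' @param cells_per_area Pattern size per area (default 20).
#' @param seed Optional seed for reproducible pattern sets.
#' @return List of `stimulus_pattern` objects, each with fields
#'   `word_id` (0-based), `category` (`"object"`/`"action"`) and `cells`
#'   (named list of 0-based cell indices per area).
#' @export
generate_patterns <- function(n_object = 6, n_action = 6,
                              cells_per_area = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cats <- rep(c("object", "action"), c(n_object, n_action))
  lapply(seq_along(cats), function(w) {
    areas <- c("A1", "M1i", if (cats[w] == "object") "V1" else "M1L")
    cells <- lapply(areas, function(a) sort(sample.int(N_EXC, cells_per_area) - 1L))
    names(cells) <- areas
    structure(list(word_id = w - 1L, category = cats[w], cells = cells),
              class = "stimulus_pattern")
  })
}

#' @export
print.stimulus_pattern <- function(x, ...) {
  cat(sprintf("stimulus_pattern word %d (%s): %s\n", x$word_id, x$category,
              paste(names(x$cells), collapse = " + ")))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the word-learning protocol: 2000 trials per word, 16
#' stimulation steps per trial, and a stimulus-to-stimulus interval (STSI)
#' that lasts until global inhibition in the multimodal hub areas PB and
#' PFi has fallen below `stsi_epsilon` (capped at `stsi_max_steps`).  The
#' drive amplitude is calibrated so that a driven cell fires within two
#' steps even against full adaptation and realistic inhibition levels;
#' the noise amplitude keeps baseline membrane fluctuations clearly
#' subthreshold so spontaneous spiking stays minimal.
#'
#' @param trials_per_word Trials per word.
#' @param stim_steps Stimulation steps per trial.
#' @param stsi_epsilon Hub global-inhibition level regarded as baseline.
#' @param stsi_max_steps Cap on the STSI length.
#' @param drive_amplitude External current applied to driven cells.
#' @param noise_amplitude Area-level noise current amplitude.
#' @param seed Optional seed applied at the start of training.
#' @return An object of class `training_config`.
#' @export
training_config <- function(trials_per_word = 2000, stim_steps = 16,
                            stsi_epsilon = 0.5, stsi_max_steps = 100,
                            drive_amplitude = 5000, noise_amplitude = 10,
                            seed = NULL) {
  stopifnot(stim_steps >= 1, stsi_max_steps >= 1, trials_per_word >= 1)
  structure(list(trials_per_word = trials_per_word, stim_steps = stim_steps,
                 stsi_epsilon = stsi_epsilon,
                 stsi_max_steps = stsi_max_steps,
                 drive_amplitude = drive_amplitude,
                 noise_amplitude = noise_amplitude, seed = seed),
            class = "training_config")
}

#' Evaluation configuration
#'
#' Cell-assembly evaluation trials comprise 5 baseline steps without
#' external input, 2 steps of pattern presentation to a single port area,
#' and 60 free propagation steps, with noise throughout; 3 trials per port
#' (auditory A1, articulatory M1i) give 6 rasters per word.
#'
#' @param baseline_steps,stim_steps,propagation_steps Phase lengths.
#' @param trials_per_port Trials per stimulation port.
#' @param drive_amplitude,noise_amplitude As in [training_config()].
#' @return An object of class `evaluation_config`.
#' @export
evaluation_config <- function(baseline_steps = 5, stim_steps = 2,
                              propagation_steps = 60, trials_per_port = 3,
                              drive_amplitude = 5000,
                              noise_amplitude = 10) {
  structure(list(baseline_steps = baseline_steps, stim_steps = stim_steps,
                 propagation_steps = propagation_steps,
                 trials_per_port = trials_per_port,
                 ports = c(auditory = "A1", articulatory = "M1i"),
                 drive_amplitude = drive_amplitude,
                 noise_amplitude = noise_amplitude),
            class = "evaluation_config")
}

#' Randomised interleaved training schedule
#'
#' @param patterns Pattern list from [generate_patterns()].
#' @param trials_per_word Repetitions of each word.
#' @param seed Optional seed.
#' @return Integer vector of pattern list positions; each word appears
#'   exactly `trials_per_word` times in randomised interleaved order.
#' @export
make_training_schedule <- function(patterns, trials_per_word, seed = NULL) {
  stopifnot(length(patterns) >= 1)
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_along(patterns), each = trials_per_word))
}

# fourth primary area: the one not covered by the pattern
unused_primary_area <- function(pattern) {
  setdiff(c("A1", "M1i", "V1", "M1L"), names(pattern$cells))
}

#' Run one word-learning trial
#'
#' Applies the pattern's cells as an additive current in its three primary
#' areas for `stim_steps` steps while the fourth primary area receives
#' uncorrelated random input (a fresh 20-cell subset, resampled every
#' trial, at the same amplitude) and all areas receive noise.  The trial
#' ends with the stimulus-to-stimulus interval: noise-only steps until
#' global inhibition in both hub areas PB and PFi has returned below
#' `stsi_epsilon`, or `stsi_max_steps` is reached (a warning is recorded
#' in the log and the trial proceeds).
#'
#' @param net Network (plasticity is applied; excitatory-to-excitatory
#'   weights change).
#' @param pattern A `stimulus_pattern`.
#' @param cfg A [training_config()].
#' @return Trial log: `list(stim_steps, stsi_steps, stsi_capped)`.
#' @export
run_training_trial <- function(net, pattern, cfg = training_config()) {
  stopifnot(inherits(pattern, "stimulus_pattern"),
            inherits(cfg, "training_config"))
  fourth <- unused_primary_area(pattern)
  n_cells <- length(pattern$cells[[1]])
  cells <- pattern$cells
  cells[[fourth]] <- sample.int(N_EXC, n_cells) - 1L
  drv <- drive_vector(net, cells, cfg$drive_amplitude)
  run_steps(net, cfg$stim_steps, drive = drv,
            noise_amplitude = cfg$noise_amplitude, plastic = TRUE)
  hubs <- match(intersect(c("PB", "PFi"), net$areas), net$areas)
  if (!length(hubs)) hubs <- seq_along(net$G)   # reduced architectures
  k <- 0L
  while (any(net$G[hubs] >= cfg$stsi_epsilon) && k < cfg$stsi_max_steps) {
    step_network(net, drive = NULL, noise_amplitude = cfg$noise_amplitude,
                 plastic = TRUE)
    k <- k + 1L
  }
  list(stim_steps = cfg$stim_steps, stsi_steps = k,
       stsi_capped = any(net$G[hubs] >= cfg$stsi_epsilon))
}

#' Train a network on a pattern set
#'
#' Runs the full randomised schedule of learning trials.
#'
#' @param net Network.
#' @param patterns Pattern list.
#' @param cfg A [training_config()].
#' @param schedule Optional precomputed schedule (defaults to
#'   [make_training_schedule()] with `cfg$seed`).
#' @param progress Print progress every 100 trials?
#' @return A summary log: data frame with one row per trial
#'   (`trial`, `word_id`, `stsi_steps`, `stsi_capped`).
#' @export
train_network <- function(net, patterns, cfg = training_config(),
                          schedule = NULL, progress = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(schedule))
    schedule <- make_training_schedule(patterns, cfg$trials_per_word)
  n <- length(schedule)
  word_id <- integer(n); stsi <- integer(n); capped <- logical(n)
  t0 <- Sys.time()
  for (i in seq_len(n)) {
    log <- run_training_trial(net, patterns[[schedule[i]]], cfg)
    word_id[i] <- patterns[[schedule[i]]]$word_id
    stsi[i] <- log$stsi_steps
    capped[i] <- log$stsi_capped
    if (progress && i %% 100L == 0L)
      message(sprintf("trial %d/%d (%.1f s elapsed)", i, n,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  data.frame(trial = seq_len(n), word_id = word_id, stsi_steps = stsi,
             stsi_capped = capped)
}

#' Run one cell-assembly evaluation trial
#'
#' With plasticity frozen: `baseline_steps` noise-only steps, then
#' `stim_steps` steps driving the pattern's cells in the port area only,
#' then `propagation_steps` free steps with noise.  Returns the spike
#' raster of all steps.
#'
#' @param net Trained network (weights are not modified).
#' @param pattern A `stimulus_pattern`.
#' @param port `"A1"`/`"auditory"` or `"M1i"`/`"articulatory"`.
#' @param cfg An [evaluation_config()].
#' @return A `spike_raster` of `baseline + stim + propagation` rows.
#' @export
run_evaluation_trial <- function(net, pattern, port = "A1",
                                 cfg = evaluation_config()) {
  if (port %in% names(cfg$ports)) port <- cfg$ports[[port]]
  if (!port %in% cfg$ports)
    stop("run_evaluation_trial: unknown port '", port, "'")
  if (!port %in% names(pattern$cells))
    stop("run_evaluation_trial: pattern has no cells in port area ", port)
  drv <- drive_vector(net, pattern$cells[port], cfg$drive_amplitude)
  r1 <- run_steps(net, cfg$baseline_steps, noise_amplitude =
                    cfg$noise_amplitude, plastic = FALSE, record = TRUE)
  r2 <- run_steps(net, cfg$stim_steps, drive = drv,
                  noise_amplitude = cfg$noise_amplitude, plastic = FALSE,
                  record = TRUE)
  r3 <- run_steps(net, cfg$propagation_steps, noise_amplitude =
                    cfg$noise_amplitude, plastic = FALSE, record = TRUE)
  raster <- rbind(r1, r2, r3)
  structure(raster, class = c("spike_raster", "matrix"), areas = net$areas,
            n_exc = net$arch$n_exc,
            stim_window = cfg$baseline_steps + seq_len(cfg$stim_steps))
}

#' Run the full evaluation of one word
#'
#' `trials_per_port` trials through the auditory port (A1) and the same
#' number through the articulatory port (M1i).
#'
#' @inheritParams run_evaluation_trial
#' @return List of spike rasters (auditory trials first).
#' @export
evaluate_word <- function(net, pattern, cfg = evaluation_config()) {
  c(lapply(seq_len(cfg$trials_per_port), function(i)
      run_evaluation_trial(net, pattern, "A1", cfg)),
    lapply(seq_len(cfg$trials_per_port), function(i)
      run_evaluation_trial(net, pattern, "M1i", cfg)))
}

#' Single-neuron testbench
#'
#' Simulates the minimal circuit of one excitatory and one inhibitory
#' unit: the excitatory unit receives a constant external current for
#' `duration` steps and drives the inhibitory unit through the central
#' excitatory-to-inhibitory weight (0.295); the inhibitory unit feeds
#' back through the one-to-one inhibitory synapse.  Used for side-by-side
#' backend comparison: with mode-matched time constants
#' ([matched_parameters()]) the felix and delay backends produce
#' identical spike trains and state trajectories.
#'
#' @param params A [model_parameters()] object (noise is disabled inside
#'   the testbench).
#' @param current_amplitude Constant external current during stimulation.
#' @param duration Stimulation length in excitatory steps.
#' @param total_steps Total simulated steps (default adds 24 post-stimulus
#'   steps to observe adaptation decay).
#' @param w_ei Excitatory-to-inhibitory weight.
#' @return Data frame with per-step traces: `step`, `V_exc` (post-reset),
#'   `omega_adapt`, `omega_rate`, `spike`, `V_inh`.
#' @export
single_neuron_testbench <- function(params, current_amplitude,
                                    duration = 16,
                                    total_steps = duration + 24,
                                    w_ei = 0.295) {
  stopifnot(inherits(params, "model_parameters"))
  d <- decay_factors(params)
  V_e <- V_i <- omega <- rate <- 0
  phi <- 0L
  out_inh_prev <- 0          # inhibitory output of the previous half-tick
  tr <- data.frame(step = seq_len(total_steps), V_exc = NA_real_,
                   omega_adapt = NA_real_, omega_rate = NA_real_,
                   spike = NA_integer_, V_inh = NA_real_)
  for (t in seq_len(total_steps)) {
    # inhibitory unit integrates the previous-step spike (0.5-step delay
    # in delay mode; same-step scheme in felix mode -- identical schedule)
    V_i <- d$inh * V_i + (1 - d$inh) * (params$k1_inh * w_ei * phi)
    out_inh <- max(V_i, 0)
    I_ext <- if (t <= duration) current_amplitude else 0
    I_e <- I_ext - params$strength_ie * out_inh
    V_e <- d$exc * V_e + (1 - d$exc) * (params$k1_exc * I_e)
    phi <- spike_decision(V_e, omega, params)
    omega <- d$adapt * omega + (1 - d$adapt) * phi
    rate <- d$favg * rate + (1 - d$favg) * phi
    if (isTRUE(params$spike_reset) && phi == 1L) V_e <- 0
    tr$V_exc[t] <- V_e
    tr$omega_adapt[t] <- omega
    tr$omega_rate[t] <- rate
    tr$spike[t] <- phi
    tr$V_inh[t] <- V_i
  }
  tr
}
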