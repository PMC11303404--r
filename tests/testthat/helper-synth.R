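# Shared scaled-down fixtures, generated in code.

# A short PLR session: 5 stimuli, 8 Hz, 96x96 default optics.
small_plr_session <- function(seed = 1L, noise = TRUE, frame_rate_hz = 8) {
  sch <- stimulus_schedule(c(10, 30, 50, 70, 90), 2, 120)
  opt <- scene_optics(noise_sd = if (noise) 0.01 else 0)
  lid <- eyelid_model(noise_sd = if (noise) 0.01 else 0)
  cfg <- session_config("plr", schedule = sch, optics = opt, eyelid = lid,
                        frame_rate_hz = frame_rate_hz, blink_rate_hz = 0.05)
  render_session(cfg, seed)
}

# A short gaze session: full 8-target grid, 2 s dwells, 1 repeat, 8 Hz.
small_gaze_session <- function(seed = 1L, noise = TRUE, frame_rate_hz = 8) {
  opt <- scene_optics(noise_sd = if (noise) 0.01 else 0)
  lid <- eyelid_model(noise_sd = if (noise) 0.01 else 0)
  cfg <- session_config("gaze", optics = opt, eyelid = lid,
                        frame_rate_hz = frame_rate_hz, blink_rate_hz = 0,
                        dwell_s = 2, baseline_s = 4, repeats = 1, padding_s = 2)
  render_session(cfg, seed)
}

# Uniform test frame.
flat_frame <- function(value, n = 32) matrix(value, n, n)

# Trace-level PLR darkness trace with known blink injections.
blinky_trace <- function(seed = 1L, blink_times = c(30, 77, 130, 181, 220),
                         blink_gain = 0.3, noise_sd = 0.002, frame_rate_hz = 31) {
  set.seed(seed)
  sch <- default_plr_schedule()
  tru <- simulate_plr_diameter(sch, plr_kinetics(), frame_rate_hz)
  clean <- simulate_darkness_trace(tru, "closed_eye", noise_sd_trace = noise_sd)
  v <- clean$values
  inj <- integer(0)
  for (b in blink_times) {
    idx <- which(clean$t_s >= b & clean$t_s < b + 0.2)
    v[idx] <- pmax(v[idx] - blink_gain, 0)   # intensity spike = darkness dip
    inj <- c(inj, idx)
  }
  list(clean = clean,
       dirty = darkness_trace(clean$t_s, v, "closed_eye", frame_rate_hz),
       injected_idx = inj, blink_times = blink_times, truth = tru,
       schedule = sch)
}
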