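# Shared synthetic movies, generated once per test session.

.movie_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.movie_cache[[key]])) .movie_cache[[key]] <- builder()
  .movie_cache[[key]]
}

# small, sparse movie: trackable by construction (steps << spacing)
small_movie <- function() {
  cached("small", function() generate_movie(movie_config(
    n_frames = 12, field_size = c(700L, 700L), n_initial_cells = 18,
    motion_step_sd = 2, division_prob = c("MEF-like" = 0.02,
                                          "neuron-like" = 0.02,
                                          "shrunken" = 0.02),
    apoptosis_prob = 0,
    conversion_schedule = data.frame(
      fraction = 0.3, mode = "without-mitosis", frame_lo = 4, frame_hi = 8,
      target = "neuron-like"),
    seed = 42L)))
}

small_movie_obs <- function() {
  cached("small_obs", function() {
    m <- small_movie()
    lapply(seq_along(m$frames), function(t)
      classify_cells(detect_cells(m$frames[[t]], m$nuclei[[t]])))
  })
}

# the demo-scale movie and its analysis (shared by the acceptance tests)
demo_analysis <- function() {
  cached("demo", function()
    run_movie_pipeline(run_config(), movie = generate_movie(movie_config())))
}

no_conversions <- data.frame(fraction = numeric(), mode = character(),
                             frame_lo = numeric(), frame_hi = numeric(),
                             target = character())

# displacement-recovery movie: division-free, sparse, so steps are pure
# Gaussian walk
displacement_movie <- function() {
  cached("disp", function() {
    m <- generate_movie(movie_config(
      n_frames = 10, field_size = c(2000L, 2000L), n_initial_cells = 220,
      motion_step_sd = 4, division_prob = 0, apoptosis_prob = 0,
      conversion_schedule = no_conversions, seed = 2027L))
    obs <- lapply(m$frames, function(f) detect_cells(f, neurites = FALSE))
    links <- lapply(seq_len(length(obs) - 1), function(t)
      link_frames(obs[[t]], obs[[t + 1]],
                  gate = 5 * max(m$config$motion_step_sd)))
    list(movie = m, obs = obs, links = links)
  })
}

# division-recovery movie: a proliferating MEF population whose growth
# carries the division probability
division_movie <- function() {
  cached("div", function() {
    m <- generate_movie(movie_config(
      n_frames = 16, field_size = c(2000L, 2000L), n_initial_cells = 220,
      motion_step_sd = 4, division_prob = 0.05, apoptosis_prob = 0,
      conversion_schedule = no_conversions, seed = 2026L))
    obs <- lapply(m$frames, function(f) detect_cells(f, neurites = FALSE))
    list(movie = m, obs = obs)
  })
}
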