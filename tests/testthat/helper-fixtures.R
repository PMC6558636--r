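# Shared fixtures, built once per test run and memoised: several test
# files interrogate the same default-regime simulation, so it is computed
# a single time.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# one default-regime movie (the standard acquisition regime): 31 objects
# per channel, 25 frames, 30 x 30 um at 0.1 um/px, fully coupled channels
default_coupled_sim <- function() {
  memo("coupled_sim", simulate_movie(
    sim_config(coupling_mode = "colocalized", coloc_fraction = 1,
               seed = 42)))
}

default_coupled_spots <- function() {
  memo("coupled_spots", detect_spots(default_coupled_sim()$movie))
}

default_coupled_tracks <- function() {
  memo("coupled_tracks", build_tracks(default_coupled_spots()))
}

# a small, fast movie for pipeline and i/o tests
small_sim <- function() {
  memo("small_sim", simulate_movie(
    sim_config(field_size_px = c(100L, 100L), n_frames = 10L,
               n_objects_per_channel = 6L,
               coupling_mode = "colocalized", coloc_fraction = 1,
               seed = 314)))
}
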