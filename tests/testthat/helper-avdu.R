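# Shared fixtures: everything is generated in code at test time.

# Luminance movie of a drifting grating on the default 100x2 test geometry.
grating_movie <- function(g, duration = 2, dt = 0.1,
                          geom = test_array_geometry()) {
  tt <- (seq_len(round(duration * 1000 / dt)) - 1) * dt / 1000
  sample_test_array(geom, g, tt)
}

# Shortened response measurement for unit tests (1 s run, final 0.5 s mean);
# acceptance tests use the full 2 s / final 1 s protocol.
quick_response <- function(params, wavelength, av, contrast = 1,
                           waveform = "square") {
  measure_response(build_test_system(params),
                   grating(waveform, wavelength, av, contrast),
                   duration = 1, window = 0.5)
}

# Small symmetric corridor for closed-loop tests.
sine_corridor <- function(freq_left = 0.03, freq_right = freq_left,
                          contrast = 1) {
  corridor_world(
    left_wall = wall_pattern("sine", freq_left, contrast = contrast),
    right_wall = wall_pattern("sine", freq_right, contrast = contrast))
}
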