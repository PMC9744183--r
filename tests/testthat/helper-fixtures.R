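# Shared fixtures, generated in code. Heavier population-level objects are
# cached per test run so several test blocks can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

probe8 <- linear_probe_geometry()

# a small deterministic unit: identical triangular spikes on 8 channels
toy_unit <- function(n_spk = 4L, amp = c(1, 0.8, 0.6, 0.45, 0.3, 0.2, 0.1, 0.05)) {
  base <- rep(0, 32)
  base[8:16] <- -c(1:5, 4:1) / 5          # trough around sample 12
  base[20:24] <- c(1, 2, 3, 2, 1) / 10    # small late positivity
  sn <- array(0, c(n_spk, 8L, 32L))
  for (ch in 1:8) sn[, ch, ] <- matrix(rep(base * amp[ch], n_spk), n_spk, byrow = TRUE)
  unit_recording("toy", seq_len(n_spk) * 0.1, sn)
}

# small labeled synthetic population for module-level tests
small_population <- function() {
  cached("small_pop", function() {
    generate_population(population_spec(6L, 3L, duration_s = 60, seed = 101))
  })
}

# reference-scale population (study-condition defaults) for acceptance checks
reference_population <- function() {
  cached("ref_pop", function() {
    generate_population(population_spec(80L, 20L, duration_s = 300, seed = 11))
  })
}

reference_spatial_tables <- function() {
  cached("ref_sp_tabs", function() {
    pop <- reference_population()
    list(nochunk = feature_table(pop, probe8, modalities = "spatial"),
         c25 = chunk_feature_table(pop, 25L, probe8, modalities = "spatial",
                                   seed = 5))
  })
}

null_spatial_tables <- function() {
  cached("null_sp_tabs", function() {
    ns <- synth_preset("null")
    pop <- generate_population(population_spec(80L, 20L, duration_s = 300,
                                               seed = 21),
                               pyr = ns$pyr, pv = ns$pv)
    list(nochunk = feature_table(pop, probe8, modalities = "spatial"),
         c25 = chunk_feature_table(pop, 25L, probe8, modalities = "spatial",
                                   seed = 6))
  })
}

# per-unit waveform feature matrix of the reference population
reference_waveform_features <- function() {
  cached("ref_wf", function() {
    pop <- reference_population()
    t(vapply(pop, waveform_features_of_unit, numeric(8)))
  })
}
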