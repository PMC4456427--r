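# shared fixture builders (all fixtures are generated in code)

# minimal long-dialect CSV: nw wells x nt sweeps x frequencies
make_long_csv <- function(path, nt = 3, wells = c("A1", "A2"),
                          freqs = ecis_frequencies()) {
  rows <- expand.grid(time_s = (seq_len(nt) - 1) * 160, well = wells,
                      frequency_hz = freqs, stringsAsFactors = FALSE)
  rows$z_real_ohm <- 1000 + as.numeric(seq_len(nrow(rows)))
  rows$z_imag_ohm <- -500 - as.numeric(seq_len(nrow(rows)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  rows
}

# small noise-free single-group experiment with an early wound (fast tests)
quick_sim <- function(v = 10.69, seed = 1, wound_h = 200, total_h = 230,
                      n_wells = 1, micromotion = FALSE, noise_sd = 0,
                      well_sd = 0) {
  sim_config(
    seed = seed,
    groups = stats::setNames(
      list(sim_group(n_wells = n_wells, front_speed = v,
                     well_sd_ohm = well_sd)), "g"),
    schedule = phase_schedule(wound_h = wound_h, total_h = total_h),
    micromotion = list(enabled = micromotion, high_var = 4e-4,
                       low_var = 4e-6, midpoint_h = 11.5, width_h = 1.5,
                       ar_tau = 5),
    noise_sd = noise_sd)
}

default_electrode <- function() calibrate_naked_electrode()
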