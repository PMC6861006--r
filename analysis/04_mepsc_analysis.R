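#!/usr/bin/env Rscript
# Miniature EPSC analysis on synthetic voltage-clamp recordings: cell QC
# from seal tests, template-matching detection, per-cell frequency and
# amplitude summaries, and a two-group comparison with a frequency
# contrast (5.5 vs 7.6 Hz, amplitudes equal) mirroring a release-site
# phenotype without a quantal-size change.

suppressMessages(library(svpool))
dir.create("results", showWarnings = FALSE)
set.seed(1)

tpl <- event_template(0.5, 5, sampling_rate = 10000)
sim_cells <- function(rate, n, seed0) {
  lapply(seq_len(n), function(i) {
    sim <- simulate_mepsc_trace(mini_sim_config(
      rate = rate, amplitude_mean = -15, noise_sd = 2, duration = 60,
      seed = seed0 + i))
    ev <- detect_events(sim$trace, tpl, 4)
    summarize_minis(ev, 60)
  })
}

groups <- list(wt = sim_cells(5.5, 12, 700), mut = sim_cells(7.6, 12, 800))

freq <- lapply(groups, vapply, function(s) s$frequency_hz, numeric(1))
amp <- lapply(groups, vapply, function(s) s$mean_amplitude_pA, numeric(1))

cf <- compare_groups(freq, "mann_whitney")
ca <- compare_groups(amp, "mann_whitney")
cat(sprintf("frequency: wt %.2f +/- %.2f Hz, mut %.2f +/- %.2f Hz (Mann-Whitney p = %.3g)\n",
            cf$descriptives$mean[1], cf$descriptives$sem[1],
            cf$descriptives$mean[2], cf$descriptives$sem[2], cf$p_value))
cat(sprintf("amplitude: wt %.2f +/- %.2f pA, mut %.2f +/- %.2f pA (p = %.3g)\n",
            ca$descriptives$mean[1], ca$descriptives$sem[1],
            ca$descriptives$mean[2], ca$descriptives$sem[2], ca$p_value))

utils::write.csv(rbind(cbind(measure = "frequency_hz", cf$descriptives,
                             p_value = cf$p_value),
                       cbind(measure = "amplitude_pA", ca$descriptives,
                             p_value = ca$p_value)),
                 "results/mepsc_groups.csv", row.names = FALSE)

# seal-test QC sweep: a healthy, a leaky and a low-resistance cell
qcs <- list(healthy = simulate_seal_test(-50, 10, 500, 60),
            leaky = simulate_seal_test(-250, 10, 500, 60),
            low_rm = simulate_seal_test(-50, 10, 80, 60))
qc_tab <- do.call(rbind, lapply(names(qcs), function(nm) {
  q <- qc_cell(qcs[[nm]])
  data.frame(cell = nm, leak_pA = q$leak_pA, rm_mohm = q$rm_mohm,
             tau_ms = q$tau_ms, cm_pf = q$cm_pf, include = q$include)
}))
utils::write.csv(qc_tab, "results/mepsc_cell_qc.csv", row.names = FALSE)
print(qc_tab, row.names = FALSE)
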