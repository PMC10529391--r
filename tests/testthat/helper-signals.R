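# Shared fixtures: small synthetic ring-downs built in code.

ring_params <- function(fn_mhz = 2, zeta = 0.3, gain = 1e-7) {
  second_order_params(2 * pi * fn_mhz * 1e6, zeta, gain = gain)
}

# signal sampled near the identification-friendly rate (~spp samples/period)
ring_signal <- function(fn_mhz = 2, zeta = 0.3, gain = 1e-7, spp = 30,
                        n_samples = 2000, delay = 0, snr_db = NULL,
                        seed = NULL) {
  simulate_pa_signal(ring_params(fn_mhz, zeta, gain),
                     ts = 1 / (spp * fn_mhz * 1e6), n_samples = n_samples,
                     delay = delay, noise_snr_db = snr_db, seed = seed)
}
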