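# Shared fixtures: parameter sets used across the suite and a small study
# configuration. All data are generated in code.

agarose_04 <- function() springpot_params(k_alpha = 1500, alpha = 0.019)
agarose_03 <- function() springpot_params(k_alpha = 700, alpha = 0.020)
agarose_025 <- function() springpot_params(k_alpha = 400, alpha = 0.019)

# storage moduli (Pa) at the 0.1 Hz / 0.1% strain reference condition
organ_reference_pa <- c(heart = 1400, kidney = 600, liver = 200)
agarose_reference_pa <- c("0.25" = 400, "0.3" = 700, "0.4" = 1400)

ten_freqs <- function(lo = 0.1, hi = 1.2, n = 10) {
  10^seq(log10(lo), log10(hi), length.out = n)
}
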