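# shared fixtures: a small, fast transcript and strong pyrophosphatase so the
# pyrophosphate level is numerically negligible where tests require it

tiny_transcript <- function(n = 500L, f = c(A = .25, C = .25, G = .25, U = .25)) {
  transcript_spec("tiny", n, f)
}

ref_params <- function() ivt_reference_params()$params

quiet_ppiase <- function(...) ppiase_params(..., quiet = TRUE)

strong_ppiase <- function() ppiase_params(c_ppase = 1, quiet = TRUE)

equimolar <- function(c0 = 10000) c(A = c0, C = c0, G = c0, U = c0)

# independent oracle: integrated Michaelis-Menten closed form for the limiting
# substrate s(t), km*log(s0/s) + (s0 - s) = k*t, solved by root bracketing
integrated_mm_s <- function(t, s0, km, k) {
  vapply(t, function(tt) {
    if (tt <= 0) return(s0)
    g <- function(s) km * log(s0 / s) + (s0 - s) - k * tt
    if (g(s0 * 1e-12) < 0) return(s0 * 1e-12)
    stats::uniroot(g, lower = s0 * 1e-12, upper = s0, tol = 1e-12)$root
  }, numeric(1))
}
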