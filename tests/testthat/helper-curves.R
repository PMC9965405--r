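# Reference parameterizations used across tests: the Gompertz plateaus and
# shape parameters of the two release media, and the photodegradation
# endpoints (82% unirradiated, 57% after 10 h).
pbs_gompertz <- c(Qmax = 83, alpha = 0.83, beta = -2.7)
ph3_gompertz <- c(Qmax = 70, alpha = 0.97, beta = -1.5)

noiseless_curve <- function(model, params, ...) {
  generate_release_curve(model = model, params = params, sigma = 0, ...)
}
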