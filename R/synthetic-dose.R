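#' Simulate a dose-response table from a four-parameter logistic curve
#'
#' Responses are drawn as `eval_4pl(params, conc) + N(0, noise_sd)`, e.g. an
#' event-frequency readout over an agonist concentration ramp.
#'
#' @param bottom,top,ec50,hill 4PL parameters (see [four_pl()]).
#' @param concentrations strictly positive concentrations (nM).
#' @param noise_sd Gaussian noise standard deviation in response units.
#' @param seed integer RNG seed.
#' @return data frame with columns `conc_nM`, `response`.
#' @export
simulate_dose_response <- function(bottom, top, ec50, hill,
                                   concentrations, noise_sd = 0, seed = 1L) {
  if (any(concentrations <= 0))
    stop_field("concentrations", "must be strictly positive")
  params <- four_pl(bottom, top, ec50, hill)
  with_seed(seed, {
    resp <- eval_4pl(params, concentrations) +
      stats::rnorm(length(concentrations), 0, noise_sd)
    data.frame(conc_nM = concentrations, response = resp)
  })
}
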