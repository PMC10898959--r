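# shared fixtures for simulation-based tests

no_exclusions <- setNames(rep(0, length(default_exclusion_fractions())),
                          names(default_exclusion_fractions()))

null_links <- function() {
  lks <- lapply(c("pm25", "pm10", "co", "o3", "so2", "no2"),
                function(p) true_link("linear", slope_below = 0))
  names(lks) <- c("pm25", "pm10", "co", "o3", "so2", "no2")
  lks
}

# single-pollutant truth: the named pollutant gets `link`, others are null
one_pollutant_links <- function(pollutant, link) {
  lks <- null_links()
  lks[[pollutant]] <- link
  lks
}

# config for method-level simulations: no exclusions, no cryptogenic cases,
# so the classifier label is exactly Bernoulli(plogis(latent logit))
method_config <- function(n, links, seed, covariate_effects = list(),
                          cryptogenic_frac = 0, ...) {
  sim_config(n_participants = n, true_links = links,
             covariate_effects = covariate_effects,
             exclusion_fractions = no_exclusions,
             cryptogenic_frac = cryptogenic_frac,
             seed = seed, ...)
}

# generate a cohort and attach the classifier's MASLD label
labelled_cohort <- function(config) {
  g <- generate_cohort(config)
  p <- g$participants
  p$masld <- classify_masld(p)$category == "masld"
  p
}

small_covariate_vars <- c("age", "sex", "smoking", "alcohol_status", "fried_intake")
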