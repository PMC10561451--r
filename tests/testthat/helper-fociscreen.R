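# shared fixtures: small fields keep unit tests fast; acceptance tests use
# the default configuration

small_config <- function(cells_per_field = 10, ...) {
  sim_config(image_size = c(256L, 256L), cells_per_field = cells_per_field,
             ...)
}

# apply a multiplicative gain to a crop's green channel (pre-clipping) and
# renormalize — the brightness-robustness probe
gain_crop <- function(cr, g, offset = 0) {
  cr$green <- cr$green * g + offset
  cr$raw_green_mean <- mean(cr$green[cr$mask])
  normalize_crop(cr)
}

# a small trained classifier, built once per test run
trained_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tset <- make_training_set(3000, sim_config(), seed = 5)
      cache <<- list(model = train_classifier(tset), tset = tset)
    }
    cache
  }
})
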