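# Shared fixtures: small morphologies and compiled models built in code.

soma_only_morph <- function() {
  generate_surrogate(morpho_config(n_primary_dendrites = 0, n_sections = 1,
                                   n_segments = 1))
}

# hand-built two-section morphology (soma + one cylinder dendrite)
two_comp_morph <- function(dend_len = 100, dend_diam = 2) {
  secs <- rbind(
    data.frame(id = 1L, parent_id = NA_integer_, kind = "soma", length = 10,
               diam_prox = 10, diam_dist = 10, nseg = 1L,
               stringsAsFactors = FALSE),
    data.frame(id = 2L, parent_id = 1L, kind = "dend", length = dend_len,
               diam_prox = dend_diam, diam_dist = dend_diam, nseg = 1L,
               stringsAsFactors = FALSE))
  dlgnIN:::new_morphology(secs, "two-comp")
}

# passive-only parameter set resting exactly at E_pas
passive_params <- function(e_pas = -70) {
  p <- parameter_set("P1")
  p$E_pas <- e_pas
  p$V_rest <- e_pas
  p
}

# default surrogate morphology, cached across tests
default_morph <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- generate_surrogate(morpho_config())
    m
  }
})

# compiled full models on the default surrogate, cached
default_model <- local({
  cache <- list()
  function(name = "P1") {
    if (is.null(cache[[name]]))
      cache[[name]] <<- compile_model(default_morph(), parameter_set(name))
    cache[[name]]
  }
})
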