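# shared fixtures, built once per test run (the protocol machinery is the
# expensive part; every test file reads from this cache)
rg_cache <- new.env(parent = emptyenv())

rg_model <- function() {
  if (is.null(rg_cache$model)) rg_cache$model <- skeleton_model()
  rg_cache$model
}

rg_ref <- function() {
  if (is.null(rg_cache$ref)) rg_cache$ref <- generate_reference_gait()
  rg_cache$ref
}

rg_setup <- function() {
  if (is.null(rg_cache$setup)) {
    rg_cache$setup <- reference_setup(rg_model(), rg_ref())
  }
  rg_cache$setup
}

# one experiment shared by the protocol and acceptance tests: the two
# hemiparetic plantarflexor conditions plus an explicit null condition
rg_experiment <- function() {
  if (is.null(rg_cache$experiment)) {
    rg_cache$experiment <- run_experiment(rg_setup(), list(
      feedback_condition("soleus", 3, 3, "stroke", label = "soleus_stroke"),
      feedback_condition("gastrocnemius", 3, 3, "stroke",
                         label = "gastrocnemius_stroke"),
      feedback_condition("soleus", 1, 1, "reference", label = "null")))
  }
  rg_cache$experiment
}

ref_params <- function(group = "soleus") {
  tab <- default_spindle_params("reference")
  row <- tab[tab$muscle_group == group, ]
  spindle_params(group, row$tau_l_s, row$tau_v_s, row$g_l, row$g_v)
}

stroke_params <- function(group = "soleus") {
  tab <- default_spindle_params("stroke")
  row <- tab[tab$muscle_group == group, ]
  spindle_params(group, row$tau_l_s, row$tau_v_s, row$g_l, row$g_v)
}
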