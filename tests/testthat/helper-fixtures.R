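# Shared fixtures, built lazily once per test run. Everything derives
# from the pinned worked-example cohort (12 genes, 6 timepoints, 12
# instances, moderate noise, one +2 h chronotype instance).

fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(fx_cache[[name]])) fx_cache[[name]] <- builder()
  fx_cache[[name]]
}

fx_bundle_es <- function() {
  fx("bundle_es", function() {
    simulate_clock_data(chronotell:::worked_example_config(1103))
  })
}

fx_panel <- function() gene_panel(fx_bundle_es()$gene_ids)

fx_model <- function() {
  fx("model", function() clock_model(fx_bundle_es(), fx_panel()))
}

fx_base_pred <- function() {
  fx("base_pred", function() {
    predict(fx_model(), fx_bundle_es(), classify = FALSE)
  })
}

fx_loo_sample <- function() {
  fx("loo_sample", function() {
    suppressWarnings(leave_one_out(fx_bundle_es(), fx_panel(),
                                   unit = "sample"))
  })
}

fx_loo_instance <- function() {
  fx("loo_instance", function() {
    leave_one_out(fx_bundle_es(), fx_panel(), unit = "instance")
  })
}

# tiny deterministic expression set for I/O and normalisation tests
fx_tiny_es <- function() {
  vals <- matrix(c(1, 2, 3, 4,
                   4, 3, 2, 1,
                   2, 4, 6, 8,
                   5, 1, 4, 2), nrow = 4, byrow = TRUE,
                 dimnames = list(c("geneA", "geneB", "geneC", "geneD"),
                                 paste0("s", 1:4)))
  expression_set(vals, times = c(0, 6, 12, 18),
                 instances = rep("liver", 4))
}

# a random PD matrix of dimension d
random_pd <- function(d, scale = 1) {
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.1 * scale
}
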