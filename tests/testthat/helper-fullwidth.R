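# The full-multiplier network forward pass is expensive, so the shape audit
# is computed once and shared by the tests that consume it.
.fullwidth_cache <- new.env(parent = emptyenv())

get_fullwidth_audit <- function() {
  if (is.null(.fullwidth_cache$audit)) {
    t0 <- proc.time()
    set.seed(1)
    net <- build_network(detector_config())
    .fullwidth_cache$audit <- audit_shapes(net, seed = 1)
    .fullwidth_cache$elapsed <- unname((proc.time() - t0)["elapsed"])
    rm(net)
    gc(verbose = FALSE)
  }
  list(audit = .fullwidth_cache$audit, elapsed = .fullwidth_cache$elapsed)
}
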