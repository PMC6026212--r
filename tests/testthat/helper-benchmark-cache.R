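# The replicated SBM benchmark is expensive; several acceptance checks share
# one run. Results are memoized per configuration for the session.

.bench_cache <- new.env(parent = emptyenv())

cached_benchmark <- function(p_out, n_networks, base_seed = 1) {
  key <- sprintf("p%s_n%d_s%d", p_out, n_networks, base_seed)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- run_benchmark(
      n_networks = n_networks, base_seed = base_seed, p_out = p_out
    )
  }
  .bench_cache[[key]]
}

bench_rho <- function(bench, method) {
  bench$mean_rho[bench$method == method]
}
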