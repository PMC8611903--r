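# Shared fixtures built in code. The medium benchmark is cached per test
# session; the big (286-node) ones are built only inside the tests that
# need them.

tiny_graph_fixture <- function(n = 6, seed = 42) {
  make_benchmark(synthetic_spec(n_nodes = n, seed = seed))
}

medium_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_benchmark(synthetic_spec(n_nodes = 60, seed = 7))
    }
    cache
  }
})

# 4-node mirror layout: homolog pairs (1,3) and (2,4)
mirror_homolog4 <- c(3L, 4L, 1L, 2L)
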