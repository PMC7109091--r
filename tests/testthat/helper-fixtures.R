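# Shared helpers for building small in-code fixtures.

seeded_image <- function(side, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed(matrix(stats::runif(side * side), side, side))
}

tiny_spec <- function(...) {
  mcnn_spec(depth = 2, n_branches = 1, base_width = 3, seed = 7, ...)
}

# direct access to package internals for oracle-style checks
mrcnn_ns <- asNamespace("mrcnn")
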