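# Shared small fixtures, built in code once per test session.

mk_img <- function(z, pitch = 19.53, units = "nm", kind = "height")
  channel_image(z, pitch, units, kind)

rand_img <- function(n, m = n, seed = 1, pitch = 19.53) {
  set.seed(seed)
  mk_img(matrix(rnorm(n * m), n, m), pitch = pitch)
}

# tiny two-channel synthetic world used by pipeline-level unit tests
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(rows = 64L, cols = 64L,
                              channels = c("height", "rm_restored_adhesion"))
      cells <- generate_dataset(cfg, 6, base_seed = 314)
      cache <<- list(config = cfg, cells = cells)
    }
    cache
  }
})

tiny_run_config <- function(...) {
  run_config(channel_kinds = c("height", "rm_restored_adhesion"),
             registry = parameter_registry(c("Sa", "Sq", "Ssk", "Sku", "Sdq",
                                             "Sdr", "Ssc", "Sds")),
             k = 6L, n_trees = 100L, seeds = 7L, ...)
}

# small labeled feature table built directly from numbers
mk_table <- function(X, label, cell_id = sprintf("c%02d", seq_len(nrow(X)))) {
  afmtexture:::new_feature_table(X, cell_id, label)
}

# linearly separable two-feature toy table: class high shifted by `sep` sd
toy_table <- function(n_per_class = 30, sep = 5, seed = 42, p_noise = 0) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  lab <- rep(c("low", "high"), each = n_per_class)
  X[lab == "high", ] <- X[lab == "high", ] + sep
  if (p_noise > 0)
    X <- cbind(X, matrix(rnorm(n * p_noise), n,
                         dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  mk_table(X, lab)
}
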