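# small cohort configuration for fast structural tests
tiny_config <- function(seed = 1, ...) {
  cohort_config(n_per_group = c(LFG = 4, LTG = 4, RFG = 4, RTG = 4, HC = 6),
                n_timepoints = 80, seed = seed, ...)
}

# raw samples with exactly the requested mean and sd (n >= 2)
exact_sample <- function(mean, sd, n) {
  x <- seq_len(n)
  as.numeric(mean + sd * scale(x))
}

# quick 3-node correlated series for edge tests
three_node_ts <- function(n = 200, r = 0.3, seed = 1,
                          nodes = c("lIFG", "lMFG", "lSTG")) {
  set.seed(seed)
  cm <- matrix(r, 3, 3); diag(cm) <- 1
  dimnames(cm) <- list(nodes, nodes)
  simulate_subject(cm, n)
}
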