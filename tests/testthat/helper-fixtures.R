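# Shared fixtures: all built in code at test time.

# the default coarse template used across tests
tpl_default <- make_region_template()

# a deterministic, noise-free print configuration
config_noiseless <- function(frog_effect = 1, ...) {
  print_config(rot_sd_deg = 0, trans_sd_cm = 0, pixel_noise_sd = 0,
               region_noise_sd = 0, frog_effect = frog_effect, ...)
}

# simulate one foot and split its strikes into identity-registered
# before/after stacks (no pose noise -> no registration needed)
null_condition_stacks <- function(seed, config = NULL, template = tpl_default,
                                  is_effect_foot = FALSE) {
  if (is.null(config)) {
    config <- print_config(rot_sd_deg = 0, trans_sd_cm = 0, seed = seed)
  }
  st <- simulate_foot_strikes(template, config,
                              is_effect_foot = is_effect_foot, seed = seed)
  cond <- vapply(st, `[[`, NA_character_, "condition")
  list(before = stack_from_prints(st[cond == "before"]),
       after = stack_from_prints(st[cond == "after"]),
       strikes = st)
}

# small all-positive print stacks (every pixel in the mask) from a matrix
# of per-strike pixel rows; used for scalar-oracle t-field tests
stacks_from_matrix <- function(B, A, nr, nc) {
  to_prints <- function(M, condition) {
    lapply(seq_len(nrow(M)), function(i) {
      peak_print(matrix(M[i, ], nr, nc), condition = condition,
                 strike_id = i)
    })
  }
  list(before = stack_from_prints(to_prints(B, "before")),
       after = stack_from_prints(to_prints(A, "after")))
}

# independent connected-components oracle (recursive flood fill, 4-neighbour)
flood_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- p[1]; c <- p[2]
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask)) next
      if (!mask[r, c] || lab[r, c] > 0L) next
      lab[r, c] <- cur
      queue <- c(queue, list(c(r - 1, c), c(r + 1, c),
                             c(r, c - 1), c(r, c + 1)))
    }
  }
  lab
}

# build a cluster_result by hand (for classification-rule tests)
manual_cluster_result <- function(clusters, threshold = 2.1, df = 26) {
  structure(list(clusters = clusters, threshold = threshold, df = df,
                 n_perm = 999L, exhaustive = FALSE, alpha = 0.05,
                 seed = 1L, perm_max = numeric()),
            class = "cluster_result")
}
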