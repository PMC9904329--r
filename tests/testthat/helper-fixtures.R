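# Shared fixtures and independent oracles.

exp1_levels <- function() c(-8, -6, -4, -2, -1, 0, 1, 2, 4, 6, 8)

default_board <- make_board()

# Brute-force hypergeometric oracle: enumerate every way of placing n_total
# objects on distinct cells of an urn with N_v visible and N_h hidden cells,
# and count how many placements leave exactly n_v objects visible.
enum_visible_pmf <- function(N_v, N_h, n_total) {
  cells <- c(rep(TRUE, N_v), rep(FALSE, N_h))  # TRUE = visible cell
  if (n_total == 0) return(c(`0` = 1))
  placements <- utils::combn(length(cells), n_total)
  visible_counts <- apply(placements, 2, function(idx) sum(cells[idx]))
  table(factor(visible_counts, levels = 0:n_total)) / ncol(placements)
}

# Mean recovered location over replicate simulated observers (selection or
# confidence task on the experiment-1 mixed-condition design).
recover_location <- function(task = c("selection", "confidence"), gen_params,
                             n_replicates, seed_base) {
  task <- match.arg(task)
  trials <- enumerate_trials(1)
  mixed <- trials[trials$condition == "mixed", ]
  vapply(seq_len(n_replicates), function(i) {
    seed <- seed_base + i
    if (task == "selection") {
      resp <- simulate_selection(mixed, gen_params, rng_seed = seed)
      pl <- prop_by_level(resp)
      fit_psychometric(pl$delta_n, pl$prop)$pse
    } else {
      resp <- simulate_confidence(mixed, gen_params, rng_seed = seed)
      pl <- prop_by_level(resp)
      fit_confidence(pl$delta_n, pl$prop)$mu
    }
  }, numeric(1))
}

# Noiseless condition-mean hidden estimates on the 18-cell estimation design
# (visible counts 6..14 under the small and large occluder urns).
exp2_cell_means <- function(prior, urns = exp2_urns("paper")) {
  cells <- expand.grid(n_v = 6:14, occluder = names(urns),
                       stringsAsFactors = FALSE)
  cells$mean_estimate <- mapply(function(n, o) predict_hidden(n, urns[[o]], prior),
                                cells$n_v, cells$occluder)
  cells
}
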