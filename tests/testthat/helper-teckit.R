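bin_cols <- paste0("bin", 1:7)

## total variation distance between two discrete distributions on a shared
## support (given as aligned probability vectors)
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

## chi-square goodness-of-fit p-value of observed counts against oracle
## probabilities, pooling all cells with expected count < 5 into one
chisq_gof_p <- function(counts, probs) {
  n <- sum(counts)
  probs <- pmax(probs, 0)
  probs <- probs / sum(probs)
  small <- n * probs < 5
  obs <- c(counts[!small], sum(counts[small]))
  ex <- c(probs[!small], sum(probs[small]))
  keep <- ex > 0
  suppressWarnings(
    stats::chisq.test(obs[keep], p = ex[keep] / sum(ex[keep]))$p.value
  )
}

## smallest GOF p-value across the observation times of one config
min_gof_p <- function(params, landscape, template = default_template()) {
  d <- simulate_ensemble(params, landscape, template)
  o <- transient_distribution(params, landscape, template)
  min(vapply(params$obs_times, function(t) {
    chisq_gof_p(d$count[d$time_s == t], o$prob[o$time_s == t])
  }, numeric(1)))
}

## a small two-condition study for pipeline tests
small_study <- function(n_molecules = 1500, master_seed = 101,
                        variants = c("HTkA-free", "WT"),
                        keep_distributions = FALSE) {
  generate_study(
    conditions = tibble::tibble(variant = variants, tfs = FALSE,
                                n_replicates = 2L),
    params = sim_params(n_molecules = n_molecules),
    master_seed = master_seed,
    keep_distributions = keep_distributions
  )
}

## exact exponential-decay bin tables for half-life estimator tests: bin-1
## fraction decays at rate k, remainder parked in bin 4
exp_decay_bin_table <- function(k, condition = "X", tfs = FALSE,
                                times = c(15, 240), replicate = 1L) {
  b1 <- exp(-k * times)
  tibble::tibble(
    condition = condition, tfs = tfs, replicate = replicate, time_s = times,
    bin1 = b1, bin2 = 0, bin3 = 0, bin4 = 1 - b1, bin5 = 0, bin6 = 0, bin7 = 0
  )
}
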