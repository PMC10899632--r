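scheme <- default_bin_scheme()

test_that("mean transcript length is the midpoint-weighted bin average", {
  expect_equal(mean_transcript_length(c(1, 0, 0, 0, 0, 0, 0), scheme), 58)
  expect_equal(mean_transcript_length(c(0, 0, 0, 0, 0, 0, 1), scheme), 216.5)
  expect_equal(mean_transcript_length(rep(1 / 7, 7), scheme),
               mean(scheme$midpoint))
  expect_equal(scheme$midpoint, c(58, 72.5, 101.5, 130.5, 159.5, 188, 216.5))
  expect_error(mean_transcript_length(rep(0.2, 7), scheme), "sum to 1")
  expect_error(mean_transcript_length(rep(1 / 6, 6), scheme), "7")
})

test_that("the rate statistic is exact on linear mean-length growth and zero when stalled", {
  times <- c(15, 30, 60, 120, 240)
  ## place mass on bins 1 and 7 so that Lbar(t) = 58 + 0.5 t exactly
  f7 <- 0.5 * times / (216.5 - 58)
  bt <- tibble::tibble(
    time_s = times, bin1 = 1 - f7, bin2 = 0, bin3 = 0, bin4 = 0, bin5 = 0,
    bin6 = 0, bin7 = f7
  )
  expect_equal(average_elongation_rate(bt, scheme), 0.5, tolerance = 1e-12)

  stalled <- tibble::tibble(time_s = times, bin1 = 1, bin2 = 0, bin3 = 0,
                            bin4 = 0, bin5 = 0, bin6 = 0, bin7 = 0)
  expect_equal(average_elongation_rate(stalled, scheme), 0)

  bt0 <- dplyr::mutate(stalled, time_s = c(0, 30, 60, 120, 240))
  expect_error(average_elongation_rate(bt0, scheme), "t = 0")
})

test_that("simulated barrier-free rate matches the oracle-derived statistic", {
  tpl <- default_template()
  free <- make_landscape(tpl, "HTkA-free")
  p <- sim_params(k_step = 0.5, k_release = 10, n_molecules = 5000, seed = 41)
  d <- simulate_ensemble(p, free, tpl)
  r_sim <- average_elongation_rate(bin_distribution(d, scheme), scheme)
  o <- transient_distribution(p, free, tpl)
  r_oracle <- average_elongation_rate(bin_distribution(o, scheme), scheme)
  expect_lt(abs(r_sim - r_oracle) / r_oracle, 0.05)
})

test_that("relative rates are plain ratios against the histone-free rate", {
  expect_equal(relative_rate(0.4, 0.5), 0.8)
  expect_equal(relative_rate(0.37, 0.37), 1)
  expect_error(relative_rate(0.4, 0), "r_free")
})

test_that("relative rate decreases strictly with first-barrier strength", {
  tpl <- default_template()
  p <- sim_params()
  rates <- vapply(c(1, 3, 10, 30, 100), function(b) {
    land <- make_landscape(tpl, "custom", barrier_factors = b,
                           first_only = TRUE)
    o <- transient_distribution(p, land, tpl)
    average_elongation_rate(bin_distribution(o, scheme), scheme)
  }, numeric(1))
  rel <- relative_rate(rates, rates[1])
  expect_equal(rel[1], 1)
  expect_true(all(diff(rel) < 0))
})

test_that("the two-point exponential fit inverts exact decay at machine precision", {
  pk <- pause_half_life(0.5, 0.25, t1 = 15, t2 = 240)
  expect_equal(pk$t_half, 225)

  flat <- pause_half_life(0.4, 0.4)
  expect_equal(flat$k, 0)
  expect_false(flat$defined)
  expect_true(is.na(flat$t_half))

  ## oracle closed-form fractions must be inverted exactly
  pk2 <- pause_half_life(exp(-0.15), exp(-2.4), t1 = 15, t2 = 240)
  expect_equal(pk2$t_half, log(2) / 0.01, tolerance = 1e-6)

  ## analytic identity across a parameter grid
  for (k in c(2e-3, 5e-3, 1e-2, 5e-2)) {
    for (tt in list(c(15, 240), c(10, 100), c(30, 960))) {
      pk <- pause_half_life(exp(-k * tt[1]), exp(-k * tt[2]),
                            t1 = tt[1], t2 = tt[2])
      expect_equal(pk$t_half, log(2) / k, tolerance = 1e-12)
    }
  }

  expect_error(pause_half_life(0, 0.2), "C1 and C2")
  expect_error(pause_half_life(0.5, -1), "C1 and C2")
  expect_error(pause_half_life(0.5, 0.2, t1 = 240, t2 = 15), "t2")
})

test_that("half-life tables normalize to the reference row exactly", {
  bt <- dplyr::bind_rows(
    exp_decay_bin_table(0.01, condition = "WT"),
    exp_decay_bin_table(0.02, condition = "A"),
    exp_decay_bin_table(0.04, condition = "B")
  )
  hl <- half_life_table(bt)
  rel <- relative_half_life(hl, reference_condition = "WT",
                            reference_tfs = FALSE)
  expect_identical(rel$rel_t_half[rel$condition == "WT"], 1)
  expect_equal(rel$rel_t_half[rel$condition == "A"], 0.5)
  expect_equal(rel$rel_t_half[rel$condition == "B"], 0.25)
  expect_error(relative_half_life(hl, reference_condition = "Z"), "missing")

  undef <- half_life_table(
    exp_decay_bin_table(0, condition = "WT")  # no decay: C2 = C1
  )
  expect_false(undef$defined)
  expect_error(relative_half_life(undef), "undefined")
})

test_that("TFS release acceleration strictly shortens the estimated stall half-life", {
  k <- 0.01
  for (mult in c(1.5, 2, 4)) {
    minus <- half_life_table(exp_decay_bin_table(k, condition = "WT"))
    plus <- half_life_table(
      exp_decay_bin_table(k * mult, condition = "WT", tfs = TRUE)
    )
    expect_lt(plus$t_half, minus$t_half)
    expect_equal(plus$t_half, minus$t_half / mult, tolerance = 1e-12)
  }
})

test_that("full-length fraction reads bin 7", {
  bt <- exp_decay_bin_table(0.01)
  expect_equal(full_length_fraction(bt), bt$bin7)
  expect_error(full_length_fraction(bt[, 1:5]), "bin7")
})

test_that("replicate summaries give mean, SE, and flag singletons", {
  res <- tibble::tibble(condition = "WT", tfs = FALSE, rate = c(0.4, 0.6))
  s <- summarize_replicates(res)
  expect_equal(s$mean, 0.5)
  expect_equal(s$se, 0.1)
  expect_equal(s$n, 2)

  same <- tibble::tibble(condition = "WT", tfs = FALSE, rate = rep(0.5, 4))
  expect_equal(summarize_replicates(same)$se, 0)

  one <- tibble::tibble(condition = "WT", tfs = FALSE, rate = 0.5)
  expect_true(is.na(summarize_replicates(one)$se))

  expect_error(summarize_replicates(res[0, ]), "no replicate")
  expect_error(summarize_replicates(res, value = "nope"), "nope")
})

test_that("compute_kinetics assembles rates, summaries and half-lives coherently", {
  bt <- generate_study(
    conditions = tibble::tibble(variant = c("HTkA-free", "WT", "E19K/G52K"),
                                tfs = FALSE, n_replicates = 2L),
    params = sim_params(n_molecules = 1500),
    master_seed = 31
  )
  kin <- compute_kinetics(bt)
  expect_s3_class(kin, "tec_kinetics")
  expect_equal(nrow(kin$per_replicate), 6)
  free <- kin$per_replicate$rel_rate[kin$per_replicate$condition == "HTkA-free"]
  expect_equal(mean(free), 1, tolerance = 1e-12)
  ## chromatin slows elongation, the double mutant most
  s <- kin$summary
  expect_lt(s$rel_rate[s$condition == "WT"], 1)
  expect_lt(s$rel_rate[s$condition == "E19K/G52K"],
            s$rel_rate[s$condition == "WT"])
  expect_identical(
    kin$half_lives$rel_t_half[kin$half_lives$condition == "WT"], 1)
  expect_true(all(kin$full_length$full_length >= 0 &
                    kin$full_length$full_length <= 1))

  expect_equal(tidy(kin), kin$per_replicate)
  gl <- glance(kin)
  expect_equal(gl$n_replicates, 6)
  expect_equal(gl$reference_condition, "WT")

  expect_error(
    compute_kinetics(dplyr::filter(bt, condition != "HTkA-free")),
    "histone-free"
  )
})
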