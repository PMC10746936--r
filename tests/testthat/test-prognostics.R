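test_that("module scores average the available (z-scored) module genes", {
  vals <- rbind(g1 = c(1, -1), g2 = c(3, -3), g3 = c(5, -5))
  colnames(vals) <- c("s1", "s2")
  st <- expression_study("X", vals, c("disease", "control"),
                         require_min_samples = FALSE)
  # raw column means before any scaling
  expect_equal(unname(module_score(st, c("g1", "g2", "g3"), zscore = FALSE)),
               c(3, -3))
  # centered pair rows z-score to +-1/sqrt(2) (sample sd convention)
  z <- module_score(st, c("g1", "g2", "g3"))
  expect_equal(unname(z), c(1, -1) / sqrt(2))
  # single-gene module equals that gene's z-row
  expect_equal(module_score(st, "g2"),
               zscore_normalize(st)$values["g2", ])
  expect_warning(s <- module_score(st, c("g1", "nope")), "absent")
  expect_equal(unname(s), unname(module_score(st, "g1")))
  expect_error(module_score(st, "nope"), "no module gene")
})

test_that("median split sends ties low and balances distinct scores", {
  g <- assign_risk_groups(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(unname(g), c("low", "low", "high", "high"))
  g2 <- assign_risk_groups(c(1, 1, 2))
  expect_equal(unname(g2), c("low", "low", "high"))
  expect_error(assign_risk_groups(c(2, 2, 2)), "identical")
  expect_error(assign_risk_groups(1), "at least 2")
})

test_that("Kaplan-Meier estimates equal the hand product-limit values", {
  # all events
  t1 <- data.frame(time = c(5, 10, 15), event = c(1, 1, 1))
  km1 <- km_estimate(t1)
  expect_equal(km1$event_times, c(5, 10, 15))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km1$at_risk, c(3, 2, 1))
  # censoring at 10: risk set 1 at t = 15
  t2 <- data.frame(time = c(5, 10, 15), event = c(1, 0, 1))
  km2 <- km_estimate(t2)
  expect_equal(km2$event_times, c(5, 15))
  expect_equal(km2$survival, c(2 / 3, 0))
  # all censored: flat at 1
  t3 <- data.frame(time = c(5, 10), event = c(0, 0))
  km3 <- km_estimate(t3)
  expect_length(km3$event_times, 0)
  expect_equal(km_survival_at(km3, c(0, 100)), c(1, 1))
  expect_error(km_estimate(data.frame(time = -1, event = 1)), "negative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:15, 1)
    tt <- round(rexp(n, 0.1), 1)
    km <- km_estimate(data.frame(time = tt, event = 1))
    for (j in seq_along(km$event_times)) {
      expect_equal(km$survival[j], mean(tt > km$event_times[j]),
                   tolerance = 1e-12)
    }
    # and matches the loop oracle with random censoring too
    ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0) next
    kmc <- km_estimate(data.frame(time = tt, event = ev))
    orc <- oracle_km(tt, ev)
    expect_equal(kmc$event_times, orc$event_times)
    expect_equal(kmc$survival, orc$survival, tolerance = 1e-12)
    expect_equal(kmc$at_risk, orc$at_risk)
  }
})

test_that("two-group log-rank matches the O-E/V oracle on small tables", {
  tab <- data.frame(time = 1:6, event = 1)
  grp <- rep(c("A", "B"), each = 3)
  got <- logrank_test(tab, grp)
  expect_equal(got$statistic, oracle_logrank(tab$time, tab$event, grp),
               tolerance = 1e-10)

  # identical groups: statistic 0, p 1
  tab2 <- data.frame(time = c(1, 2, 3, 1, 2, 3), event = 1)
  got2 <- logrank_test(tab2, rep(c("A", "B"), each = 3))
  expect_equal(got2$statistic, 0, tolerance = 1e-12)
  expect_equal(got2$p_value, 1)

  # random small tables
  set.seed(77)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    tt <- sample(1:8, n, replace = TRUE) + runif(n) * 0.01
    ev <- rbinom(n, 1, 0.7)
    gg <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(gg)) < 2 || sum(ev) == 0) next
    if (sum(ev[gg == "A"]) + sum(ev[gg == "B"]) == 0) next
    got <- logrank_test(data.frame(time = tt, event = ev), gg)
    expect_equal(got$statistic, oracle_logrank(tt, ev, gg),
                 tolerance = 1e-10)
  }
})

test_that("log-rank is invariant to label swap and time rescaling", {
  set.seed(13)
  tt <- rexp(30); ev <- rbinom(30, 1, 0.8)
  gg <- rep(c("A", "B"), 15)
  s1 <- logrank_test(data.frame(time = tt, event = ev), gg)$statistic
  s2 <- logrank_test(data.frame(time = tt, event = ev),
                     ifelse(gg == "A", "B", "A"))$statistic
  s3 <- logrank_test(data.frame(time = tt * 365, event = ev), gg)$statistic
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(s1, s3, tolerance = 1e-12)
  expect_error(logrank_test(data.frame(time = tt, event = ev),
                            rep("A", 30)), "2 non-empty")
})

test_that("prognostic evaluation wires scores, groups, KM and log-rank", {
  cfg <- simulation_config(seed = 3, survival_beta = 1.5)
  set.seed(3)
  n <- 120
  genes <- paste0("g", 1:6)
  ids <- sprintf("P%03d", 1:n)
  base <- rnorm(n)
  vals <- t(sapply(genes, function(g) 8 + base + rnorm(n, sd = 0.4)))
  dimnames(vals) <- list(genes, ids)
  st <- expression_study("V", vals, rep("disease", n),
                         require_min_samples = FALSE)
  scores <- module_score(st, genes)
  surv <- simulate_survival(scores, cfg, seed = 3)
  rep <- evaluate_prognostic_module(surv, genes, st,
                                    stratify_by_stage = TRUE)
  expect_named(rep$km, c("high", "low"), ignore.order = TRUE)
  expect_true(rep$logrank$p_value < 0.05)
  expect_true(rep$prognostic)
  expect_equal(rep$n_excluded_unknown_stage, 0)
  expect_true(rep$logrank_stage$p_value < 0.05)
  # unknown stages excluded from stage analyses only
  surv2 <- surv; surv2$stage[1:2] <- "unknown"
  rep2 <- evaluate_prognostic_module(surv2, genes, st,
                                     stratify_by_stage = TRUE)
  expect_equal(rep2$n_excluded_unknown_stage, 2)
  expect_equal(rep2$logrank$p_value, rep$logrank$p_value)
  expect_error(evaluate_prognostic_module(
    data.frame(sample_id = "zz", time = 1, event = 1), genes, st),
    "no shared samples")
})
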