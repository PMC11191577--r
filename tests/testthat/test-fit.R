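test_that("the fitted-model object exposes the standard methods", {
  fit <- shared_fit108()
  expect_s3_class(fit, "lymph_hmm")
  expect_named(coef(fit),
               c("b1", "b2", "b3", "b4", "t12", "t23", "t34", "p_late"))
  expect_true(all(coef(fit) >= 0 & coef(fit) <= 1))

  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_lt(as.numeric(ll), 0)
  expect_equal(as.numeric(ll),
               cohort_log_likelihood(coef(fit), shared_cohort108()))
  expect_equal(attr(ll, "df"), 8)

  s <- summary(fit)
  expect_s3_class(s, "summary.lymph_hmm")
  expect_equal(nrow(s$posterior), 8)
  expect_output(print(s), "Posterior marginals")
  expect_output(print(fit), "posterior means")

  res <- residuals(fit)
  expect_equal(nrow(res), 16)
  expect_equal(sum(res$residual), 0, tolerance = 1e-10)
  expect_lt(max(abs(res$residual)), 0.2)
})

test_that("predict returns occult-involvement risks per level and draw", {
  fit <- shared_fit108()
  z <- c(I = 0, II = 1, III = 0, IV = 0)
  r <- predict(fit, diagnosis = z, stage = "early")
  expect_named(r, c("I", "II", "III", "IV"))
  expect_true(all(r >= 0 & r <= 1))
  # a level that tested positive carries more risk than under N0
  r_n0 <- predict(fit, diagnosis = c(I = 0, II = 0, III = 0, IV = 0),
                  stage = "early")
  expect_gt(r["II"], r_n0["II"])

  d <- predict(fit, diagnosis = z, stage = "late", level = c("II", "III"),
               type = "draws")
  expect_equal(dim(d), c(nrow(fit$samples$draws), 2))
  expect_equal(colMeans(d),
               predict(fit, diagnosis = z, stage = "late",
                       level = c("II", "III")))
  # joint involvement query
  rj <- predict(fit, diagnosis = z, stage = "early", level = "I+II")
  expect_lte(rj, min(predict(fit, diagnosis = z, stage = "early",
                             level = c("I", "II"))))
})

test_that("simulate draws reproducible cohorts from the fitted parameters", {
  fit <- shared_fit108()
  sim <- simulate(fit, seed = 2)
  expect_s3_class(sim, "lnl_cohort")
  expect_equal(nrow(sim), 108)
  expect_identical(sim, simulate(fit, seed = 2))
  sims <- simulate(fit, nsim = 2, seed = 2, n_early = 5, n_late = 5)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 10)
})

test_that("the Bayesian-network variant fits without a time parameter", {
  cohort <- simulate_cohort(n_early = 25, n_late = 15, seed = 12)
  fit <- lymph_hmm(cohort, model = "bn", n_steps = 60, burn_in = 30,
                   seed = 12)
  expect_named(coef(fit), c("b1", "b2", "b3", "b4", "t12", "t23", "t34"))
  expect_lt(fit$loglik, 0)
  r <- predict(fit, diagnosis = c(I = 0, II = 1, III = 0, IV = 0))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("configuration loading fills defaults and rejects bad input", {
  cfg <- load_config()
  expect_equal(cfg$observation$sensitivity, 0.81)
  expect_equal(cfg$observation$specificity, 0.63)
  expect_equal(cfg$time$t_max, 10L)

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("seed: 4", path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$seed, 4)
  expect_equal(cfg2$observation$sensitivity, 0.81)

  writeLines("observation:\n  sensitivity: 1.3", path)
  expect_error(load_config(path), "sensitivity")
  writeLines("observaton:\n  sensitivity: 0.8", path)
  expect_error(load_config(path), "unknown configuration key")
  expect_error(load_config("missing.yaml"), "not found")

  out <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, out)
  expect_equal(unclass(load_config(out))[c("seed", "observation", "time")],
               unclass(cfg)[c("seed", "observation", "time")])
})

test_that("the pipeline chains simulate, fit, risk and evaluate", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "config.yaml")
  writeLines(c("sampler:", "  n_steps: 40", "  burn_in: 20"), cfg_path)
  cohort_path <- file.path(dir, "cohort.csv")
  post_path <- file.path(dir, "posterior.csv")
  risk_path <- file.path(dir, "risk.csv")

  expect_equal(run_pipeline("simulate",
                            list(config = cfg_path, seed = 3,
                                 n_early = 12, n_late = 8,
                                 out = cohort_path)), 0L)
  expect_true(file.exists(cohort_path))
  suppressMessages(run_pipeline("fit", list(config = cfg_path, seed = 3,
                                            cohort = cohort_path,
                                            out = post_path)))
  expect_true(file.exists(post_path))
  expect_true(file.exists(paste0(post_path, ".summary.json")))
  draws <- read.csv(post_path, comment.char = "#")
  expect_equal(ncol(draws), 8)
  # artifacts embed seed and config hash
  expect_match(readLines(post_path, n = 2), "seed: 3", all = FALSE)
  expect_match(readLines(post_path, n = 2), "config_hash", all = FALSE)

  suppressMessages(run_pipeline("risk", list(
    config = cfg_path, seed = 3, posterior = post_path,
    diagnosis = "I=neg,II=pos,III=neg,IV=neg", stage = "late",
    level = "III", out = risk_path)))
  risk <- read.csv(risk_path, comment.char = "#")
  expect_equal(risk$level, "III")
  expect_true(risk$mean > 0 && risk$mean < 1)

  rep_dir <- file.path(dir, "report")
  suppressMessages(run_pipeline("evaluate", list(
    config = cfg_path, seed = 3, cohort = cohort_path, out = rep_dir)))
  expect_true(file.exists(file.path(rep_dir, "summary.json")))
  summ <- jsonlite::read_json(file.path(rep_dir, "summary.json"))
  expect_equal(sum(unlist(summ$fold_sizes)), 20)
  expect_true(all(is.finite(unlist(summ$heldout_loglik))))

  # empty cohort aborts with an actionable message
  empty_path <- file.path(dir, "empty.csv")
  writeLines("patient_id,t_stage,lvl_I,lvl_II,lvl_III,lvl_IV", empty_path)
  expect_error(run_pipeline("fit", list(cohort = empty_path,
                                        out = post_path)), "empty cohort")
})
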