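test_that("model_spec normalises interactions and enforces hierarchy", {
  s <- model_spec(c("a", "b"), list(c("b", "a")))
  expect_equal(s$interactions, list(c("a", "b")))  # order-insensitive
  expect_error(model_spec(c("a"), list(c("a", "b"))), "hierarchy")
  expect_error(model_spec(c("a", "a")), "duplicate")
  expect_error(model_spec(c("a", "b"),
                          list(c("a", "b"), c("b", "a"))), "duplicate")
  expect_error(model_spec("a", list(c("a", "a"))), "distinct")
})

test_that("design expansion covers categorical, interaction and order", {
  co <- tiny_cohort()
  sch <- attr(co, "schema")
  df <- as.data.frame(co)
  df$age_risk <- rep(c(0, 1, 2, 1), 10)
  co2 <- cohort_table(df, c(sch, age_risk = "categorical"))
  d <- build_design(model_spec("age_risk"), co2)
  expect_equal(colnames(d$X), c("age_risk=1", "age_risk=2"))
  # numeric interaction column is the product
  d2 <- build_design(model_spec(c("x1", "z"), list(c("x1", "z"))), co)
  expect_equal(colnames(d2$X), c("x1", "z", "x1:z"))
  expect_equal(d2$X[, "x1:z"], d2$X[, "x1"] * d2$X[, "z"])
  # deterministic column order across runs
  d3 <- build_design(model_spec(c("x1", "z"), list(c("x1", "z"))), co)
  expect_identical(colnames(d2$X), colnames(d3$X))
  # missing values in used columns are an error naming the column
  df$z[3] <- NA
  co3 <- cohort_table(df, c(sch, age_risk = "categorical"))
  expect_error(build_design(model_spec("z"), co3), "z")
  # unseen level at predict time is an error
  df2 <- as.data.frame(co2); df2$age_risk[1] <- 9
  co4 <- cohort_table(df2, c(sch, age_risk = "categorical"))
  expect_error(build_design(model_spec("age_risk"), co4,
                            xlev = d$xlev), "unseen")
})

test_that("fit_cox agrees with survival::coxph to high precision", {
  set.seed(201)
  n <- 400
  df <- data.frame(
    patient_id = sprintf("p%04d", 1:n), trial = "T",
    x = rbinom(n, 1, 0.5), z = rnorm(n),
    g = sample(c("lo", "mid", "hi"), n, TRUE))
  eta <- 0.7 * df$x - 0.4 * df$z + 0.5 * (df$g == "hi")
  df$time_days <- rexp(n, 0.002 * exp(eta))
  df$event <- rbinom(n, 1, 0.75)
  df$event[1] <- 1
  co <- cohort_table(df, c(x = "binary", z = "numeric",
                           g = "categorical"))
  spec <- model_spec(c("x", "z", "g"), list(c("x", "z")))
  fit <- fit_cox(spec, co)
  expect_true(fit$converged)
  ref <- survival::coxph(
    survival::Surv(time_days, event) ~ x + z + relevel(factor(g), "hi") +
      x:z, data = df, ties = "breslow")
  # align columns: reference coding order differs, compare by value set
  expect_equal(sort(unname(fit$coef)), sort(unname(coef(ref))),
               tolerance = 1e-6)
  expect_equal(sort(unname(fit$se)),
               sort(unname(sqrt(diag(vcov(ref))))), tolerance = 1e-6)
  # optimum partial likelihood is at least the null value
  expect_gte(fit$loglik[2], fit$loglik[1])
})

test_that("binary log-hazard of 0.7 is recovered at n = 2000", {
  set.seed(211)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.002 * exp(0.7 * x))
  cens <- rexp(n, 0.001)
  df <- data.frame(patient_id = as.character(1:n), trial = "T",
                   time_days = pmin(tt, cens),
                   event = as.numeric(tt <= cens), x = x)
  fit <- fit_cox(model_spec("x"), cohort_table(df, c(x = "binary")))
  expect_lt(abs(fit$coef[["x"]] - 0.7), 0.1)
})

test_that("null covariate z-statistics are calibrated", {
  set.seed(221)
  inside <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    n <- 500
    df <- data.frame(patient_id = as.character(1:n), trial = "T",
                     time_days = rexp(n, 0.002),
                     event = rbinom(n, 1, 0.8), x = rnorm(n))
    df$event[1] <- 1
    fit <- fit_cox(model_spec("x"), cohort_table(df, c(x = "numeric")))
    inside <- inside + (abs(fit$coef[["x"]] / fit$se[["x"]]) < 1.96)
  }
  expect_gte(inside / reps, 0.85)
})

test_that("singular designs are flagged, not fatal", {
  co <- tiny_cohort()
  df <- as.data.frame(co)
  df$x1dup <- df$x1  # duplicated column
  co2 <- cohort_table(df, c(attr(co, "schema"), x1dup = "binary"))
  expect_warning(fit <- fit_cox(model_spec(c("x1", "x1dup")), co2),
                 "singular")
  expect_false(fit$converged)
  expect_true(fit$singular)
  expect_error(predict_risk(fit, co2), "converge")
})

test_that("risk is the centered linear predictor", {
  co <- tiny_cohort()
  fit <- fit_cox(model_spec(c("x1", "z")), co)
  r <- predict_risk(fit, co)
  d <- build_design(fit$spec, co)
  expect_equal(unname(r),
               drop(sweep(d$X, 2, fit$center) %*% fit$coef))
  # a patient at the covariate origin scores minus the centering offset
  df <- as.data.frame(co)[1, ]
  df$x1 <- 0; df$z <- 0
  co1 <- cohort_table(df, attr(co, "schema"))
  expect_equal(unname(predict_risk(fit, co1)),
               -sum(fit$center * fit$coef), tolerance = 1e-12)
  # doubling a coefficient doubles that term's contribution
  fit2 <- fit
  fit2$coef[["z"]] <- 2 * fit$coef[["z"]]
  delta <- predict_risk(fit2, co) - r
  expect_equal(unname(delta),
               (as.data.frame(co)$z - fit$center[["z"]]) *
                 fit$coef[["z"]])
})

test_that("affine covariate rescaling leaves risk ranking unchanged", {
  co <- tiny_cohort(n = 60)
  fit <- fit_cox(model_spec(c("x1", "z")), co)
  df <- as.data.frame(co)
  df$z <- 10 * df$z + 5
  co2 <- cohort_table(df, attr(co, "schema"))
  fit2 <- fit_cox(model_spec(c("x1", "z")), co2)
  expect_equal(order(predict_risk(fit, co)),
               order(predict_risk(fit2, co2)))
})

test_that("fitted models survive a JSON round trip", {
  co <- tiny_cohort()
  fit <- fit_cox(model_spec(c("x1", "z"), list(c("x1", "z"))), co)
  f <- withr::local_tempfile(fileext = ".json")
  write_cox_model(fit, f)
  back <- read_cox_model(f)
  expect_equal(back$coef, fit$coef)
  expect_equal(predict_risk(back, co), predict_risk(fit, co))
})

test_that("end-to-end risk ranking is strongly concordant with truth", {
  sim <- generate_cohort(ci_sim_config(n = 900), seed = 7)
  spec <- model_spec(c("mh_01", "met_01", "lab_01", "lab_02"))
  fit <- fit_cox(spec, sim$cohort)
  r <- predict_risk(fit, sim$cohort)
  expect_gte(concordance_index(r, as_surv_outcome(sim$cohort)), 0.6)
})
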