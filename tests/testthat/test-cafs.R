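test_that("forward candidates follow the base-plus-interactions recipe", {
  s <- model_spec(c("A", "B"))
  fc <- forward_candidates(s, c("C", "D"))
  expect_length(fc, 6)  # 2 features x (1 base + 2 interactions)
  labels <- vapply(fc, format, "")
  expect_setequal(labels, c(
    "<model_spec> A + B + C", "<model_spec> A + B + C + A:C",
    "<model_spec> A + B + C + B:C", "<model_spec> A + B + D",
    "<model_spec> A + B + D + A:D", "<model_spec> A + B + D + B:D"))
  # empty spec: no interactions possible
  fc2 <- forward_candidates(model_spec(), "C")
  expect_length(fc2, 1)
  expect_equal(fc2[[1]]$main, "C")
  # excluded features never appear
  s2 <- model_spec("A", exclude = "D")
  fc3 <- forward_candidates(s2, c("C", "D"))
  expect_false(any(grepl("D", vapply(fc3, format, ""))))
  expect_length(forward_candidates(s, character()), 0)
})

test_that("candidate count formula |F| * (1 + |mains|) always holds", {
  set.seed(301)
  pool <- LETTERS[1:12]
  for (r in 1:25) {
    nm <- sample(0:5, 1)
    mains <- sample(pool, nm)
    ints <- if (nm >= 2 && runif(1) < 0.5)
      list(sort(sample(mains, 2))) else list()
    spc <- model_spec(mains, ints)
    space <- setdiff(pool, mains)
    space <- sample(space, sample(0:length(space), 1))
    expect_length(forward_candidates(spc, space),
                  length(space) * (1 + nm))
  }
})

test_that("backward removal preserves the term hierarchy", {
  s <- model_spec(c("A", "B"), list(c("A", "B")))
  bc <- backward_candidates(s)
  labels <- vapply(bc, format, "")
  expect_setequal(labels, c("<model_spec> B", "<model_spec> A",
                            "<model_spec> A + B"))
  s2 <- model_spec(c("A", "B", "C"))
  expect_length(backward_candidates(s2), 3)
  expect_true(all(vapply(backward_candidates(s2),
                         function(x) length(x$main) == 2, TRUE)))
  # one main: single candidate, the empty model
  bc3 <- backward_candidates(model_spec("A"))
  expect_length(bc3, 1)
  expect_length(bc3[[1]]$main, 0)
  expect_length(backward_candidates(model_spec()), 0)
  # candidate count = mains + interactions
  s3 <- model_spec(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  expect_length(backward_candidates(s3), 5)
})

test_that("backward then forward can reconstruct the original spec", {
  s <- model_spec(c("A", "B", "C"))
  bc <- backward_candidates(s)[[3]]  # drops C
  fc <- forward_candidates(bc, "C")
  expect_true(any(vapply(fc, function(x) cafsurv:::spec_equal(x, s),
                         TRUE)))
})

test_that("mc_cv is seed-deterministic and honours a metric stub", {
  co <- tiny_cohort(n = 80)
  cfg <- search_config(metric = function(risk, outcome) 0.7,
                       reps_screen = 10, reps_full = 20)
  res <- mc_cv(model_spec("x1"), co, 20, cfg)
  expect_equal(res$mean_metric, 0.7)
  expect_equal(res$sd_metric, 0)
  expect_equal(res$n_reps, 20)
  cfg2 <- search_config(metric = "cIndex", reps_screen = 10,
                        reps_full = 20, seed = 5)
  a <- mc_cv(model_spec(c("x1", "z")), co, 20, cfg2)
  b <- mc_cv(model_spec(c("x1", "z")), co, 20, cfg2)
  expect_identical(a, b)  # bit-identical at equal seeds
  c2 <- mc_cv(model_spec(c("x1", "z")), co, 20, cfg2, seed = 6)
  expect_false(identical(a$mean_metric, c2$mean_metric))
  # empty spec scores the constant-risk baseline exactly
  e <- mc_cv(model_spec(), co, 10, cfg2)
  expect_equal(e$mean_metric, 0.5)
})

test_that("mc_cv mean is stable under patient row permutation", {
  sim <- generate_cohort(ci_sim_config(n = 400), seed = 31)
  cfg <- search_config(metric = "cIndex", seed = 9)
  spec <- model_spec(c("mh_01", "lab_01"))
  a <- mc_cv(spec, sim$cohort, 150, cfg)
  perm <- withr::with_seed(1, sample(nrow(sim$cohort)))
  co2 <- cohort_table(as.data.frame(sim$cohort)[perm, ],
                      attr(sim$cohort, "schema"))
  b <- mc_cv(spec, co2, 150, cfg)
  expect_equal(a$mean_metric, b$mean_metric, tolerance = 0.02)
})

test_that("true-model CV beats a noise-only model across paired runs", {
  sim <- generate_cohort(ci_sim_config(n = 500), seed = 17)
  cfg <- search_config(metric = "cIndex")
  wins <- 0
  for (s in 1:5) {
    a <- mc_cv(model_spec(c("mh_01", "mh_02", "met_01")), sim$cohort,
               60, cfg, seed = s)
    b <- mc_cv(model_spec(c("mh_04", "pm_03")), sim$cohort, 60, cfg,
               seed = s)
    wins <- wins + (a$mean_metric > b$mean_metric)
  }
  expect_equal(wins, 5)
})

test_that("rescreening promotes exactly top_k and re-ranks", {
  co <- tiny_cohort(n = 80)
  # deterministic stub metric keyed on model size keeps this cheap
  cfg <- search_config(metric = function(risk, outcome) 0.5,
                       reps_screen = 5, reps_full = 10, top_k = 30)
  mk <- function(nm) model_spec(nm)
  cands <- lapply(paste0(rep(c("x1", "x2", "z"), 14)[1:40], ""),
                  function(v) mc_cv(mk(v), co, 5, cfg))
  resc <- rescreen_top(cands, co, cfg)
  expect_length(resc, 30)
  expect_true(all(vapply(resc, function(r) r$n_reps, 0L) == 10))
  resc5 <- rescreen_top(cands[1:5], co, cfg)
  expect_length(resc5, 5)
  # screening/rescreen consistency at honest metrics
  cfg2 <- search_config(metric = "cIndex", reps_screen = 60,
                        reps_full = 200, top_k = 3, seed = 3)
  sim <- generate_cohort(ci_sim_config(n = 400), seed = 23)
  cands2 <- lapply(list(model_spec("mh_01"), model_spec("mh_02"),
                        model_spec("lab_01")),
                   function(s) mc_cv(s, sim$cohort, 60, cfg2))
  resc2 <- rescreen_top(cands2, sim$cohort, cfg2)
  for (r in resc2) {
    scr <- Filter(function(c) cafsurv:::spec_equal(c$spec, r$spec),
                  cands2)[[1]]
    # screened mean agrees with the rescreened mean within its own
    # Monte-Carlo standard error band
    expect_lt(abs(scr$mean_metric - r$mean_metric),
              3 * max(scr$sd_metric / sqrt(60), 0.005))
  }
})

test_that("the curator hook controls the search", {
  sim <- generate_cohort(ci_sim_config(n = 300), seed = 41)
  cfg <- fast_config(metric = "cIndex", seed = 2)
  # a curator that always terminates: one-iteration trace, spec kept
  stopper <- function(best, candidates, trace, config)
    list(action = "terminate", rationale = "stop at once")
  init <- model_spec("mh_01")
  res <- cafs_search(init, sim$cohort, c("mh_02", "pm_01"), cfg,
                     curator = stopper)
  expect_length(res$trace, 1)
  expect_equal(res$trace[[1]]$action, "terminate")
  expect_true(cafsurv:::spec_equal(res$spec, init))
  # empty feature space with a real model: terminates unchanged
  res2 <- cafs_search(model_spec(c("mh_01", "met_01")), sim$cohort,
                      character(), cfg)
  expect_true(cafsurv:::spec_equal(res2$spec,
                                   model_spec(c("mh_01", "met_01"))))
  expect_equal(res2$trace[[length(res2$trace)]]$action, "terminate")
})

test_that("search replays identically from config and seed", {
  sim <- generate_cohort(ci_sim_config(n = 300), seed = 43)
  cfg <- search_config(metric = "cIndex", reps_screen = 20,
                       reps_full = 60, top_k = 4, max_iterations = 2,
                       seed = 11)
  space <- c("mh_01", "mh_02", "met_01", "lab_01")
  r1 <- cafs_search(model_spec(), sim$cohort, space, cfg)
  r2 <- cafs_search(model_spec(), sim$cohort, space, cfg)
  expect_identical(format(r1$spec), format(r2$spec))
  expect_identical(r1$result$mean_metric, r2$result$mean_metric)
})

test_that("branch exclusions bind and identical branches deduplicate", {
  sim <- generate_cohort(ci_sim_config(n = 300), seed = 47)
  cfg <- search_config(metric = "cIndex", reps_screen = 15,
                       reps_full = 40, top_k = 3, max_iterations = 2,
                       seed = 13)
  space <- c("mh_01", "mh_02", "met_01")
  expect_warning(
    fits <- branch_search(list(model_spec(), model_spec()), sim$cohort,
                          space, cfg, seeds = c(99L, 99L)),
    "dedup")
  expect_length(fits, 1)
  fits2 <- branch_search(list(model_spec()), sim$cohort, space, cfg,
                         exclusions = list("mh_01"))
  expect_false(any(grepl("mh_01", format(fits2[[1]]$spec))))
})
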