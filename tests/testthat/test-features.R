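test_that("binary block merging matches its three documented modes", {
  blk <- rbind(c(0, 1, 0), c(0, 0, 0))
  expect_equal(merge_binary_block(blk, "logical_or")$score, c(1, 0))
  blk2 <- rbind(c(1, 1, 0), c(1, 0, 0))
  expect_equal(merge_binary_block(blk2, "sum")$score, c(2, 1))
  # logical_or equals element-wise max over features
  set.seed(7)
  b <- matrix(rbinom(60, 1, 0.4), 10)
  expect_equal(merge_binary_block(b, "logical_or")$score,
               apply(b, 1, max))
  # weights reproduce scores when re-applied
  res <- merge_binary_block(b, "sum")
  expect_equal(apply_merge_weights(res$weights, b), res$score)
})

test_that("z-score weights equal independent univariable Cox Wald z", {
  set.seed(11)
  n <- 500
  x <- rbinom(n, 1, 0.4)
  tt <- rexp(n, 0.002 * exp(0.8 * x))
  ev <- as.numeric(tt <= quantile(tt, 0.8))
  tt <- pmin(tt, quantile(tt, 0.8))
  out <- surv_outcome(tt, ev)
  res <- merge_binary_block(matrix(x, ncol = 1), "zscore_sum",
                            outcome = out)
  ref <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = "breslow")
  z_ref <- unname(coef(ref) / sqrt(diag(vcov(ref))))
  expect_equal(res$weights$weights, z_ref, tolerance = 1e-6)
  expect_equal(res$score, x * z_ref, tolerance = 1e-6)
  # degenerate check: all weights forced to 1 reproduces mode = sum
  w1 <- res$weights; w1$weights[] <- 1
  expect_equal(apply_merge_weights(w1, matrix(x, ncol = 1)), x)
})

test_that("zscore_sum requires an outcome and zeroes constant features", {
  blk <- cbind(a = c(1, 0, 1, 0), b = c(1, 1, 1, 1))
  expect_error(merge_binary_block(blk, "zscore_sum"), "outcome")
  out <- surv_outcome(c(10, 20, 30, 40), c(1, 1, 0, 1))
  expect_warning(res <- merge_binary_block(blk, "zscore_sum", out),
                 "constant")
  expect_equal(res$weights$weights[2], 0)
})

test_that("protective/harmful labels follow the strict 1.64 rule", {
  set.seed(21)
  n <- 800
  harm <- rbinom(n, 1, 0.4)   # strong hazard increase -> z >> 1.64
  pro <- rbinom(n, 1, 0.4)    # strong hazard decrease -> z << -1.64
  nul <- rbinom(n, 1, 0.4)
  tt <- rexp(n, 0.002 * exp(1.2 * harm - 1.2 * pro))
  out <- surv_outcome(tt, rep(1, n))
  lab <- classify_protective_harmful(cbind(harm = harm, pro = pro,
                                           nul = nul), out)
  expect_gt(lab$z[lab$feature == "harm"], 1.64)
  expect_lt(lab$z[lab$feature == "pro"], -1.64)
  # labels are exactly the strict threshold rule applied to z
  expect_identical(lab$label,
                   ifelse(lab$z > 1.64, "protective",
                   ifelse(lab$z < -1.64, "harmful", "neutral")))
  # the comparison is strict: a z exactly at the threshold is neutral
  z_at <- abs(lab$z[lab$feature == "harm"])
  lab2 <- classify_protective_harmful(cbind(harm = harm), out,
                                      threshold = z_at)
  expect_identical(lab2$label, "neutral")
  # flip_sign swaps the two labels
  lab3 <- classify_protective_harmful(cbind(harm = harm, pro = pro),
                                      out, flip_sign = TRUE)
  expect_identical(lab3$label, c("harmful", "protective"))
  # constant feature is neutral with a warning
  expect_warning(lab4 <- classify_protective_harmful(
    cbind(k = rep(1, n)), out), "constant")
  expect_identical(lab4$label, "neutral")
})

test_that("a feature independent of outcome is usually neutral", {
  set.seed(31)
  n <- 600
  neutral <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.002)
    lab <- classify_protective_harmful(cbind(x = x),
                                       surv_outcome(tt, rep(1, n)))
    neutral <- neutral + (lab$label == "neutral")
  }
  # two-sided tail mass beyond +/-1.64 is ~10% under the null
  expect_gte(neutral / reps, 0.8)
})

test_that("TLV sums lesions, zeroes lesion-free patients, flags missing", {
  lt <- lesion_table(data.frame(
    patient_id = c("p1", "p1", "p2", "p3", "p3"),
    size = c(2, 3, 4, NA, NA),
    is_bone = c(0, 1, 0, 0, 1)))
  tlv <- compute_tlv(lt, c("p1", "p2", "p3", "p4"))
  expect_equal(unname(tlv), c(5, 4, NA, 0))
  # partial missingness: observed sizes summed, missing excluded
  lt2 <- lesion_table(data.frame(patient_id = c("q", "q"),
                                 size = c(7, NA), is_bone = c(0, 0)))
  expect_equal(unname(compute_tlv(lt2, "q")), 7)
})

test_that("TLV is additive over arbitrary splits of a lesion table", {
  set.seed(41)
  ids <- sprintf("p%02d", 1:10)
  nles <- rpois(10, 3) + 1
  lt <- lesion_table(data.frame(
    patient_id = rep(ids, nles),
    size = runif(sum(nles), 0.5, 5),
    is_bone = rbinom(sum(nles), 1, 0.3)))
  # oracle: independent group-by-sum
  oracle <- setNames(as.numeric(tapply(lt$size, lt$patient_id, sum)[ids]),
                     ids)
  expect_equal(compute_tlv(lt, ids), oracle)
  sel <- seq_len(nrow(lt)) %% 2 == 0
  a <- compute_tlv(lesion_table(as.data.frame(lt)[sel, ]), ids)
  b <- compute_tlv(lesion_table(as.data.frame(lt)[!sel, ]), ids)
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  expect_equal(a + b, oracle)
})

test_that("TLV imputation applies stratum mean-per-lesion times count", {
  # one deceased reference patient: TLV 10 over 2 lesions -> 5/lesion;
  # one censored reference patient: TLV 4 over 4 lesions -> 1/lesion
  imp <- impute_tlv(ref_tlv = c(10, 4), ref_lesion_count = c(2, 4),
                    ref_event = c(1, 0),
                    target_nonbone_count = c(3, 3, 0),
                    target_event = c(1, 0, 1))
  expect_equal(imp, c(15, 3, 0))
  # stratum-constant per-lesion volume v reproduces v * count
  imp2 <- impute_tlv(c(6, 6, 2, 4), c(3, 3, 1, 2), c(1, 1, 0, 0),
                     target_nonbone_count = c(2, 5),
                     target_event = c(1, 0))
  expect_equal(imp2, c(2 * 2, 2 * 5))
  expect_error(impute_tlv(c(5), c(1), c(1), 1, 0), "censored")
})

test_that("imputation on the reference itself is exact when volumes are
           stratum-constant with one lesion per patient", {
  tlv <- c(3, 3, 8, 8)
  ev <- c(0, 0, 1, 1)
  imp <- impute_tlv(tlv, rep(1, 4), ev, rep(1, 4), ev)
  expect_equal(imp, tlv)
})

test_that("lab PCA identifies factor-driven labs and projects exactly", {
  set.seed(51)
  # rank-1 case: two perfectly correlated labs
  x <- rnorm(50)
  labs <- cbind(a = x, b = 2 * x + 1)
  meta <- fit_lab_pca(labs, n_components = 2, loading_threshold = 0.25)
  expect_equal(meta$sdev[1]^2 / sum(meta$sdev^2), 1, tolerance = 1e-10)
  expect_setequal(meta$significant_labs, c("a", "b"))
  # projection at the stored centers is zero
  expect_equal(as.numeric(project_lab_pca(
    meta, matrix(meta$center, 1, dimnames = list(NULL, c("a", "b"))))),
    c(0, 0), tolerance = 1e-12)
  # projection equals the brute-force standardised matrix product
  new <- cbind(a = rnorm(7), b = rnorm(7))
  std <- sweep(sweep(new, 2, meta$center), 2, meta$scale, "/")
  expect_equal(project_lab_pca(meta, new), std %*% meta$loadings)
  # training scores reproduce fit-time scores and are centered,
  # with nonincreasing component variances
  sc <- project_lab_pca(meta, labs)
  expect_equal(colMeans(sc), c(PC1 = 0, PC2 = 0), tolerance = 1e-8)
  v <- apply(sc, 2, var)
  expect_true(all(diff(v) <= 1e-12))
  expect_error(fit_lab_pca(cbind(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("factor-loaded labs and only those are PC1-significant", {
  set.seed(61)
  n <- 1000
  f <- rnorm(n)
  labs <- cbind(
    sapply(1:6, function(i) 0.9 * f + rnorm(n, sd = 0.5)),
    sapply(1:4, function(i) rnorm(n)))
  colnames(labs) <- sprintf("lab%02d", 1:10)
  meta0 <- fit_lab_pca(labs, 2, loading_threshold = 0.01)
  thr <- max(abs(meta0$loadings[, 1])) / 2
  meta <- fit_lab_pca(labs, 2, loading_threshold = thr)
  expect_setequal(meta$significant_labs, sprintf("lab%02d", 1:6))
})

test_that("age and race recodings match the published mapping", {
  expect_equal(recode_age_risk(c(80, 60, 70)), c(0L, 1L, 2L))
  expect_equal(recode_age_risk(c(65, 75)), c(2L, 2L))  # inclusive bounds
  expect_equal(recode_age_risk(c(64.9, 75.1)), c(1L, 0L))
  expect_error(recode_age_risk(-1), "> 0")
  # image is exactly {0,1,2} over a dense sweep
  expect_setequal(unique(recode_age_risk(seq(1, 100, by = 0.5))),
                  c(0L, 1L, 2L))
  expect_equal(recode_race(c("white", "black", "Other", "ASIAN")),
               c(1L, 0L, 1L, 0L))
  expect_true(is.na(recode_race(NA)))
})

test_that("ECOG dual coding emits numeric and one-hot columns", {
  ec <- recode_ecog(c(0, 1, 2, 1))
  expect_named(ec, c("ecog_num", "ecog_0", "ecog_1", "ecog_2"))
  expect_equal(ec$ecog_num, c(0, 1, 2, 1))
  expect_equal(ec$ecog_1, c(0L, 1L, 0L, 1L))
})

test_that("harm_pro composite weights the two sums by their Wald z", {
  set.seed(71)
  n <- 800
  sh <- rpois(n, 2)
  sp <- rpois(n, 2)
  tt <- rexp(n, 0.002 * exp(0.4 * sh))
  out <- surv_outcome(tt, rep(1, n))
  hp <- derive_harm_pro(sp, sh, out)
  expect_equal(hp$score, hp$z_harm * sh + hp$z_pro * sp)
  expect_gt(abs(hp$z_harm), abs(hp$z_pro))
  # harmful sum identically zero: feature reduces to z_pro * sum_pro
  hp0 <- derive_harm_pro(sp, rep(0, n), out)
  expect_equal(hp0$z_harm, 0)
  expect_equal(hp0$score, hp0$z_pro * sp)
  # collinear sums are rejected
  expect_error(derive_harm_pro(sh, sh, out), "collinear|rank")
})

test_that("only the sum carrying hazard dominates across replicates", {
  set.seed(81)
  wins <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    n <- 500
    sh <- rpois(n, 2); sp <- rpois(n, 2)
    tt <- rexp(n, 0.002 * exp(0.5 * sh))
    hp <- derive_harm_pro(sp, sh, surv_outcome(tt, rep(1, n)))
    wins <- wins + (abs(hp$z_harm) > abs(hp$z_pro))
  }
  expect_gte(wins, 17)
})
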