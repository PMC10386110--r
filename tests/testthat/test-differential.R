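study_pm <- function() {
  fx <- streptomyces_presence_fixture()
  fc <- align_features(fx$features)
  pm <- suppressWarnings(build_presence_matrix(fc, design = fx$design))
  list(pm = pm, fc = fc)
}

cluster_masses <- function(pm, ids) {
  pm$clusters$consensus_mass[match(ids, pm$clusters$cluster_id)]
}

test_that("presence matrices cover the design and respect the intensity floor", {
  x <- study_pm()
  expect_equal(ncol(x$pm$presence), 18)  # 3 conditions x 6 weeks x 1 fraction
  expect_equal(nrow(x$pm$presence), 12)
  # control columns all-false except the single week-3 detection
  ctrl <- x$pm$presence[, x$pm$design$condition == "C", drop = FALSE]
  expect_equal(sum(ctrl), 1)

  # a floor above every intensity blanks the matrix
  pm0 <- suppressWarnings(build_presence_matrix(
    x$fc, design = x$pm$design[names(x$pm$design) != "sample_id"],
    intensity_floor = 1e9))
  expect_false(any(pm0$presence))

  dup <- rbind(x$pm$design, x$pm$design[1, ])
  expect_error(build_presence_matrix(x$fc, design = dup), "duplicate design")

  empty <- align_features(x$fc$members[0, names(x$fc$members) != "cluster_id"])
  pme <- suppressWarnings(build_presence_matrix(
    empty, design = x$pm$design[names(x$pm$design) != "sample_id"]))
  expect_equal(nrow(pme$presence), 0)
})

test_that("experimental-only detection reproduces the study fixture", {
  x <- study_pm()
  only <- detect_only_experimental(x$pm)
  expect_gte(length(only), 5)
  masses <- cluster_masses(x$pm, only)
  expect_true(any(abs(masses - 572.3175) < 1e-3))
  expect_false(any(abs(masses - 707.5335) < 1e-3))
  # never intersects clusters with any control presence
  ctrl_any <- rownames(x$pm$presence)[
    rowSums(x$pm$presence[, x$pm$design$condition == "C"]) > 0]
  expect_length(intersect(as.character(only), ctrl_any), 0)
})

test_that("experimental-only detection equals a brute-force column scan", {
  set.seed(61)
  for (rep in 1:25) {
    sim <- gen_feature_tables(sim_config(seed = rep + 1000,
                                         dropout_prob = 0.2))
    fc <- align_features(sim$features, mass_tol_ppm = 10, rt_tol_min = 0.5)
    pm <- suppressWarnings(build_presence_matrix(fc, design = sim$truth$design))
    got <- detect_only_experimental(pm)
    is_ctrl <- pm$design$condition == "C"
    want <- pm$clusters$cluster_id[apply(pm$presence, 1, function(row) {
      !any(row[is_ctrl]) && any(row[!is_ctrl])
    })]
    expect_equal(got, want)
  }
})

test_that("adding a control presence can only remove a cluster from the detector output", {
  x <- study_pm()
  only <- detect_only_experimental(x$pm)
  pm2 <- x$pm
  target <- match(only[1], pm2$clusters$cluster_id)
  pm2$presence[target, which(pm2$design$condition == "C")[1]] <- TRUE
  only2 <- detect_only_experimental(pm2)
  expect_false(only[1] %in% only2)
  expect_setequal(setdiff(only, only[1]), only2)
})

test_that("the detector requires control and experimental columns", {
  x <- study_pm()
  no_ctrl <- x$pm
  keep <- no_ctrl$design$condition != "C"
  no_ctrl$presence <- no_ctrl$presence[, keep, drop = FALSE]
  no_ctrl$design <- no_ctrl$design[keep, , drop = FALSE]
  expect_error(detect_only_experimental(no_ctrl), "no control")
})

test_that("the induction window recovers the late-eluting induced metabolites", {
  x <- study_pm()
  ids <- induced_in_window(x$pm, 10.6, 17.0)
  masses <- cluster_masses(x$pm, ids)
  for (m in c(264.0747, 436.2219, 439.2704, 440.3655, 270.1833, 212.2139,
              270.2561)) {
    expect_true(any(abs(masses - m) < 1e-3), info = sprintf("mass %.4f", m))
  }
  expect_length(induced_in_window(x$pm, 0, 0.1), 0)
  expect_error(induced_in_window(x$pm, 5, 2), "rt_low")

  # equal presence in both groups is excluded (strict inequality)
  pm2 <- x$pm
  i707 <- which(abs(pm2$clusters$consensus_mass - 707.5335) < 1e-3)
  pm2$presence[i707, ] <- FALSE
  pm2$presence[i707, which(pm2$design$condition == "C")[1]] <- TRUE
  pm2$presence[i707, which(pm2$design$condition == "O2")[1]] <- TRUE
  expect_false(pm2$clusters$cluster_id[i707] %in%
                 induced_in_window(pm2, 0.1, 17.9))
})

test_that("presence/activity concordance is the simple matching coefficient", {
  x <- study_pm()
  # metabolite absent only at O3 week 5 vs DPPH pattern absent there too
  i751 <- which(abs(x$pm$clusters$consensus_mass - 751.3685) < 1e-3)
  exp_cols <- x$pm$design$condition != "C"
  presence <- x$pm$presence[i751, exp_cols]
  dpph <- parse_activity_table(dpph_reference_grid())
  dpph <- dpph[dpph$fraction == "cultural_liquid" & dpph$condition != "C", ]
  activity <- dpph$call[match(
    paste(x$pm$design$condition[exp_cols], x$pm$design$week[exp_cols]),
    paste(dpph$condition, dpph$week))] == "+"
  expect_equal(presence_activity_concordance(presence, activity), 1.0)

  v <- c(TRUE, FALSE, TRUE)
  expect_equal(presence_activity_concordance(v, !v), 0)
  expect_error(presence_activity_concordance(v, v[1:2]), "length")

  set.seed(71)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    a <- runif(n) > 0.5; b <- runif(n) > 0.5
    expect_equal(presence_activity_concordance(a, b), sum(a == b) / n)
  }
})

test_that("detector precision is 1.0 under dropout across seeded simulations", {
  for (seed in 1:50) {
    sim <- gen_feature_tables(sim_config(
      seed = seed, dropout_prob = 0.3,
      n_constitutive = 6, n_experimental_only = 4, n_induced = 4,
      n_control_only = 2))
    fc <- align_features(sim$features, mass_tol_ppm = 10, rt_tol_min = 0.5)
    pm <- suppressWarnings(build_presence_matrix(fc, design = sim$truth$design))
    got <- detect_only_experimental(pm)
    # map detected clusters back to planted features via their members
    detected_feats <- unique(
      fc$members$feature_id[fc$members$cluster_id %in% got])
    cls <- sim$truth$class[match(detected_feats, sim$truth$feature_id)]
    expect_true(all(cls == "experimental_only"),
                info = sprintf("seed %d", seed))
  }
})

test_that("at zero dropout the detector recovers exactly the planted class", {
  for (seed in c(3, 4, 5)) {
    sim <- gen_feature_tables(sim_config(seed = seed, dropout_prob = 0))
    fc <- align_features(sim$features, mass_tol_ppm = 10, rt_tol_min = 0.5)
    pm <- suppressWarnings(build_presence_matrix(fc, design = sim$truth$design))
    got <- detect_only_experimental(pm)
    detected_feats <- unique(
      fc$members$feature_id[fc$members$cluster_id %in% got])
    planted <- sim$truth$feature_id[sim$truth$class == "experimental_only"]
    expect_setequal(detected_feats, planted)
  }
})
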