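test_that("windowed paired contrasts follow the tail conventions and closed form", {
  ctrl <- c(5, 6, 7, 5.5, 6.5)
  oth <- ctrl + c(1, 2, 3, 2, 2)
  r <- windowed_ttest(ctrl, oth, "DD", "mua", layer = "L2/3", window_ms = c(140, 170))
  d <- oth - ctrl
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, pt(t_hand, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$tail, "greater")
  # SSA on MUA is one-tailed "less"
  r2 <- windowed_ttest(ctrl, oth, "SSA", "mua")
  expect_equal(r2$tail, "less")
  expect_equal(r2$p, pt(t_hand, 4), tolerance = 1e-12)
  # CSD is two-tailed; identical values give t = 0, p = 1
  r3 <- windowed_ttest(ctrl, ctrl + c(0, 0, 0, 0, 0), "DD", "csd_avrec")
  expect_equal(r3$tail, "two.sided")
  expect_true(is.na(r3$t) || r3$t == 0 || r3$p == 1)
  r4 <- windowed_ttest(ctrl, ctrl + rnorm(5), "DD", "csd_avrec")
  expect_equal(r4$tail, "two.sided")
  expect_error(windowed_ttest(c(1, 2), c(2, 3), "DD", "mua"), "3 subjects")
  expect_error(windowed_ttest(c(1, 2, NA), c(2, 3, 4), "DD", "mua"), "incomplete")
})

roi_table <- function(effect_l23_dev = 0, n = 10, seed = 1) {
  set.seed(seed)
  tbl <- expand.grid(subject = sprintf("s%02d", seq_len(n)),
                     layer = c("L1", "L2/3", "L4", "L5"),
                     context = c("control", "redundant", "deviant"),
                     stringsAsFactors = FALSE)
  subj_fx <- rnorm(n)
  tbl$value <- rnorm(nrow(tbl), sd = 0.5) + subj_fx[match(tbl$subject,
                                                          unique(tbl$subject))]
  sel <- tbl$layer == "L2/3" & tbl$context == "deviant"
  tbl$value[sel] <- tbl$value[sel] + effect_l23_dev
  tbl
}

test_that("ROI ANOVA is location invariant and finds an injected interaction", {
  tbl <- roi_table(effect_l23_dev = 2, seed = 2)
  r <- roi_anova(tbl)
  expect_lt(r$interaction_p, 0.05)
  expect_false(is.null(r$contrasts))
  hit <- r$contrasts[r$contrasts$layer == "L2/3" & r$contrasts$contrast == "DD", ]
  expect_lt(hit$p, 0.01)
  expect_gt(hit$estimate, 0)
  # adding a constant to every cell leaves all F statistics unchanged
  tbl2 <- tbl; tbl2$value <- tbl2$value + 100
  r2 <- roi_anova(tbl2)
  expect_equal(r2$anova$F, r$anova$F, tolerance = 1e-8)
  # the planned supragranular delta/theta test always runs
  expect_false(is.null(r$planned))
  expect_equal(r$planned$layer, "L2/3")
  expect_equal(r$planned$tail, "greater")
  expect_error(roi_anova(tbl[-1, ]), "incomplete")
})

test_that("null interaction p-values are approximately uniform", {
  ps <- vapply(1:120, function(i) roi_anova(roi_table(0, seed = 100 + i),
                                            planned_layer = NA,
                                            sphericity = "none")$interaction_p,
               numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cluster permutation is deterministic, sign-symmetric and valid", {
  set.seed(21)
  maps <- array(rnorm(10 * 12 * 100), c(10, 12, 100))
  maps[, 4:8, 30:37] <- maps[, 4:8, 30:37] - 1.5
  a <- cluster_permutation(maps, n_perm = 400, seed = 5)
  b <- cluster_permutation(maps, n_perm = 400, seed = 5)
  expect_identical(vapply(a$clusters, `[[`, numeric(1), "p"),
                   vapply(b$clusters, `[[`, numeric(1), "p"))
  # the injected negative block is found and covers most of its bins
  sig <- Filter(function(cl) cl$significant, a$clusters)
  expect_gte(length(sig), 1)
  expect_equal(sig[[1]]$sign, "negative")
  blk <- expand.grid(depth = 4:8, frequency = 30:37)
  cov <- mean(paste(blk$depth, blk$frequency) %in%
                paste(sig[[1]]$members[, 1], sig[[1]]$members[, 2]))
  expect_gte(cov, 0.5)
  # negating the maps mirrors clusters with identical masses and p-values
  n <- cluster_permutation(-maps, n_perm = 400, seed = 5)
  expect_equal(sort(vapply(n$clusters, `[[`, numeric(1), "mass")),
               sort(-vapply(a$clusters, `[[`, numeric(1), "mass")))
  expect_equal(sort(vapply(n$clusters, `[[`, numeric(1), "p")),
               sort(vapply(a$clusters, `[[`, numeric(1), "p")))
  # degenerate inputs
  expect_error(cluster_permutation(maps, n_perm = 50), "n_perm")
  expect_error(cluster_permutation(maps[1:3, , ], n_perm = 400), "5 subjects")
  empty <- cluster_permutation(array(0, c(6, 4, 5)), n_perm = 400)
  expect_length(empty$clusters, 0)
})

test_that("permutation p-values are valid at several alpha levels", {
  set.seed(22)
  hits <- matrix(FALSE, 150, 3)
  alphas <- c(0.01, 0.025, 0.05)
  for (r in 1:150) {
    maps <- array(rnorm(8 * 6 * 30), c(8, 6, 30))
    ct <- cluster_permutation(maps, n_perm = 400, seed = 1000 + r)
    ps <- vapply(ct$clusters, `[[`, numeric(1), "p")
    pmin_ <- if (length(ps)) min(ps) else 1
    hits[r, ] <- pmin_ <= alphas
  }
  for (j in 1:3) {
    ci_hi <- alphas[j] + 3 * sqrt(alphas[j] * (1 - alphas[j]) / 150)
    expect_lte(mean(hits[, j]), ci_hi)
  }
})

test_that("effect recovery cross-references tests against the truth catalogue", {
  truth <- default_ground_truth()
  # build a fake cohort_stats object with exactly the expected signatures
  wt <- expand.grid(layer = c("L1", "L2/3", "L4", "L5"), t_lo = seq(50, 230, 30),
                    contrast = c("SSA", "DD"), stringsAsFactors = FALSE)
  wt$domain <- "mua"; wt$t_hi <- wt$t_lo + 30
  wt$estimate <- 0.01; wt$t <- 0.1; wt$df <- 9; wt$p <- 0.9
  wt$kept_pos <- c("L1" = 1, "L2/3" = 4, "L4" = 8, "L5" = 11)[wt$layer]
  sel_ssa <- wt$layer == "L4" & wt$t_lo == 50 & wt$contrast == "SSA"
  wt$estimate[sel_ssa] <- -1; wt$t[sel_ssa] <- -3; wt$p[sel_ssa] <- 0.01
  sel_dd <- wt$layer == "L2/3" & wt$t_lo == 170 & wt$contrast == "DD"
  wt$estimate[sel_dd] <- 1; wt$t[sel_dd] <- 4; wt$p[sel_dd] <- 0.004
  planned <- data.frame(layer = "L2/3", contrast = "DD", estimate = 1, t = 3,
                        df = 9, p = 0.01, tail = "greater")
  post <- data.frame(layer = rep(c("L1", "L2/3", "L4", "L5"), each = 2),
                     contrast = rep(c("DD", "SSA"), 4),
                     estimate = c(-1, 0, 1, 0, 0, 0, 0, 0),
                     t = c(-3, 0, 3, 0, 0, 0, 0, 0), df = 9,
                     p = c(0.01, 0.9, 0.01, 0.9, 0.9, 0.9, 0.9, 0.9))
  roi_tests <- list(
    early_delta_theta = list(interaction_p = 0.5, contrasts = NULL, planned = planned),
    mid_high_gamma = list(interaction_p = 0.01, contrasts = post, planned = NULL),
    early_high_beta = list(interaction_p = 0.01, contrasts = post, planned = NULL))
  cl <- list(list(members = cbind(depth = c(6, 7), frequency = c(36, 36)),
                  mass = -50, sign = "negative", p = 0.004, significant = TRUE))
  st <- structure(list(windowed = wt, roi_tests = roi_tests,
                       ies_cluster = list(clusters = cl),
                       freqs = seq(2, 101, length.out = 100),
                       rois = default_rois()), class = "cohort_stats")
  rec <- run_effect_recovery(st, truth)
  expect_true(all(rec$detected))
  # zero-signal stats detect nothing
  wt0 <- wt; wt0$p <- 0.9; wt0$t <- 0; wt0$estimate <- 0
  st0 <- st; st0$windowed <- wt0
  st0$roi_tests <- lapply(roi_tests, function(r) {
    r$interaction_p <- 0.8; r$contrasts <- NULL
    if (!is.null(r$planned)) r$planned$p <- 0.7
    r
  })
  st0$ies_cluster <- list(clusters = list())
  expect_false(any(run_effect_recovery(st0, truth)$detected))
})
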