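test_that("two-way ANOVA reproduces the hand-computed decomposition", {
  d <- data.frame(A = rep(c("a1", "a2"), each = 4),
                  B = rep(c("b1", "b1", "b2", "b2"), 2),
                  y = c(1, 3, 5, 7, 2, 4, 10, 12))
  a <- anova_two_way(d, "y", "A", "B")
  tab <- a$table
  expect_equal(tab$sum_sq[tab$term == "A"], 18)
  expect_equal(tab$sum_sq[tab$term == "B"], 72)
  expect_equal(tab$sum_sq[tab$term == "A:B"], 8)
  expect_equal(tab$sum_sq[tab$term == "Residuals"], 8)
  expect_equal(tab$F[tab$term == "A"], 9)
  expect_equal(tab$F[tab$term == "B"], 36)
  expect_equal(tab$F[tab$term == "A:B"], 4)
  # balanced decomposition: term SS sum to the total SS
  expect_equal(sum(tab$sum_sq), sum((d$y - mean(d$y))^2))

  dc <- d; dc$y <- 5
  ac <- anova_two_way(dc, "y", "A", "B")
  expect_true(all(ac$table$sum_sq < 1e-20))
  expect_true(all(ac$table$p[ac$table$term != "Residuals"] == 1))

  d_empty <- d[-(1:2), ]   # a1:b1 cell empty
  expect_error(anova_two_way(d_empty, "y", "A", "B"), "empty cells")
})

test_that("interaction test is calibrated on additive data", {
  set.seed(47)
  pvals <- replicate(60, {
    d <- expand.grid(A = paste0("a", 1:4), B = paste0("b", 1:3),
                     r = 1:3)
    d$y <- as.numeric(d$A) + 0.5 * as.numeric(d$B) + rnorm(nrow(d))
    a <- anova_two_way(d, "y", "A", "B")
    a$table$p[a$table$term == "A:B"]
  })
  expect_lt(mean(pvals < 0.05), 0.18)   # ~ alpha with Monte-Carlo slack
  expect_gt(median(pvals), 0.2)         # not concentrated near zero
})

test_that("blocked ANOVA removes block variation before testing", {
  set.seed(53)
  d <- expand.grid(depth = paste0("d", 1:4), block = paste0("t", 1:3),
                   r = 1:3)
  shift <- c(t1 = 0, t2 = 5, t3 = -4)
  d$y <- shift[d$block] + rnorm(nrow(d))
  b <- anova_blocked(d, "y", factor = "depth", block = "block")
  tab <- b$table
  expect_gt(tab$sum_sq[tab$term == "block"],
            10 * tab$sum_sq[tab$term == "depth"] / 3)
  expect_gt(tab$p[tab$term == "depth"], 0.01)

  # pure factor effect: same F as the additive two-way
  d$y2 <- as.numeric(d$depth) * 2 + rnorm(nrow(d))
  b2 <- anova_blocked(d, "y2", factor = "depth", block = "block")
  a2 <- anova_two_way(d, "y2", "block", "depth", interaction = FALSE)
  expect_equal(b2$table$F[b2$table$term == "depth"],
               a2$table$F[a2$table$term == "depth"])

  # single block reduces to one-way
  d1 <- d[d$block == "t1", ]
  b1 <- anova_blocked(d1, "y2", factor = "depth", block = "block")
  expect_equal(nrow(b1$table), 2)

  d_gap <- d[!(d$depth == "d1" & d$block == "t1"), ]
  expect_error(anova_blocked(d_gap, "y", "depth", "block"), "missing cell")
})

test_that("Tukey letters separate exactly the significant pairs", {
  set.seed(59)
  d <- data.frame(g = rep(c("g1", "g2"), each = 6),
                  y = rnorm(12, 10, 0.5))
  a <- aov(y ~ g, d)
  cl <- tukey_cld(a, "g")
  expect_equal(cl$letters$letters, c("a", "a"))

  d3 <- data.frame(g = rep(c("g1", "g2", "g3"), each = 5),
                   y = c(rnorm(5, 0, 0.1), rnorm(5, 0, 0.1),
                         rnorm(5, 10, 0.1)))
  cl3 <- tukey_cld(aov(y ~ g, d3), "g")
  lt <- setNames(cl3$letters$letters, cl3$letters$level)
  expect_equal(unname(lt["g1"]), unname(lt["g2"]))
  expect_false(lt["g3"] == lt["g1"])
  # highest mean letters first
  expect_equal(cl3$letters$level[1], "g3")
  expect_equal(cl3$letters$letters[1], "a")

  # Tukey-adjusted p never below the unadjusted pairwise t-test p
  p_t <- t.test(d3$y[d3$g == "g1"], d3$y[d3$g == "g2"],
                var.equal = TRUE)$p.value
  expect_gte(cl3$p_matrix["g1", "g2"] + 1e-12, p_t)
})

test_that("letter assignments are valid over random mean vectors", {
  set.seed(61)
  for (i in 1:25) {
    g <- sample(3:6, 1)
    mu <- rnorm(g, 0, sample(c(0.5, 2), 1))
    d <- data.frame(g = rep(paste0("g", 1:g), each = 5),
                    y = rnorm(5 * g, rep(mu, each = 5), 1))
    cl <- tukey_cld(aov(y ~ g, d), "g")
    ord <- match(cl$letters$level, rownames(cl$p_matrix))
    expect_true(cld_is_valid(cl$letters$letters,
                             cl$p_matrix[ord, ord, drop = FALSE]))
  }
})

test_that("assumption diagnostics report Levene, Shapiro and skewness", {
  set.seed(67)
  res <- rnorm(100)
  grp <- rep(letters[1:4], each = 25)
  ck <- assumption_checks(res, grp)
  expect_true(ck$shapiro$p > 0.001)
  expect_true(is.finite(ck$levene$p))
  expect_lt(abs(ck$skewness), 0.6)
  # symmetric residuals: skewness near zero on average
  sk <- replicate(50, e1071::skewness(rnorm(200)))
  expect_lt(abs(mean(sk)), 0.1)
  # normal residuals pass Shapiro in at least 90% of seeds
  sh <- replicate(100, shapiro.test(rnorm(100))$p.value)
  expect_gte(mean(sh > 0.05), 0.9)
  expect_message(assumption_checks(c(1, 2), c("a", "b")), "skipped")
})

test_that("percent decline is computed per temperature then averaged", {
  d <- expand.grid(depth_cm = c("0-10", "10-20", "60-70", "80-90"),
                   temperature_C = c(4, 25))
  d$v <- c(100, 90, 5, 3.6, 100, 90, 5, 3.6)
  pd <- percent_decline(d, "v")
  expect_equal(pd$per_temperature$percent_decline, c(96.4, 96.4))
  expect_equal(pd$mean, 96.4)
  expect_equal(pd$se, 0)
  # equal upper and lower values -> 0%
  d0 <- d; d0$v <- 50
  expect_equal(percent_decline(d0, "v")$mean, 0)
  # scale invariance
  d2 <- d; d2$v <- d$v * 17
  expect_equal(percent_decline(d2, "v")$mean, pd$mean)
  # configured cell exclusion removes a spurious cell from the average
  dbad <- d; dbad$v[dbad$depth_cm == "0-10" & dbad$temperature_C == 4] <- 1e6
  pd_ex <- percent_decline(dbad, "v",
                           exclude_cells = data.frame(depth_cm = "0-10",
                                                      temperature_C = 4))
  expect_equal(pd_ex$per_temperature$percent_decline[1],
               100 * (90 - 3.6) / 90)
})

test_that("enzyme trait ratios are element-wise and reciprocal", {
  tr <- expand.grid(enzyme = c("BG", "LAP", "AP"), depth_cm = "0-10",
                    core = 1, temperature_C = c(4, 25),
                    stringsAsFactors = FALSE)
  tr$vmax_ds <- c(10, 4, 20, 10, 4, 20)
  tr$km <- c(50, 100, 50, 50, 100, 50)
  tr$ce_ds <- tr$vmax_ds / tr$km
  rt <- enzyme_ratios(tr)
  bl <- rt[rt$pair == "BG:LAP", ]
  expect_equal(bl$vmax_ratio, c(2.5, 2.5))
  expect_equal(bl$km_ratio, c(0.5, 0.5))
  # identical traits give unit ratios
  tr2 <- tr; tr2$vmax_ds <- 5; tr2$km <- 50; tr2$ce_ds <- 0.1
  expect_true(all(unlist(enzyme_ratios(tr2)[, 5:7]) == 1))
  # ratio(X:Y) * ratio(Y:X) = 1 on random tables
  set.seed(71)
  tr3 <- tr
  tr3$vmax_ds <- runif(6, 1, 100)
  tr3$km <- runif(6, 10, 300)
  tr3$ce_ds <- tr3$vmax_ds / tr3$km
  rt3 <- enzyme_ratios(tr3)
  swap <- tr3
  swap$enzyme <- c("LAP", "BG", "AP", "LAP", "BG", "AP")[match(
    tr3$enzyme, c("BG", "LAP", "AP"))]
  rt3s <- enzyme_ratios(swap)
  m <- merge(rt3[rt3$pair == "BG:LAP", ], rt3s[rt3s$pair == "BG:LAP", ],
             by = c("depth_cm", "core", "temperature_C"))
  expect_equal(m$vmax_ratio.x * m$vmax_ratio.y, rep(1, nrow(m)))
})
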