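make_table <- function(lines, wells, gen, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(lines, function(ln) {
    data.frame(line_id = ln, well_id = paste0(ln, seq_len(wells)),
               gen(wells), stringsAsFactors = FALSE)
  }))
}

test_that("parameter CV matches hand computation and recovers generated CV", {
  tab <- data.frame(line_id = "L1", MFR = c(1, 2, 3), NBR = c(2, 2, 2))
  cv <- parameter_cv(tab, params = c("MFR", "NBR"))
  expect_equal(cv$mean_cv[cv$parameter == "MFR"], 50)   # 100 * sd/mean = 50
  expect_equal(cv$mean_cv[cv$parameter == "NBR"], 0)
  expect_true(cv$stable[cv$parameter == "NBR"])

  # generated CV of 20% per line, 30 wells x 5 lines
  tab2 <- make_table(paste0("L", 1:5), 30, function(n) {
    data.frame(MFR = rnorm(n, 10, 2))
  }, seed = 42)
  cv2 <- parameter_cv(tab2, params = "MFR")
  expect_equal(cv2$mean_cv, 20, tolerance = 3 / 20)
})

test_that("PCA: correlated columns collapse to PC1, isotropic data split evenly", {
  x <- rnorm(40)
  tab <- data.frame(a = x, b = 2 * x + 3)
  pc <- pca_embed(tab, c("a", "b"))
  expect_equal(pc$variance_explained[1], 100, tolerance = 1e-8)

  set.seed(8)
  tab2 <- data.frame(a = rnorm(1000), b = rnorm(1000))
  pc2 <- pca_embed(tab2, c("a", "b"))
  expect_equal(pc2$variance_explained[1], 50, tolerance = 5 / 50)
  expect_equal(sum(pc2$variance_explained), 100)

  # reconstruction from all components is lossless
  z <- scale(as.matrix(tab2))
  recon <- pc2$scores %*% t(pc2$loadings)
  expect_lt(max(abs(recon - z)), 1e-8)

  # fixed sign convention: largest-magnitude loading is positive
  expect_true(all(apply(pc2$loadings, 2, function(l) l[which.max(abs(l))]) > 0))

  expect_error(pca_embed(tab[1, , drop = FALSE]), "at least 2")
})

test_that("variance explained by batch matches the analytic ratio", {
  set.seed(12)
  n <- 4000
  batch <- rep(c("A", "B"), each = n / 2)
  y <- rnorm(n, ifelse(batch == "A", 0, 2), 1)   # gap 2, within-SD 1
  tab <- data.frame(mea_batch = batch, MFR = y)
  v <- variance_explained_by_batch(tab, "mea_batch", params = "MFR")
  expect_equal(v$per_parameter$r_squared, 0.5, tolerance = 0.05)
  expect_equal(v$combined_pct, 50, tolerance = 5)

  # randomly shuffled factor: combined share near (levels-1)/(n-1)
  tab$mea_batch <- sample(tab$mea_batch)
  v0 <- variance_explained_by_batch(tab, "mea_batch", params = "MFR")
  expect_lt(v0$combined_pct, 1)

  tab$mea_batch <- "A"
  expect_warning(v1 <- variance_explained_by_batch(tab, "mea_batch",
                                                   params = "MFR"),
                 "single level")
  expect_equal(v1$per_parameter$r_squared, 0)
  expect_equal(v1$combined_pct, 0)
})

test_that("group comparisons: nulls are null and shifted groups are detected", {
  # identical groups: adjusted p stays near 1
  tab <- data.frame(line_id = rep(c("A", "B"), each = 10),
                    MFR = rep(1:10, 2), NBR = rep(seq(2, 4, length.out = 10), 2))
  res <- group_compare(tab, "line_id", params = c("MFR", "NBR"))
  expect_true(all(res$p_adj >= 0.9))
  expect_false(any(res$significant))

  # 2-SD mean shift, n = 12 per group, Bonferroni across the 17-parameter
  # family.  Oracle: Mann-Whitney power by the ARE-0.955 normal
  # approximation (effective d = 2*sqrt(0.955), alpha = 0.05/17) is ~0.89;
  # assert within 3 Monte-Carlo SDs below that.
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    t2 <- data.frame(line_id = rep(c("A", "B"), each = 12),
                     MFR = c(rnorm(12, 0, 1), rnorm(12, 2, 1)))
    r <- group_compare(t2, "line_id", params = "MFR",
                       correction = "none")
    r$p[1] < 0.05 / 17
  }, logical(1))
  expect_gte(mean(hits), 0.89 - 3 * sqrt(0.89 * 0.11 / 200))

  # multi-group path: Kruskal-Wallis/ANOVA with post hoc tables
  set.seed(77)
  t3 <- data.frame(line_id = rep(c("A", "B", "C"), each = 15),
                   MFR = c(rnorm(15, 0), rnorm(15, 0), rnorm(15, 3)))
  r3 <- group_compare(t3, "line_id", params = "MFR", posthoc = TRUE)
  expect_true(r3$significant[1])
  ph <- attr(r3, "posthoc")$MFR
  expect_true(!is.null(ph))
  expect_equal(nrow(ph), 3)   # three pairwise comparisons
})

test_that("Bonferroni over the parameter family matches the definition", {
  set.seed(3)
  tab <- data.frame(line_id = rep(c("A", "B"), each = 12))
  for (p in mea_parameters()) tab[[p]] <- rnorm(24)
  res <- group_compare(tab, "line_id")
  expect_equal(nrow(res), 17)
  ok <- !is.na(res$p)
  expect_equal(res$p_adj[ok], pmin(1, res$p[ok] * 17))
})

test_that("Holm-Sidak adjustment is the monotone step-down Sidak", {
  p <- c(0.001, 0.01, 0.04, 0.2)
  adj <- holm_sidak(p)
  manual <- cummax(1 - (1 - p)^(4:1))
  expect_equal(adj, manual)
  expect_true(all(adj >= p - 1e-12))
})

test_that("burst-shape comparison finds late-phase differences only", {
  set.seed(19)
  t_grid <- seq(0.01, 2, by = 0.02)
  mk <- function(n, theta) {
    m <- t(vapply(seq_len(n), function(i) {
      100 * dgamma(t_grid, 2, scale = theta) * runif(1, 0.9, 1.1) +
        abs(rnorm(length(t_grid), 0, 0.4))
    }, numeric(length(t_grid))))
    attr(m, "t") <- t_grid
    m
  }
  a <- mk(15, 0.15)
  res0 <- burst_shape_compare(a, mk(15, 0.15))
  expect_lt(sum(res0$significant), 3)   # null: essentially nothing

  b <- mk(15, 0.35)                      # slower decay
  res <- burst_shape_compare(mk(15, 0.15), b)
  late <- res$t_s > 0.8
  expect_gt(sum(res$significant[late]), 5)

  bad <- mk(15, 0.35)[, 1:50]
  attr(bad, "t") <- t_grid[1:50]
  expect_error(burst_shape_compare(a, bad), "bin grids")
})

test_that("identical shape sets yield no significant bins", {
  m <- matrix(rep(1:10, each = 6), nrow = 6)
  attr(m, "t") <- (1:10 - 0.5) * 0.1
  res <- burst_shape_compare(m, m)
  expect_false(any(res$significant))
})

test_that("wells_required matches the noncentral-t oracle", {
  n <- wells_required(1.21)
  expect_equal(n, 12)
  expect_equal(n, ceiling(power.t.test(delta = 1.21, sd = 1,
                                       sig.level = 0.05, power = 0.8)$n))
  expect_equal(wells_required(50), 2)

  # monotone in effect size and in target power
  ns <- vapply(c(0.5, 0.8, 1.2, 2), wells_required, numeric(1))
  expect_true(all(diff(ns) <= 0))
  np <- vapply(c(0.5, 0.8, 0.9, 0.99), function(pw) {
    wells_required(1, power = pw)
  }, numeric(1))
  expect_true(all(diff(np) >= 0))
})

test_that("post hoc power of a null comparison is near alpha", {
  tab <- data.frame(line_id = rep(c("A", "B"), each = 12),
                    MFR = rep(seq(1, 2, length.out = 12), 2))
  ph <- post_hoc_power(tab, "line_id", "MFR")
  expect_equal(ph$d, 0)
  expect_equal(ph$power, 0.05, tolerance = 1e-6)

  set.seed(41)
  tab2 <- data.frame(line_id = rep(c("A", "B"), each = 12),
                     MFR = c(rnorm(12, 0), rnorm(12, 3)))
  expect_gt(post_hoc_power(tab2, "line_id", "MFR")$power, 0.95)
})
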