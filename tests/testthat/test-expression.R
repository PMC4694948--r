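make_mat <- function(group_means, n_rep = 3, noise = 0, seed = 1) {
  set.seed(seed)
  g <- length(group_means[[1]])
  mat <- do.call(cbind, lapply(group_means, function(mu) {
    matrix(rep(mu, n_rep), ncol = n_rep) + rnorm(g * n_rep, 0, noise)
  }))
  rownames(mat) <- paste0("g", seq_len(g))
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  groups <- factor(rep(names(group_means), each = n_rep),
                   levels = names(group_means))
  list(mat = mat, groups = groups)
}

test_that("the ANOVA screen matches aov() and handles constants", {
  d <- make_mat(list(A = c(5, 1, 7), B = c(5, 3, 7), C = c(5, 2, 7)),
                n_rep = 2, noise = 0.4, seed = 2)
  got <- anova_screen(d$mat, d$groups)
  for (i in 1:3) {
    fit <- summary(aov(d$mat[i, ] ~ d$groups))[[1]]
    expect_equal(got$f[i], fit[["F value"]][1], tolerance = 1e-9)
    expect_equal(got$p[i], fit[["Pr(>F)"]][1], tolerance = 1e-9)
  }

  const <- make_mat(list(A = c(4, 4), B = c(4, 4)), n_rep = 2, noise = 0)
  res <- anova_screen(const$mat, const$groups)
  expect_equal(res$f, c(0, 0))
  expect_equal(res$p, c(1, 1))

  expect_error(anova_screen(d$mat[, 1:3], factor(c("A", "A", "B"))),
               ">= 2 replicates")
})

test_that("the ANOVA screen is calibrated under the null", {
  set.seed(123)
  mat <- matrix(rnorm(2000 * 6), 2000)
  rownames(mat) <- paste0("g", 1:2000)
  groups <- factor(rep(c("A", "B", "C"), each = 2))
  res <- anova_screen(mat, groups)
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("cell-type-selective calls require the fold over every other group", {
  d <- make_mat(list(A = c(10, 10), B = c(8, 9.5), C = c(8, 8)),
                n_rep = 3, noise = 0.05, seed = 3)
  res <- celltype_selective(d$mat, d$groups, fold = 2, alpha = 0.05)
  expect_true("g1" %in% res$sets$A)   # 4-fold over both others
  expect_false("g2" %in% res$sets$A)  # only 1.41-fold over B
  # Selective sets are pairwise disjoint by construction.
  expect_length(intersect(res$sets$A, res$sets$B), 0)
  expect_length(intersect(res$sets$A, res$sets$C), 0)
  expect_error(celltype_selective(d$mat[, 1:6], d$groups[1:6]), "3 groups")
})

test_that("selective-gene recovery on planted truth is accurate", {
  cfg <- sim_config(n_genes = 600, de_fold = 4, expr_noise_sd = 0.2,
                    selective_per_group = 50, seed = 505)
  sim <- simulate_methylome(cfg, generate_layout(cfg))
  ex <- simulate_expression(cfg, sim$truth)
  cts <- c("qHSC", "LSEC", "HEP")
  cols <- ex$groups$sample[ex$groups$group %in% cts]
  res <- celltype_selective(ex$matrix[, cols],
                            factor(ex$groups$group[match(cols, ex$groups$sample)],
                                   levels = cts))
  truth <- sim$truth
  for (ct in cts) {
    planted <- truth$gene[!is.na(truth$selective_group) &
                            truth$selective_group == ct]
    called <- res$sets[[ct]]
    expect_gte(length(intersect(called, planted)) / length(planted), 0.9)
    fdr <- if (length(called)) mean(!called %in% planted) else 0
    expect_lte(fdr, 0.1)
  }
})

test_that("differential expression matches t.test and classifies by fold and p", {
  d <- make_mat(list(q = c(8, 8, 8), a = c(10, 8, 7.2)),
                n_rep = 3, noise = 0.1, seed = 4)
  res <- differential_expression(d$mat, d$groups)
  for (i in 1:3) {
    tt <- t.test(d$mat[i, d$groups == "a"], d$mat[i, d$groups == "q"],
                 var.equal = TRUE)
    expect_equal(res$records$p_value[i], tt$p.value, tolerance = 1e-9)
    expect_equal(res$records$t[i], unname(tt$statistic), tolerance = 1e-9)
  }
  expect_equal(res$records$class[1], "up")        # planted 4-fold up
  expect_equal(res$records$class[2], "unchanged")
  expect_equal(res$records$class[3], "unchanged") # 1.74-fold: below cutoff

  ident <- make_mat(list(q = c(5, 6), a = c(5, 6)), n_rep = 3, noise = 0)
  resi <- differential_expression(ident$mat, ident$groups)
  expect_true(all(resi$records$class == "unchanged"))
  expect_true(all(resi$records$p_value == 1))
})

test_that("DE and selective sets shrink as thresholds tighten", {
  set.seed(6)
  d <- make_mat(list(q = rnorm(200, 8), a = rnorm(200, 8, 1.2)),
                n_rep = 3, noise = 0.3, seed = 6)
  sizes <- vapply(c(1.5, 2, 3, 4), function(f) {
    r <- differential_expression(d$mat, d$groups, fold = f)
    length(r$up) + length(r$down)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  alphas <- vapply(c(0.1, 0.05, 0.01), function(a) {
    r <- differential_expression(d$mat, d$groups, alpha = a)
    length(r$up) + length(r$down)
  }, numeric(1))
  expect_true(all(diff(alphas) <= 0))
})

test_that("the DE t-test is calibrated on simulated null expression", {
  cfg <- sim_config(n_genes = 2000, de_fold = 1, seed = 99)
  sim <- simulate_methylome(cfg, generate_layout(cfg))
  ex <- simulate_expression(cfg, sim$truth)
  cols <- ex$groups$sample[ex$groups$group %in% c("qHSC", "aHSC")]
  res <- differential_expression(
    ex$matrix[, cols],
    factor(ex$groups$group[match(cols, ex$groups$sample)],
           levels = c("qHSC", "aHSC")))
  rate <- mean(res$records$p_value <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000) + 0.005)
})

test_that("list overlap percentages follow the mapped intersection", {
  expect_equal(list_overlap(c("a", "b"), c("a", "b"))$pct_of_a, 100)
  expect_equal(list_overlap(c("a", "b"), c("c", "d"))$pct_of_a, 0)

  map <- data.frame(from = paste0("m", 1:10), to = paste0("h", 1:10))
  a <- paste0("m", 1:10)
  b <- c(paste0("h", 1:4), paste0("x", 1:16))
  ov <- list_overlap(a, b, map)
  expect_equal(ov$n_overlap, 4)
  expect_equal(ov$pct_of_a, 40)
  expect_equal(ov$pct_of_b, 20)

  bad <- data.frame(from = c("m1", "m1"), to = c("h1", "h2"))
  expect_error(list_overlap(a, b, bad), "many-to-many")

  partial <- data.frame(from = paste0("m", 1:5), to = paste0("h", 1:5))
  expect_equal(list_overlap(a, b, partial)$n_unmapped_a, 5)
})
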