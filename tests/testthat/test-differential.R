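test_that("detection gate applies min.pct in either group and combined cells", {
  # gene1: 15% of group a (6/40), 0% of b -> passes both conditions
  # gene2: 9% in each group -> fails min.pct everywhere
  # gene3: 50% of a 6-cell group a (3 cells), 0 elsewhere -> fails combined 5
  cells_a <- sprintf("a%02d", 1:40)
  cells_b <- sprintf("b%02d", 1:40)
  m <- matrix(0, 3, 80, dimnames = list(c("g1", "g2", "g3"),
                                        c(cells_a, cells_b)))
  m["g1", cells_a[1:6]] <- 1
  m["g2", cells_a[1:3]] <- 1
  m["g2", cells_b[1:3]] <- 1  # 3/40 = 7.5% < 10%
  norm <- Matrix::Matrix(m, sparse = TRUE)
  expect_identical(test_gate(norm, cells_a, cells_b), "g1")

  m3 <- matrix(0, 1, 12, dimnames = list("g3", c(sprintf("a%d", 1:6),
                                                 sprintf("b%d", 1:6))))
  m3["g3", 1:3] <- 1
  norm3 <- Matrix::Matrix(m3, sparse = TRUE)
  expect_length(test_gate(norm3, sprintf("a%d", 1:6), sprintf("b%d", 1:6),
                          min_pct = 0.1, min_cells_feature = 5), 0)
  expect_error(test_gate(norm3, character(0), sprintf("b%d", 1:6)),
               "group_a")
})

test_that("avg_log2FC matches its closed form and is antisymmetric", {
  # group a cells all at expm1 = 3, group b at expm1 = 1 -> log2(4/2) = 1
  norm <- make_norm(cbind(matrix(log1p(3), 2, 4), matrix(log1p(1), 2, 4)))
  a <- colnames(norm)[1:4]
  b <- colnames(norm)[5:8]
  fc <- fold_change(norm, a, b)
  expect_equal(unname(fc), c(1, 1))
  expect_equal(unname(fold_change(norm, b, a)), -unname(fc))
  expect_equal(unname(fold_change(norm, a, a)), c(0, 0))

  # meanlog dialect: difference of mean logs over log(2)
  expect_equal(unname(fold_change(norm, a, b, method = "meanlog")),
               rep((log1p(3) - log1p(1)) / log(2), 2))
})

test_that("rank-sum p-values match enumeration, degenerate and tie cases", {
  expect_equal(wilcoxon_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_test(c(5, 5, 5), c(5, 5)), 1)
  # extreme separation at n = m = 3: exact two-sided p is 2/20
  expect_equal(wilcoxon_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_test(c(1, 2, 3), c(4, 5, 6)),
               enumerate_ranksum_p(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)

  # tie-heavy vectors: approximation agrees with a permutation oracle
  set.seed(91)
  for (i in 1:3) {
    a <- sample(1:4, 20, replace = TRUE)
    b <- sample(2:5, 20, replace = TRUE)
    obs <- wilcoxon_test(a, b, exact_limit = 10)
    pooled <- c(a, b)
    r <- rank(pooled)
    u_obs <- sum(r[1:20]) - 20 * 21 / 2
    u_perm <- replicate(1e4, {
      idx <- sample(40, 20)
      sum(r[idx]) - 20 * 21 / 2
    })
    p_perm <- mean(abs(u_perm - 200) >= abs(u_obs - 200))
    expect_lt(abs(obs - p_perm), 0.025)
  }
})

test_that("BH adjustment follows the step-up rule and is order-preserving", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  # monotone in the ranks of the raw p-values
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("DEG flags require both the effect-size and significance gates", {
  # constant-valued groups: avg_log2FC = log2(2.3/2) = 0.202, p tiny
  norm <- make_norm(rbind(c(rep(log1p(1.3), 60), rep(log1p(1.0), 60)),
                          c(rep(log1p(4.0), 60), rep(log1p(1.0), 60))))
  ann <- toy_ann(colnames(norm), rep(c("Iso-P8", "Iso-R1"), each = 60))
  degs <- find_degs(norm, ann, sea_contrast(cell_type = "Hep"))
  g1 <- degs[degs$gene == "g01", ]
  expect_equal(g1$avg_log2FC, log2(2.3 / 2))
  expect_lt(g1$p_adj, 0.05)
  expect_false(g1$is_deg)
  expect_identical(g1$direction, "none")
  g2 <- degs[degs$gene == "g02", ]
  expect_true(g2$is_deg)
  expect_identical(g2$direction, "up")
})

test_that("reversing a contrast negates fold changes and keeps p-values", {
  sim <- simulate_parabiosis(sim_config(n_genes = 120, cell_types = c(Hep = 40),
                                        n_planted_up = 10, n_planted_down = 10,
                                        seed = 2))
  norm <- normalize_counts(sim$counts)
  fwd <- find_degs(norm, sim$annotation, sea_contrast(cell_type = "Hep"))
  rev <- find_degs(norm, sim$annotation,
                   contrast_spec("Iso-R1", "Iso-P8", cell_type = "Hep"))
  merged <- dplyr::inner_join(tidy(fwd), tidy(rev), by = "gene")
  expect_equal(nrow(merged), nrow(fwd))
  expect_equal(merged$avg_log2FC.x, -merged$avg_log2FC.y)
  expect_equal(merged$p_value.x, merged$p_value.y)
})

test_that("planted strong effects are recovered and permuted labels are null", {
  sens_strong <- sens_all <- numeric(0)
  for (s in 1:3) {
    sim <- simulate_parabiosis(sim_config(cell_types = c(Hep = 200), seed = s))
    norm <- normalize_counts(qc_filter(sim$counts)$counts)
    degs <- find_degs(norm, sim$annotation, sea_contrast(cell_type = "Hep"))
    planted <- sim$truth[sim$truth$planted, ]
    found <- degs$direction[match(planted$gene, degs$gene)]
    ok <- !is.na(found) & found == planted$direction
    sens_all <- c(sens_all, mean(ok))
    sens_strong <- c(sens_strong, mean(ok[abs(planted$true_lfc) >= 1]))
  }
  expect_gte(mean(sens_strong), 0.9)
  expect_gte(mean(sens_all), 0.8)

  # random relabelling: essentially nothing is flagged
  sim <- simulate_parabiosis(sim_config(n_genes = 500, cell_types = c(Hep = 100),
                                        seed = 7))
  norm <- normalize_counts(qc_filter(sim$counts, toy_qc())$counts)
  ann <- sim$annotation
  set.seed(21)
  ann$group <- sample(ann$group)
  degs <- find_degs(norm, ann, sea_contrast(cell_type = "Hep"))
  expect_lte(mean(degs$is_deg), 0.05)
})
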