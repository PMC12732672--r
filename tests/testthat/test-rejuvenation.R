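test_that("reversed and rescued classification follows the published gates", {
  sea <- fake_degs(paste0("g", 1:6),
                   lfc = c(0.5, 0.5, 0.5, 0.5, 0.5, -0.6),
                   p_adj = rep(0.001, 6))
  rej <- fake_degs(paste0("g", 1:5),
                   lfc = c(-0.15, -0.30, 0.20, -0.15, -0.05),
                   p_adj = c(0.001, 0.001, 0.001, 0.2, 0.001))
  st <- classify_reversal(sea, rej)
  get <- function(g) as.character(st$status[st$gene == g])
  expect_identical(get("g1"), "reversed")       # opposite, |0.15| > 0.1, sig
  expect_identical(get("g2"), "rescued")        # opposite, |0.30| > 0.25, sig
  expect_identical(get("g3"), "not_reversed")   # same direction
  expect_identical(get("g4"), "not_reversed")   # not significant in REJ
  expect_identical(get("g5"), "not_reversed")   # below the 0.1 gate
  expect_identical(get("g6"), "not_reversed")   # absent from REJ tested set
  expect_true(is.na(st$rej_lfc[st$gene == "g6"]))

  # dropping the REJ significance requirement promotes g4 only
  st2 <- classify_reversal(sea, rej, require_rej_significance = FALSE)
  expect_identical(as.character(st2$status[st2$gene == "g4"]), "reversed")
  expect_identical(as.character(st2$status[st2$gene == "g5"]), "not_reversed")
})

test_that("rescued genes are always a subset of reversed genes", {
  set.seed(33)
  for (i in 1:20) {
    genes <- paste0("g", 1:40)
    sea <- fake_degs(genes, lfc = runif(40, -1, 1), p_adj = runif(40, 0, 0.1))
    rej <- fake_degs(sample(genes, 30), lfc = runif(30, -1, 1),
                     p_adj = runif(30, 0, 0.1))
    st <- classify_reversal(sea, rej)
    rescued <- st$gene[st$status == "rescued"]
    relaxed <- classify_reversal(sea, rej, reverse_lfc = 0.1)
    expect_true(all(rescued %in%
                      relaxed$gene[relaxed$status %in% c("reversed", "rescued")]))
    # monotone in the reversed threshold
    strict <- classify_reversal(sea, rej, reverse_lfc = 0.2, rescue_lfc = 0.3)
    n_rev <- function(x) sum(x$status %in% c("reversed", "rescued"))
    expect_lte(n_rev(strict), n_rev(relaxed))
  }
})

test_that("classification rejects tables from different scopes", {
  sim <- simulate_parabiosis(sim_config(n_genes = 60,
                                        cell_types = c(A = 10, B = 10),
                                        n_planted_up = 5, n_planted_down = 5,
                                        seed = 9))
  norm <- normalize_counts(sim$counts)
  sea_a <- find_degs(norm, sim$annotation, sea_contrast(cell_type = "A"),
                     min_cells_feature = 1)
  rej_b <- find_degs(norm, sim$annotation, rej_contrast(cell_type = "B"),
                     min_cells_feature = 1)
  expect_error(classify_reversal(sea_a, rej_b), "different")
})

test_that("reversal ratios report exact fractions and half-up display", {
  st <- fake_degs(paste0("g", 1:10), lfc = rep(0.5, 10), p_adj = rep(0.01, 10))
  status <- classify_reversal(
    st,
    fake_degs(paste0("g", 1:10), lfc = c(rep(-0.5, 3), rep(0.5, 7)),
              p_adj = rep(0.01, 10))
  )
  rr <- reversal_ratio(status, scope = "toy")
  expect_equal(rr$n_up, 10)
  expect_equal(rr$n_up_reversed, 3)
  expect_equal(rr$pct_up_reversed_exact, 30)
  expect_true(is.na(rr$pct_down_reversed))  # no down-DEGs: undefined, not 0

  expect_equal(pct_display(203, 424), 48)
  expect_equal(pct_display(357, 1515), 24)
  expect_equal(pct_display(5, 8), 63)   # 62.5 rounds up
  expect_equal(pct_display(0, 7), 0)
  expect_true(is.na(pct_display(0, 0)))
})

test_that("variance-stabilized HVG ranking matches a direct recomputation", {
  set.seed(14)
  # row-constant lambdas; rows 3-5 anchor the trend at mean 10 so the
  # bimodal gene g01 (same mean, tenfold variance) dominates after
  # standardization
  mat <- matrix(rpois(10 * 30, lambda = c(1, 5, 10, 10, 10, 2, 8, 5, 3, 4)),
                nrow = 10)
  mat[1, ] <- rep(c(0, 20), 15)
  mat[10, ] <- 3                            # constant gene
  norm <- make_norm(mat)
  got <- suppressWarnings(select_hvg(norm, n = 10))
  expect_identical(got[1], "g01")
  expect_false("g10" %in% got)

  # brute-force standardized variance with the documented small-n trend fit
  x <- as.matrix(norm)
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  pos <- v > 0
  fit <- predict(lm(log10(v[pos]) ~ poly(log10(mu[pos]), 2)))
  exp_sd <- sqrt(10^fit)
  clip <- sqrt(ncol(x))
  z <- pmin(pmax(sweep(sweep(x[pos, ], 1, mu[pos]), 1, exp_sd, "/"), -clip), clip)
  std_var <- apply(z, 1, var)
  expected <- rownames(x)[pos][order(-std_var, rownames(x)[pos])]
  expect_identical(got, expected)
})

test_that("the CV statistic has its worked value and invariances", {
  # group means differ by exactly (1, 2, 3): CV = sd/mean = 1/2
  a <- cbind(c(1, 2, 3), c(1, 2, 3))
  b <- cbind(c(2, 4, 6), c(2, 4, 6))
  norm <- make_norm(cbind(a, b))
  ann <- toy_ann(colnames(norm), rep(c("Iso-R1", "Iso-P8"), each = 2))
  cv <- cv_statistic(norm, ann, "Iso-R1", "Iso-P8", hvgs = rownames(norm))
  expect_equal(cv, 0.5)

  # scaling the difference vector leaves the CV unchanged
  b10 <- cbind(c(11, 22, 33), c(11, 22, 33))
  norm10 <- make_norm(cbind(a, b10))
  cv10 <- cv_statistic(norm10, ann, "Iso-R1", "Iso-P8", hvgs = rownames(norm10))
  expect_equal(cv10, cv, tolerance = 1e-12)

  # gene order does not matter
  perm <- c(3, 1, 2)
  cv_perm <- cv_statistic(norm[perm, ], ann, "Iso-R1", "Iso-P8",
                          hvgs = rownames(norm)[perm])
  expect_equal(cv_perm, cv, tolerance = 1e-12)

  # identical group means: undefined marker
  norm_eq <- make_norm(cbind(a, a))
  expect_true(is.na(cv_statistic(norm_eq, ann, "Iso-R1", "Iso-P8",
                                 hvgs = rownames(norm_eq))))
  expect_error(cv_statistic(norm, ann, "Iso-R1", "Iso-P8", hvgs = character(0)),
               "empty")
})

test_that("CV delta is zero when the intervened group duplicates the aged", {
  set.seed(8)
  base <- matrix(rpois(40 * 6, 5), 40, 6)
  aged <- matrix(rpois(40 * 6, c(rep(5, 20), rep(9, 20))), 40, 6)
  norm <- make_norm(cbind(base, aged, aged))
  ann <- toy_ann(colnames(norm),
                 rep(c("Iso-R1", "Iso-P8", "Het-P8"), each = 6))
  out <- cv_delta(norm, ann, cell_type = "Hep", hvgs = rownames(norm))
  expect_equal(out$delta_cv, 0)
  expect_equal(out$cv_aged, out$cv_intervened)

  # intervened identical to young: intervened CV undefined -> delta NA
  norm2 <- make_norm(cbind(base, aged, base))
  colnames(norm2) <- colnames(norm)
  out2 <- cv_delta(norm2, ann, cell_type = "Hep", hvgs = rownames(norm2))
  expect_true(is.na(out2$cv_intervened))
  expect_true(is.na(out2$delta_cv))
})

test_that("group similarity equals the direct covariance formula", {
  norm <- make_norm(cbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1), c(1, 3, 2)))
  ann <- toy_ann(colnames(norm),
                 c("Iso-R1", "Iso-P8", "Het-P8", "Het-R1"))
  r <- group_similarity(norm, ann, rownames(norm))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r["Iso-R1", "Iso-P8"], 1)   # identical mean vectors
  expect_equal(r["Iso-R1", "Het-P8"], -1)  # exactly reversed

  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(r["Iso-R1", "Het-R1"], pearson(c(1, 2, 3), c(1, 3, 2)),
               tolerance = 1e-12)
  expect_true(isSymmetric(unclass(r)))
})
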