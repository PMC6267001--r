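test_that("spearman matches known values and the permutation oracle", {
  # monotone relationships
  expect_equal(spearman_assoc(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_assoc(1:8, -(1:8))$rho, -1)
  # frozen hand case: ranks (2,1,4,3,5), sum d^2 = 4, rho = 1 - 24/120
  ex <- spearman_assoc(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(ex$rho, 0.8)
  expect_equal(ex$p, 16 / 120, tolerance = 1e-12)
  expect_equal(ex$p, oracle_spearman_p(1:5, c(2, 1, 4, 3, 5)))
  # symmetry and invariance under strictly monotone transforms
  x <- c(3, 1, 4, 1.5, 9, 2.6); y <- c(2, 7, 1.8, 2.8, 1, 8)
  expect_equal(spearman_assoc(x, y), spearman_assoc(y, x))
  expect_equal(spearman_assoc(exp(x), y)$rho, spearman_assoc(x, y)$rho)
  # -1/y is a strictly increasing transform for positive y
  expect_equal(spearman_assoc(x, -1 / y)$rho, spearman_assoc(x, y)$rho)
  # degenerate input
  expect_error(spearman_assoc(rep(1, 5), 1:5),
               class = "skinmwas_error_degenerate")
})

test_that("spearman exact p agrees with enumeration on random untied inputs",
{
  withr::local_seed(401)
  for (i in 1:40) {
    n <- sample(4:7, 1)
    x <- sample(n); y <- sample(n)
    got <- spearman_assoc(x, y)
    expect_equal(got$p, oracle_spearman_p(x, y), tolerance = 1e-10,
                 info = paste("case", i))
  }
})

test_that("signed-rank test matches known values and the sign-flip oracle", {
  # six positive differences: the two extreme assignments out of 2^6
  r <- wilcoxon_signed_rank(rep(0, 6), 1:6)
  expect_equal(r$statistic, 21)
  expect_equal(r$p, 2 / 64)
  # degenerate: no nonzero differences
  d0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(d0$p, 1)
  expect_true(d0$degenerate)
  # tied |d| case, exact by enumeration over 2^4 signings
  rt <- wilcoxon_signed_rank(c(0, 0, 0, 1), c(1, 2, 3, 0))
  or <- oracle_signed_rank(c(1, 2, 3, -1))
  expect_equal(rt$statistic, or$statistic)
  expect_equal(rt$p, or$p)
  # zeros dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(5, 0, 0), c(5, 1, 2))$n_used, 2L)
})

test_that("signed-rank p agrees with enumeration on random inputs", {
  withr::local_seed(402)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    before <- rnorm(n); after <- rnorm(n)
    got <- wilcoxon_signed_rank(before, after)
    expect_equal(got$p, oracle_signed_rank(after - before)$p,
                 tolerance = 1e-10, info = paste("case", i))
  }
})

test_that("rank-sum test matches known values and the assignment oracle", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p, 0.1)
  # symmetry under group swap
  a <- c(1.2, 5, 2.3, 8); b <- c(0.4, 6.1, 2.9)
  expect_equal(wilcoxon_rank_sum(a, b)$p, wilcoxon_rank_sum(b, a)$p)
  # identical samples: no separation
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("rank-sum p agrees with enumeration on random inputs", {
  withr::local_seed(403)
  for (i in 1:40) {
    m <- sample(3:4, 1); n <- sample(3:4, 1)
    a <- rnorm(m); b <- rnorm(n)
    expect_equal(wilcoxon_rank_sum(a, b)$p, oracle_rank_sum(a, b),
                 tolerance = 1e-10, info = paste("case", i))
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::local_seed(404)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_gte(min(q), min(p))
    expect_true(all(q <= 1))
    # order equivariance
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), q[o])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "skinmwas_error_config")
})

test_that("feature association recovers a planted taxon among nulls", {
  st <- simulate_study(tiny_sim_config(seed = 42), genes = FALSE)
  res <- associate_features(st$taxa, st$metadata, "underarm", "children")
  planted_clade <- st$truth$registry$clade[
    st$truth$registry$role == "planted"]
  hit <- res[res$feature == planted_clade, ]
  expect_true(hit$significant)
  expect_gt(hit$rho, 0.2)
  expect_equal(hit$direction, "up")
  expect_equal(hit$n_samples, 30)
  expect_equal(hit$n_pairs, 15)
  # q >= p within the family
  expect_true(all(res$q_spearman >= res$p_spearman - 1e-12))
  expect_true(all(res$q_wilcoxon >= res$p_wilcoxon - 1e-12))
})

test_that("constant features are excluded with a note, not an error", {
  st <- simulate_study(tiny_sim_config(seed = 17), genes = FALSE)
  taxa <- rbind(st$taxa, flatliner = 0)
  expect_message(
    res <- associate_features(taxa, st$metadata, "underarm", "children"),
    "constant")
  expect_false("flatliner" %in% res$feature)
  expect_identical(attr(res, "excluded"), "flatliner")
})

test_that("broken pairing raises an error listing the subjects", {
  st <- simulate_study(tiny_sim_config(seed = 23), genes = FALSE)
  meta <- st$metadata[-1, ]  # drop C01's 1h underarm sample
  expect_error(
    associate_features(st$taxa, meta, "underarm", "children"),
    "C01", class = "skinmwas_error_pairing")
})

test_that("youth stratum pools children and teens", {
  cfg <- sim_config(n_children = 8, n_teens = 5, sites = "underarm",
                    n_taxa = 10,
                    planted_taxa = default_planted_effects()[1, ],
                    seed = 31)
  st <- simulate_study(cfg, genes = FALSE)
  res <- associate_all_strata(st$taxa, st$metadata, "underarm")
  expect_setequal(unique(res$stratum), c("youth", "children", "teens"))
  expect_equal(unique(res$n_samples[res$stratum == "youth"]), 26)
  expect_equal(unique(res$n_samples[res$stratum == "children"]), 16)
  expect_equal(unique(res$n_samples[res$stratum == "teens"]), 10)
})

test_that("the species report renders n.s. and arrows", {
  assoc <- tibble::tibble(
    feature = c("a", "b"), site = "underarm", stratum = "youth",
    rho = c(0.67, -0.45), q_spearman = c(5e-7, 0.2),
    q_wilcoxon = c(0.04, 0.5), direction = c("up", "down"),
    significant = c(TRUE, FALSE))
  tbl <- format_association_table(assoc)
  expect_equal(tbl$spearman_q[2], "n.s.")
  expect_equal(tbl$direction, c("↑", "↓"))
  expect_equal(tbl$wilcoxon_q, c("0.04", "n.s."))
})
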