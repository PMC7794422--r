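test_that("benjamini_hochberg matches hand-worked and edge cases", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("benjamini_hochberg equals the quadratic-time reference", {
  withr::local_seed(8)
  for (rep in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    if (rep %% 3 == 0) p <- round(p, 1)  # force ties
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("consistent_upregulated applies strict thresholds", {
  t1 <- de_table(data.frame(gene_id = c("a", "b", "c", "d"),
                            log2FC = c(1, 1, -2, 1),
                            pvalue = c(0.001, 0.001, 0.001, 0.5),
                            fdr = c(0.01, 0.05, 0.01, 0.6)))
  t2 <- de_table(data.frame(gene_id = c("a", "b", "c", "d"),
                            log2FC = c(2, 1, 2, 1),
                            pvalue = rep(0.001, 4),
                            fdr = rep(0.01, 4)))
  got <- consistent_upregulated(list(t1, t2))
  expect_equal(got, "a")  # b fails fdr == 0.05 (strict), c is down, d fails fdr
  # universe intersection
  expect_equal(consistent_upregulated(list(t1, t2),
                                      universe = c("zzz")), character(0))
  # antitone in thresholds: tightening never adds genes
  loose <- consistent_upregulated(list(t1, t2), l2fc_min = 0,
                                  fdr_max = 0.2)
  tight <- consistent_upregulated(list(t1, t2), l2fc_min = 0.5,
                                  fdr_max = 0.02)
  expect_true(all(tight %in% loose))
  expect_error(consistent_upregulated(list(t1)), "length")
})

test_that("pearson_by_group reports r, p and degenerate cases", {
  expr <- rbind(a = c(1, 2, 3, 4, 10, 20, 30),
                b = c(3, 5, 7, 9, 5, 5, 5))
  groups <- c(rep("lin", 4), rep("flat", 3))
  res <- pearson_by_group(expr, "a", "b", groups)
  lin <- res[res$group == "lin", ]
  expect_equal(lin$pearson_r, 1)           # b = 2a + 1
  flat <- res[res$group == "flat", ]
  expect_true(is.na(flat$pearson_r))
  expect_equal(flat$note, "zero variance")
  # r matches the direct covariance formula and the t-based p
  withr::local_seed(2)
  x <- stats::rnorm(5); y <- stats::rnorm(5)
  res <- pearson_by_group(rbind(a = x, b = y), "a", "b", rep("g", 5))
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson_r, r_direct, tolerance = 1e-12)
  tt <- r_direct * sqrt(3 / (1 - r_direct^2))
  expect_equal(res$p, 2 * stats::pt(-abs(tt), df = 3), tolerance = 1e-12)
  # anticorrelation
  res <- pearson_by_group(rbind(a = x, b = -x), "a", "b", rep("g", 5))
  expect_equal(res$pearson_r, -1)
})

test_that("ddct_fold_change implements 2^-ddCt", {
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1)
  expect_equal(ddct_fold_change(19, 15, 20, 15), 2)
  expect_equal(ddct_fold_change(20, 15, 22, 15), 4)
  expect_error(ddct_fold_change(Inf, 1, 1, 1), "finite")
})

test_that("enrichment score matches boundary examples and the oracle", {
  ranked <- stats::setNames(c(4, 3, 2, 1), c("g1", "g2", "g3", "g4"))
  r <- preranked_enrichment(ranked, "g1", weight_p = 0, n_perm = 50,
                            seed = 1)
  expect_equal(r$es, 1)
  expect_equal(r$leading_edge, "g1")
  r <- preranked_enrichment(ranked, "g4", weight_p = 0, n_perm = 50,
                            seed = 1)
  expect_equal(r$es, -1)
  expect_error(preranked_enrichment(ranked, c("g1", "g2", "g3", "g4")),
               "strictly between")
  expect_error(preranked_enrichment(ranked, "nope"), "strictly between")
  # exhaustive oracle equality on random small lists, both weights
  withr::local_seed(13)
  for (rep in 1:200) {
    n <- sample(3:20, 1)
    scores <- sort(stats::rnorm(n), decreasing = TRUE)
    names(scores) <- paste0("g", seq_len(n))
    nh <- sample(n - 1, 1)
    set <- sample(names(scores), nh)
    wp <- sample(c(0, 1), 1)
    got <- preranked_enrichment(scores, set, weight_p = wp, n_perm = 2,
                                seed = 1)
    expect_equal(got$es,
                 oracle_es(scores, names(scores) %in% set, wp),
                 tolerance = 1e-12)
  }
})

test_that("enrichment agrees with an independent GSEA implementation", {
  withr::local_seed(77)
  scores <- sort(stats::rnorm(200), decreasing = TRUE)
  names(scores) <- paste0("g", 1:200)
  set <- sample(names(scores)[1:80], 25)  # top-skewed set
  mine <- preranked_enrichment(scores, set, weight_p = 1, n_perm = 100,
                               seed = 1)
  ref <- suppressWarnings(
    fgsea::fgsea(list(s = set), scores, nPermSimple = 500,
                 gseaParam = 1))
  expect_equal(mine$es, ref$ES, tolerance = 1e-9)
})

test_that("nominal p is uniform under a random-set null", {
  withr::local_seed(31)
  n <- 80
  scores <- sort(stats::rnorm(n), decreasing = TRUE)
  names(scores) <- paste0("g", seq_len(n))
  pvals <- vapply(1:120, function(i) {
    set <- sample(names(scores), 8)
    preranked_enrichment(scores, set, weight_p = 1, n_perm = 200,
                         seed = 1000 + i)$nominal_p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("GMT round-trips through write_gmt/read_gmt", {
  f <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(myo = c("MYOG", "MEF2A", "TNNI1"), other = c("RB1"))
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
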