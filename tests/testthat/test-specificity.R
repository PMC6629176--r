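test_that("specificity index hits the formula-forced endpoints", {
  # one-hot profile: JSD(p, p) = 0, score exactly 1
  one_hot <- c(a = 0, b = 5, c = 0)
  r <- specificity_index(one_hot)
  expect_equal(r$score, 1)
  expect_equal(r$argmax_tissue, "b")

  # uniform over 5 tissues: the formula value, cross-checked against an
  # independent (KL-form) JSD implementation
  u <- rep(1, 5)
  e <- c(1, 0, 0, 0, 0)
  expected <- 1 - sqrt(jsd_oracle(rep(0.2, 5), e))
  expect_equal(specificity_index(u)$score, expected, tolerance = 1e-12)

  # two tissues [1, 1]: JSD2 = 1.5 - 0.75 * log2(3), oracle-checked
  jsd_closed <- 1.5 - 0.75 * log2(3)
  expect_equal(jsd_oracle(c(0.5, 0.5), c(1, 0)), jsd_closed, tolerance = 1e-12)
  expect_equal(specificity_index(c(1, 1))$score, 1 - sqrt(jsd_closed),
               tolerance = 1e-12)

  expect_error(specificity_index(c(0, 0)), "all-zero")
  expect_error(specificity_index(c(-1, 2)), "negative")
})

test_that("specificity index is scale invariant and permutation equivariant", {
  set.seed(21)
  for (i in 1:50) {
    p <- rlnorm(sample(2:8, 1))
    s <- specificity_index(p)$score
    expect_equal(specificity_index(137 * p)$score, s, tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(specificity_index(p[perm])$score, s, tolerance = 1e-12)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("adding mass to the argmax tissue never decreases the score", {
  set.seed(22)
  for (i in 1:200) {
    p <- rlnorm(sample(2:8, 1))
    k <- which.max(p)
    s0 <- specificity_index(p)$score
    p2 <- p
    p2[k] <- p2[k] + runif(1, 0, 3) * max(p)
    expect_gte(specificity_index(p2)$score, s0 - 1e-12)
  }
})

test_that("binary specificity call uses a closed threshold", {
  expect_true(is_specific(1.0, 0.8))
  expect_false(is_specific(0.0, 0.8))
  expect_true(is_specific(0.8, 0.8))
})

test_that("stage-specific SEs follow the coverage-fraction rule", {
  a <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(1000, 6000),
                  id = c("s1", "s2"), stringsAsFactors = FALSE)
  ident <- stage_specific_ses(list(emb = a, adult = a))
  expect_false(any(ident$emb$specific))
  expect_false(any(ident$adult$specific))

  b <- data.frame(chrom = "chr1", start = 20000, end = 21000, id = "t1",
                  stringsAsFactors = FALSE)
  disj <- stage_specific_ses(list(emb = a, adult = b))
  expect_true(all(disj$emb$specific))
  expect_true(all(disj$adult$specific))

  # 60% of bases covered with threshold 0.5: shared
  part <- stage_specific_ses(list(
    emb = data.frame(chrom = "chr1", start = 0, end = 1000, stringsAsFactors = FALSE),
    adult = data.frame(chrom = "chr1", start = 400, end = 1400, stringsAsFactors = FALSE)
  ), max_other_cover = 0.5)
  expect_equal(part$emb$other_cover, 0.6)
  expect_false(part$emb$specific)
})

test_that("fisher association reports the sample odds ratio and exact p", {
  flat <- fisher_association(rbind(c(1, 1), c(1, 1)))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)
  expect_equal(fisher_association(rbind(c(4, 1), c(2, 3)))$odds_ratio, 6)
  diag <- fisher_association(rbind(c(5, 0), c(0, 5)))
  expect_equal(diag$odds_ratio, Inf)
  expect_equal(diag$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_true(is.na(fisher_association(rbind(c(0, 3), c(0, 2)))$odds_ratio))
})

test_that("fisher p matches full enumeration on random tables", {
  set.seed(31)
  for (i in 1:200) {
    t <- matrix(sample(0:8, 4, replace = TRUE), 2)
    got <- fisher_association(t)$p_value
    expect_equal(got, fisher_p_oracle(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 tolerance = 1e-12)
  }
})

make_expr <- function(values_by_circ) {
  m <- do.call(rbind, values_by_circ)
  colnames(m) <- sprintf("heart:adult:%d", seq_len(ncol(m)))
  rownames(m) <- names(values_by_circ)
  expression_matrix(m)
}

test_that("class expression summary: medians and exact rank-sum p", {
  classes <- data.frame(circ_id = paste0("c", 1:8),
                        label = rep(c("SE-circRNA", "TE-circRNA"), each = 4),
                        stringsAsFactors = FALSE)
  # SE values all strictly greater than TE values: most extreme U
  vals <- as.list(c(11, 12, 13, 14, 1, 2, 3, 4))
  names(vals) <- paste0("c", 1:8)
  expr <- make_expr(vals)
  res <- class_expression_summary(expr, classes)
  expect_equal(res$medians[["SE-circRNA"]], 12.5)
  expect_equal(res$medians[["TE-circRNA"]], 2.5)
  expect_equal(res$p_value, mw_p_oracle(c(11, 12, 13, 14), c(1, 2, 3, 4)),
               tolerance = 1e-12)
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-12)

  # identical distributions: equal medians
  vals2 <- as.list(c(5, 6, 7, 8, 5, 6, 7, 8))
  names(vals2) <- paste0("c", 1:8)
  res2 <- class_expression_summary(make_expr(vals2), classes)
  expect_equal(res2$medians[["SE-circRNA"]], res2$medians[["TE-circRNA"]])

  # empty TE class: test skipped with a warning
  classes3 <- data.frame(circ_id = paste0("c", 1:8),
                         label = c(rep("SE-circRNA", 4), rep("other", 4)),
                         stringsAsFactors = FALSE)
  expect_warning(res3 <- class_expression_summary(expr, classes3), "skipped")
  expect_true(is.na(res3$p_value))
})

test_that("rank-sum p matches enumeration across random 4v4 configurations", {
  set.seed(33)
  for (i in 1:30) {
    pool <- sample(100, 8)
    x <- pool[1:4]; y <- pool[5:8]
    got <- secirc:::rank_sum_test(x, y)
    expect_equal(got, mw_p_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("planted SE-circRNAs are more tissue specific than the rest", {
  d <- tiny_dataset()
  expr <- read_expression_matrix(d$paths$expression)
  spec <- specificity_scores(expr)
  se <- spec$score[spec$entity_id %in% d$ledger$planted_SE_circ_ids]
  rest <- spec$score[!spec$entity_id %in% d$ledger$planted_SE_circ_ids]
  expect_gt(mean(se), mean(rest))
  expect_true(all(spec$argmax_tissue[spec$entity_id %in%
                                       d$ledger$planted_SE_circ_ids] == "heart"))
})
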