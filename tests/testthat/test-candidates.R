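de_expr <- function(m1, m2) {
  # one circ per row of cbind(m1, m2), 1 replicate per stage
  m <- cbind(m1, m2)
  colnames(m) <- c("heart:embryonic:1", "heart:adult:1")
  rownames(m) <- paste0("c", seq_len(nrow(m)))
  expression_matrix(m)
}

test_that("fold-change filter applies the pseudocount and +/- interval", {
  expr <- de_expr(c(1, 2, 0), c(3, 2, 0))
  de <- fold_change_filter(expr, c("embryonic", "adult"), 1.5, 0.1)
  expect_equal(de$fold_change[1], 3.1 / 1.1, tolerance = 1e-12)
  expect_true(de$is_de[1])
  expect_equal(de$fold_change[2], 1)
  expect_false(de$is_de[2])
  expect_equal(de$fold_change[3], 1)  # both zero: pseudocount keeps FC at 1
  expect_false(de$is_de[3])
  # downregulation passes via the lower arm of the interval
  down <- fold_change_filter(de_expr(10, 2), c("embryonic", "adult"))
  expect_true(down$is_de)
  expect_lt(down$log2fc, 0)
  expect_error(fold_change_filter(expr, c("embryonic", "p56")), "stage absent")
})

test_that("reciprocal fold changes multiply to one", {
  set.seed(41)
  for (i in 1:25) {
    m1 <- rlnorm(6, 1, 1); m2 <- rlnorm(6, 1, 1)
    pc <- runif(1, 0, 1)
    fwd <- fold_change_filter(de_expr(m1, m2), c("embryonic", "adult"),
                              pseudocount = pc)$fold_change
    rev <- fold_change_filter(de_expr(m1, m2), c("adult", "embryonic"),
                              pseudocount = pc)$fold_change
    expect_equal(fwd * rev, rep(1, 6), tolerance = 1e-12)
  }
})

test_that("conservation filter requires a complete three-species row", {
  orth <- data.frame(spA_id = c("c1", "c2", "c3"),
                     spB_id = c("b1", NA, "b3"),
                     spC_id = c("x1", "x2", NA), stringsAsFactors = FALSE)
  expect_equal(conservation_filter(c("c1", "c2", "c3", "c9"), orth), "c1")
  expect_setequal(conservation_filter(c("c1", "c2", "c3"), orth,
                                      require_all = FALSE),
                  c("c1", "c2", "c3"))
  empty <- orth[0, ]
  expect_equal(conservation_filter(c("c1"), empty), character(0))
  expect_error(conservation_filter("c1", orth[, 1:2]), "malformed")
})

test_that("percent identity behaves on controlled alignments", {
  a <- strrep("ACGT", 25)
  expect_equal(percent_identity(a, a), 100)
  b <- a
  substr(b, 50, 50) <- ifelse(substr(a, 50, 50) == "A", "C", "A")
  expect_equal(percent_identity(a, b), 99)
  # symmetry
  set.seed(42)
  x <- random_dna(60); y <- random_dna(55)
  expect_equal(percent_identity(x, y), percent_identity(y, x))
  expect_error(nw_align("", "ACGT"))
})

test_that("alignment scores match the Biostrings dynamic-programming oracle", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(43)
  for (i in 1:25) {
    a <- random_dna(sample(20:60, 1))
    b <- if (i %% 3 == 0) paste(rev(strsplit(a, "")[[1]]), collapse = "") else
      random_dna(sample(20:60, 1))
    got <- nw_align(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(got$score, Biostrings::score(ref))
    # identity recomputed from the reported alignment is consistent
    ca <- strsplit(got$aligned_a, "")[[1]]
    cb <- strsplit(got$aligned_b, "")[[1]]
    expect_equal(percent_identity(a, b),
                 100 * sum(ca == cb & ca != "-") / length(ca))
  }
})

test_that("alignment column map transfers positions through indels", {
  a <- "ACGTACGTAC"
  b <- "ACGTCGTAC"  # A at position 4 deleted in b
  map <- alignment_column_map(a, b)
  expect_equal(length(map), 10L)
  expect_equal(map[1:4], 0:3)
  expect_equal(map[6:10], 4:8)
  expect_equal(alignment_column_map(a, a), 0:9)
})

test_that("candidate selection intersects the funnel and ranks deterministically", {
  classes <- data.frame(circ_id = c("c1", "c2", "c3", "c4"),
                        label = c("SE-circRNA", "SE-circRNA", "TE-circRNA",
                                  "SE-circRNA"), stringsAsFactors = FALSE)
  de <- data.frame(circ_id = c("c1", "c2", "c3", "c4"),
                   log2fc = c(1, -2, 3, 1),
                   is_de = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  spec <- data.frame(entity_id = c("c1", "c2"), score = c(0.9, 0.2),
                     stringsAsFactors = FALSE)
  cand <- select_candidates(classes, de, c("c1", "c2", "c3", "c4"), spec)
  expect_equal(cand$circ_id, c("c2", "c1"))  # |log2fc| 2 ranks above 1
  expect_equal(cand$rank, 1:2)
  # empty DE set: empty output
  de0 <- de; de0$is_de <- FALSE
  expect_equal(nrow(select_candidates(classes, de0, "c1", spec)), 0L)
  # specificity breaks |log2fc| ties, then circ id
  de_tie <- data.frame(circ_id = c("c1", "c2"), log2fc = c(1, -1),
                       is_de = TRUE, stringsAsFactors = FALSE)
  cand_tie <- select_candidates(classes[1:2, ], de_tie, c("c1", "c2"), spec)
  expect_equal(cand_tie$circ_id, c("c1", "c2"))
})

test_that("funnel counts are monotone on synthetic data", {
  d <- tiny_dataset()
  expr <- read_expression_matrix(d$paths$expression)
  peaks <- read_bed(d$paths$peaks)
  circs <- read_bed(d$paths$circs)
  regions <- call_superenhancers(peaks)
  classes <- classify_circs(assign_enhancers(regions, circs), circs)
  de <- fold_change_filter(expr, c("embryonic", "adult"))
  conserved <- conservation_filter(rownames(expr$values),
                                   read_orthologs(d$paths$orthologs))
  cand <- select_candidates(classes, de, conserved)
  expect_lte(nrow(cand), sum(classes$label == "SE-circRNA"))
  expect_lte(nrow(cand), sum(de$is_de))
  expect_lte(nrow(cand), length(conserved))
  expect_setequal(cand$circ_id, d$ledger$planted_candidate_ids)
})
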