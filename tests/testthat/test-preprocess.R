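make_ct <- function(df) {
  df$animal <- as.character(df$animal)
  class(df) <- c("ct_table", "data.frame")
  df
}

test_that("per-sample median centering yields forced dCt arithmetic", {
  # two samples x three genes, hand-computed through both centering steps
  ct <- make_ct(data.frame(
    animal = rep(c("a1", "a2"), each = 3),
    strain = "disease", organ = "o",
    age_weeks = rep(c(4, 6), each = 3),
    gene = rep(c("g1", "g2", "g3"), 2),
    ct = c(10, 12, 14,   11, 15, 13)
  ))
  ex <- normalize_ct(ct)
  # sample a1: dCt = (-2, 0, 2); sample a2: dCt = (-2, 2, 0)
  # per-gene medians over the two samples: g1 -2, g2 1, g3 1
  # value = -(dCt - med): a1 (0, 1, -1), a2 (0, -1, 1)
  expect_equal(ex$value, c(0, 1, -1, 0, -1, 1))
})

test_that("identical samples normalize to exactly zero", {
  ct <- make_ct(data.frame(
    animal = rep(c("a1", "a2", "a3"), each = 3),
    strain = "disease", organ = "o", age_weeks = 4,
    gene = rep(c("g1", "g2", "g3"), 3),
    ct = rep(c(10, 12, 17), 3)
  ))
  expect_equal(normalize_ct(ct)$value, rep(0, 9))
})

test_that("both median-zero invariants hold on random data", {
  set.seed(21)
  ct <- make_ct(expand.grid(
    animal = paste0("a", 1:6), strain = "disease", organ = c("o1", "o2"),
    age_weeks = c(4, 8), gene = paste0("g", 1:5),
    stringsAsFactors = FALSE
  ))
  ct$ct <- rnorm(nrow(ct), 20, 3)
  ex <- normalize_ct(ct)
  # per (organ, gene): median over samples of ddCt (= -value) is zero
  med_gene <- tapply(-ex$value, interaction(ex$organ, ex$gene),
                     stats::median)
  expect_true(all(abs(med_gene) < 1e-12))
  # per sample: median over genes of dCt is zero by construction
  dct <- ct$ct - ave(ct$ct, interaction(ct$animal, ct$organ, ct$age_weeks),
                     FUN = stats::median)
  med_sample <- tapply(dct, interaction(ct$animal, ct$organ, ct$age_weeks),
                       stats::median)
  expect_true(all(abs(med_sample) < 1e-12))
})

test_that("samples with every gene missing are excluded with a warning", {
  ct <- make_ct(data.frame(
    animal = rep(c("a1", "a2"), each = 2),
    strain = "disease", organ = "o", age_weeks = 4,
    gene = rep(c("g1", "g2"), 2),
    ct = c(10, 12, NA, NA)
  ))
  expect_warning(ex <- normalize_ct(ct), "all genes missing")
  expect_false("a2" %in% ex$animal)
})

test_that("pseudo-reference ranks respect a brute-force sort of scores", {
  set.seed(31)
  ct <- make_ct(data.frame(
    animal = rep(paste0("a", 1:4), each = 3),
    strain = "disease", organ = "o", age_weeks = 4,
    gene = rep(c("g1", "g2", "g3"), 4),
    ct = rnorm(12, 20)
  ))
  rep_tab <- rank_pseudo_reference(ct)
  wide <- matrix(ct$ct, 4, 3, byrow = TRUE)
  scores <- c(apply(wide, 2, sd), sd(apply(wide, 1, median)))
  expect_equal(rep_tab$median_rank, rank(scores, ties.method = "min")[4])
  expect_equal(rep_tab$n_candidates, 4)
})

test_that("degenerate and monotone stability cases rank as expected", {
  # all genes constant across samples: every candidate ties at rank 1
  ct <- make_ct(data.frame(
    animal = rep(c("a1", "a2"), each = 3),
    strain = "disease", organ = "o", age_weeks = 4,
    gene = rep(c("g1", "g2", "g3"), 2),
    ct = rep(c(10, 11, 12), 2)
  ))
  expect_equal(rank_pseudo_reference(ct)$median_rank, 1)
  # one wildly variable gene is ranked last among candidates
  ct2 <- ct
  ct2$ct[ct2$gene == "g3"] <- c(5, 40)
  r2 <- rank_pseudo_reference(ct2)
  expect_lt(r2$median_rank, 4)
})

test_that("imputation is the identity on complete data", {
  set.seed(41)
  ex <- data.frame(
    animal = rep(paste0("a", 1:5), each = 3),
    strain = "disease", organ = "o",
    age_weeks = rep(c(4, 6, 8, 12, 16), each = 3),
    gene = rep(c("g1", "g2", "g3"), 5),
    value = rnorm(15)
  )
  expect_equal(impute_missing(ex, k = 2), ex)
})

test_that("imputation uses the k-nearest-sample mean (exhaustive oracle)", {
  # five samples, three genes, one missing entry, k = 2
  vals <- matrix(c(1.0, 2.0, 3.0,
                   1.1, 2.1, 3.3,
                   5.0, 6.0, 9.0,
                   1.05, 2.05, NA,
                   4.0, 1.0, 7.0), 5, 3, byrow = TRUE)
  ex <- data.frame(
    animal = rep(paste0("a", 1:5), each = 3),
    strain = "disease", organ = "o", age_weeks = rep(c(4, 6, 8, 12, 16),
                                                     each = 3),
    gene = rep(c("g1", "g2", "g3"), 5),
    value = as.vector(t(vals))
  )
  out <- impute_missing(ex, k = 2)
  # distances on shared genes (g1, g2): a1 and a2 are nearest to a4
  expected <- mean(c(3.0, 3.3))
  expect_equal(out$value[ex$animal == "a4" & ex$gene == "g3"], expected)
  # non-missing entries untouched
  expect_equal(out$value[!is.na(ex$value)], ex$value[!is.na(ex$value)])
})

test_that("imputation with too few neighbors warns and uses all", {
  ex <- data.frame(
    animal = rep(c("a1", "a2"), each = 2),
    strain = "disease", organ = "o", age_weeks = c(4, 4, 6, 6),
    gene = rep(c("g1", "g2"), 2),
    value = c(1, NA, 2, 5)
  )
  expect_warning(out <- impute_missing(ex, k = 10), "neighbor")
  expect_equal(out$value[2], 5)
})

test_that("replicate averaging and dropped-cell grids behave", {
  ex <- data.frame(
    animal = rep(c("a1", "a2"), 5),
    strain = "disease",
    organ = rep(c("o1", "o2"), c(6, 4)),
    age_weeks = c(4, 4, 6, 6, 8, 8, 4, 4, 6, 6),
    gene = "g1",
    value = c(1, 3, 2, 2, 5, 7, 0, 1, 2, 3)
  )
  pr <- mean_profiles(ex)
  expect_equal(pr$mean[pr$organ == "o1"], c(2, 2, 6))
  expect_equal(pr$n_rep[pr$organ == "o1"], c(2, 2, 2))
  # o2 lacks age 8: its grid carries fewer points
  expect_equal(nrow(pr[pr$organ == "o2", ]), 2)
})

test_that("profile scaling is an invertible affine map with degenerate case", {
  pr <- data.frame(strain = "disease", organ = "o", gene = c("g1", "g1",
                                                             "g1"),
                   age_weeks = c(4, 6, 8), mean = c(2, 4, 6), n_rep = 1)
  class(pr) <- c("profile_set", "data.frame")
  sc <- scale_profiles(pr)
  expect_equal(sc$scaled, c(0, 0.5, 1))
  # inverse transform recovers the input
  expect_equal(sc$scaled * (sc$scale_max - sc$scale_min) + sc$scale_min,
               pr$mean, tolerance = 1e-12)
  # idempotence on a scaled non-constant profile
  pr2 <- pr; pr2$mean <- sc$scaled
  expect_equal(scale_profiles(pr2)$scaled, sc$scaled, tolerance = 1e-12)
  # constant profile maps to zeros
  pr3 <- pr; pr3$mean <- rep(5, 3)
  expect_equal(scale_profiles(pr3)$scaled, c(0, 0, 0))
})
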