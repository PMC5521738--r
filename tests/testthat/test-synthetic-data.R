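test_that("zero-density networks are pure self-decay", {
  m <- generate_network(2, 3, density = 0, seed = 4)
  expect_true(all(diag(m$K_true) < 0))
  off <- m$K_true; diag(off) <- 0
  expect_true(all(off == 0))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_network(3, 4, 0.1, seed = 7)
  b <- generate_network(3, 4, 0.1, seed = 7)
  expect_identical(a$K_true, b$K_true)
  expect_identical(a$E0, b$E0)
  c <- generate_network(3, 4, 0.1, seed = 8)
  expect_false(identical(a$K_true, c$K_true))
})

test_that("generated networks are spectrally stable (eigenvalue oracle)", {
  m <- generate_network(3, 4, 0.1, seed = 7)
  ev <- eigen(m$K_true, only.values = TRUE)$values
  expect_lte(max(Re(ev)), 0)
  # requested off-diagonal density honored within one edge
  n_off <- sum(m$K_true[row(m$K_true) != col(m$K_true)] != 0)
  expect_lte(abs(n_off - round(0.1 * 12 * 11)), 1)
})

test_that("dimension and density preconditions are enforced", {
  expect_error(generate_network(0, 3, 0.1))
  expect_error(generate_network(2, 2, -0.1))
})

test_that("null dynamics and the scalar closed form integrate exactly", {
  m0 <- structure(list(K_true = matrix(0, 2, 2,
                                       dimnames = list(c("o.a", "o.b"),
                                                       c("o.a", "o.b"))),
                       E0 = c(o.a = 1.3, o.b = 0.4),
                       nodes = c("o.a", "o.b"), times = c(0, 2, 5)),
                  class = "ground_truth_model")
  tr <- simulate_truth(m0)
  expect_equal(tr$value, rep(c(1.3, 0.4), each = 3), tolerance = 1e-9)

  m1 <- structure(list(K_true = matrix(-1, 1, 1,
                                       dimnames = list("o.a", "o.a")),
                       E0 = c(o.a = 1), nodes = "o.a", times = c(0, 1, 2, 3)),
                  class = "ground_truth_model")
  tr1 <- simulate_truth(m1)
  expect_equal(tr1$value, exp(-c(0, 1, 2, 3)), tolerance = 1e-7)
})

test_that("rotational dynamics reproduce sine and cosine", {
  K <- matrix(c(0, -1, 1, 0), 2, 2,
              dimnames = list(c("o.a", "o.b"), c("o.a", "o.b")))
  m <- structure(list(K_true = K, E0 = c(o.a = 0, o.b = 1),
                      nodes = c("o.a", "o.b"), times = seq(0, 6, by = 0.5)),
                 class = "ground_truth_model")
  tr <- simulate_truth(m)
  tt <- seq(0, 6, by = 0.5)
  expect_equal(tr$value[tr$gene == "a"], sin(tt), tolerance = 1e-6)
  expect_equal(tr$value[tr$gene == "b"], cos(tt), tolerance = 1e-6)
})

test_that("trajectories match the matrix-exponential closed form", {
  m <- generate_network(2, 3, 0.2, seed = 12)
  tr <- simulate_truth(m)
  for (tt in m$times) {
    closed <- as.vector(Matrix::expm(m$K_true * (tt - m$times[1])) %*% m$E0)
    got <- tr$value[tr$age_weeks == tt]
    expect_equal(got, closed, tolerance = 1e-6)
  }
})

test_that("unstable truths are rejected at simulation time", {
  K <- matrix(0.5, 1, 1, dimnames = list("o.a", "o.a"))
  m <- structure(list(K_true = K, E0 = c(o.a = 1), nodes = "o.a",
                      times = 0:3),
                 class = "ground_truth_model")
  expect_error(simulate_truth(m), "unstable")
})

test_that("rewired disease models change only the requested structure", {
  m <- generate_network(3, 4, 0.2, seed = 31)
  d <- rewire_model(m, n_rewire = 3, n_flip = 2, seed = 32)
  expect_identical(d$nodes, m$nodes)
  expect_identical(d$E0, m$E0)
  expect_lte(spectral_abscissa(d$K_true), 0)
  off <- which(row(m$K_true) != col(m$K_true))
  removed <- sum(m$K_true[off] != 0 & d$K_true[off] == 0)
  added <- sum(m$K_true[off] == 0 & d$K_true[off] != 0)
  flipped <- sum(sign(m$K_true[off]) == -sign(d$K_true[off]) &
                   m$K_true[off] != 0 & d$K_true[off] != 0)
  expect_equal(removed, 3)
  expect_equal(added, 3)
  expect_equal(flipped, 2)
  expect_identical(rewire_model(m, 3, 2, seed = 32)$K_true, d$K_true)
})

test_that("normalization round-trips the noiseless Ct layer", {
  # after -ddCt normalization, the difference between two genes of the same
  # organ differs from the true expression difference only by a constant
  m <- generate_network(1, 4, 0.2, seed = 9)
  tr <- simulate_truth(m)
  ct <- generate_ct_dataset(tr, "disease", replicates = 1, noise_sd = 0,
                            seed = 2)
  ex <- normalize_ct(ct)
  val <- function(g) ex$value[ex$gene == g][order(ex$age_weeks[ex$gene == g])]
  tru <- function(g) tr$value[tr$gene == g][order(tr$age_weeks[tr$gene == g])]
  for (g in c("gene02", "gene03", "gene04")) {
    diff_norm <- val(g) - val("gene01")
    diff_true <- tru(g) - tru("gene01")
    expect_equal(diff_norm - diff_true,
                 rep((diff_norm - diff_true)[1], 5), tolerance = 1e-9)
  }
})

test_that("dropped cells are entirely absent", {
  m <- generate_network(2, 3, 0.1, seed = 5)
  tr <- simulate_truth(m)
  ct <- generate_ct_dataset(tr, "disease", replicates = 2,
                            drop_cells = data.frame(organ = "organ01",
                                                    age_weeks = 12),
                            seed = 3)
  expect_equal(sum(ct$organ == "organ01" & ct$age_weeks == 12), 0)
  expect_gt(sum(ct$organ == "organ02" & ct$age_weeks == 12), 0)
})

test_that("missing-at-random rate matches its binomial expectation", {
  m <- generate_network(2, 10, 0.05, seed = 6)
  tr <- simulate_truth(m)
  ct <- generate_ct_dataset(tr, "disease", replicates = 5,
                            missing_rate = 0.04, seed = 11)
  n <- nrow(ct)
  n_missing <- sum(is.na(ct$ct))
  ci <- stats::qbinom(c(0.0005, 0.9995), n, 0.04)
  expect_gte(n_missing, ci[1])
  expect_lte(n_missing, ci[2])
})

test_that("ct dataset writer emits CSV plus a JSON ground-truth sidecar", {
  m <- generate_network(1, 3, 0.1, seed = 2)
  tr <- simulate_truth(m)
  ct <- generate_ct_dataset(tr, "control", replicates = 2, seed = 1)
  path <- file.path(withr::local_tempdir(), "ct.csv")
  write_ct_dataset(ct, m, path)
  expect_true(file.exists(path))
  side <- jsonlite::read_json(sub("csv$", "json", path),
                              simplifyVector = TRUE)
  expect_equal(side$seed, m$seed)
  expect_equal(unname(as.matrix(side$K_true)), unname(m$K_true),
               tolerance = 1e-12)
})
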