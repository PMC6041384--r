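# Representational similarity analysis: edit distance, model matrices,
# brain similarity and group inference.

test_that("feature edit distance handles identity, single-feature and indel cases", {
  ft <- toy_inventory()
  pa <- toy_form("pa", c("p", "a"))
  ba <- toy_form("ba", c("b", "a"))
  a1 <- toy_form("a", "a")
  expect_equal(feature_edit_distance(pa, pa), 0)
  # /p/ and /b/ differ in exactly one feature
  expect_equal(feature_edit_distance(pa, ba), 1)
  expect_equal(feature_edit_distance(pa, a1, indel_cost = 3), 3)
  expect_error(feature_edit_distance(pa, phonological_form("x", "p", ft[1:2, ])),
               "inventory")
  expect_error(phonological_form("bad", c("p", "q"), ft), "unknown segment")
})

test_that("the DP distance equals the exhaustive-alignment oracle on random short strings", {
  ft <- toy_inventory()
  segs <- rownames(ft)
  set.seed(5)
  for (i in 1:60) {
    la <- sample(1:3, 1); lb <- sample(1:3, 1)
    sa <- sample(segs, la, replace = TRUE)
    sb <- sample(segs, lb, replace = TRUE)
    indel <- sample(c(1, 2, 3), 1)
    expect_equal(feature_edit_distance(toy_form("a", sa), toy_form("b", sb), indel),
                 oracle_edit_distance(sa, sb, ft, indel))
  }
})

test_that("feature edit distance is a metric on the toy inventory (strings up to length 3)", {
  ft <- toy_inventory()
  segs <- rownames(ft)
  strings <- unlist(lapply(1:3, function(l) {
    g <- do.call(expand.grid, rep(list(segs), l))
    apply(g, 1, paste, collapse = " ")
  }))
  forms <- lapply(seq_along(strings), function(i) {
    toy_form(paste0("s", i), strsplit(strings[i], " ")[[1]])
  })
  n <- length(forms)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- feature_edit_distance(forms[[i]], forms[[j]])
      d[j, i] <- feature_edit_distance(forms[[j]], forms[[i]])
    }
  }
  expect_true(all(d == t(d)))          # symmetry, computed both ways
  expect_true(all(diag(d) == 0))
  for (k in seq_len(n)) {              # triangle inequality through every midpoint
    expect_true(all(d <= outer(d[, k], d[k, ], "+") + 1e-9))
  }
})

test_that("phonological model matrices are symmetric negated distances with rank fidelity", {
  ft <- toy_inventory()
  forms <- list(toy_form("w1", c("p", "a")), toy_form("w2", c("b", "a")),
                toy_form("w3", c("t", "t", "a")))
  m <- phonological_model_matrix(forms)
  expect_true(isSymmetric(m$values))
  expect_true(all(diag(m$values) == 0))
  expect_true(all(m$values <= 0))
  # rank order matches hand-computed distances
  d12 <- feature_edit_distance(forms[[1]], forms[[2]])
  d13 <- feature_edit_distance(forms[[1]], forms[[3]])
  d23 <- feature_edit_distance(forms[[2]], forms[[3]])
  expect_equal(order(c(m$values[1, 2], m$values[1, 3], m$values[2, 3])),
               order(-c(d12, d13, d23)))
  same <- list(toy_form("w1", "a"), toy_form("w2", "a"), toy_form("w3", "a"))
  ms <- phonological_model_matrix(same)
  expect_true(all(ms$values == 0))
  dup <- list(toy_form("w1", "a"), toy_form("w1", "a"))
  expect_error(phonological_model_matrix(dup), "duplicate")
})

test_that("semantic similarity is the cosine of the supplied vectors", {
  v <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0), d = c(1, 1, 0))
  m <- semantic_model_matrix(v)
  expect_equal(m$values["a", "b"], 1)
  expect_equal(m$values["a", "c"], 0)
  expect_equal(m$values["d", "a"], 1 / sqrt(2))
  expect_error(semantic_model_matrix(rbind(a = c(1, 0), z = c(0, 0))), "zero semantic vector")
})

test_that("brain similarity is tie-corrected Spearman with undefined pairs flagged", {
  b <- rbind(w1 = c(1, 2, 3, 4), w2 = c(2, 4, 6, 8), w3 = c(4, 3, 2, 1))
  m <- brain_similarity_matrix(b)
  expect_equal(m$values["w1", "w2"], 1)
  expect_equal(m$values["w1", "w3"], -1)
  # ties resolved by average ranks: these two patterns agree perfectly
  tied <- rbind(a = c(1, 2, 2, 3), b = c(1, 3, 3, 4))
  mt <- brain_similarity_matrix(tied)
  expect_equal(mt$values["a", "b"], 1)
  expect_equal(mt$values["a", "b"], oracle_spearman(c(1, 2, 2, 3), c(1, 3, 3, 4)))
  # constant pattern -> flagged NA pair, no error
  cst <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(2, 1, 4, 3))
  mc <- brain_similarity_matrix(cst)
  expect_true(is.na(mc$values["a", "b"]))
  expect_equal(attr(mc, "undefined_pairs"), 2L)
  expect_false(is.na(mc$values["b", "c"]))
})

test_that("package Spearman values match the definitional rank formula on tied vectors", {
  set.seed(7)
  for (i in 1:200) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    m <- brain_similarity_matrix(rbind(a = x, b = y))
    expect_equal(m$values["a", "b"], oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("rsa correlation is monotone-invariant, permutation-equivariant and validated", {
  set.seed(9)
  v <- matrix(stats::rnorm(25), 5, 5)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  ids <- letters[1:5]
  brain <- similarity_matrix(v, ids, "brain")
  expect_equal(rsa_correlation(brain, brain), 1)
  # strictly increasing transform of the model leaves the correlation unchanged
  model <- similarity_matrix(exp(2 * v), ids, "semantic")
  expect_equal(rsa_correlation(brain, model), 1)
  lt3 <- matrix(0, 3, 3)
  lt3[lower.tri(lt3)] <- c(0.1, 0.2, 0.3)
  lt3 <- lt3 + t(lt3)
  m1 <- similarity_matrix(lt3, letters[1:3], "brain")
  lt3b <- matrix(0, 3, 3)
  lt3b[lower.tri(lt3b)] <- c(5, 6, 7)
  lt3b <- lt3b + t(lt3b)
  m2 <- similarity_matrix(lt3b, letters[1:3], "semantic")
  expect_equal(rsa_correlation(m1, m2), 1)
  # identical permutation of both matrices
  p <- c(3, 1, 5, 2, 4)
  bp <- similarity_matrix(v[p, p], ids[p], "brain")
  mp <- similarity_matrix(exp(2 * v)[p, p], ids[p], "semantic")
  expect_equal(rsa_correlation(bp, mp), rsa_correlation(brain, model))
  # word-set mismatch
  other <- similarity_matrix(v, letters[6:10], "semantic")
  expect_error(rsa_correlation(brain, other), "same words")
})

test_that("rsa correlation with ties matches a brute-force rank computation", {
  b4 <- matrix(0, 4, 4)
  b4[lower.tri(b4)] <- c(0.2, 0.2, 0.5, 0.1, 0.4, 0.3)
  b4 <- b4 + t(b4); diag(b4) <- 1
  m4 <- matrix(0, 4, 4)
  m4[lower.tri(m4)] <- c(1, 3, 2, 6, 5, 4)
  m4 <- m4 + t(m4); diag(m4) <- 0
  got <- rsa_correlation(similarity_matrix(b4, letters[1:4], "brain"),
                         similarity_matrix(m4, letters[1:4], "semantic"))
  expect_equal(got, oracle_spearman(c(0.2, 0.2, 0.5, 0.1, 0.4, 0.3), c(1, 3, 2, 6, 5, 4)))
})

test_that("group RSA tests match closed-form t statistics and reporting conventions", {
  g <- group_rsa_test(c(0.1, 0.2, 0.3), tail = "greater")
  expect_equal(g$t, 3.4641, tolerance = 1e-4)
  expect_equal(g$dof, 2)
  expect_equal(g$p, 0.0371, tolerance = 1e-3)
  sym <- group_rsa_test(c(-0.2, -0.1, 0.1, 0.2), tail = "greater")
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 0.5)
  expect_equal(group_rsa_test(stats::rnorm(30))$dof, 29)
  expect_true(group_rsa_test(rep(0.2, 5))$degenerate)

  b <- between_group_rsa_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(b$t, -3.674, tolerance = 1e-3)
  expect_equal(b$dof, 4)
  expect_equal(between_group_rsa_test(stats::rnorm(30), rep(1:2, c(10, 20)))$dof, 28)
  eq <- between_group_rsa_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(eq$t, 0)
  expect_error(between_group_rsa_test(1:4, rep("a", 4)), "two groups")
})

test_that("the packaged inventory covers the stimulus list and splits 20/10 by condition", {
  words <- load_stimulus_words()
  expect_equal(sum(words$condition == "word"), 20)
  expect_equal(sum(words$condition == "pseudoword"), 10)
  ft <- load_phoneme_features()
  segs <- unique(unlist(strsplit(words$phonemes, " ")))
  expect_true(all(segs %in% rownames(ft)))
  forms <- stimulus_phonological_forms()
  expect_length(forms, 30)
  m <- phonological_model_matrix(forms)
  expect_true(isSymmetric(m$values))
})
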