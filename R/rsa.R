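# Representational similarity analysis: phonological feature edit distance,
# model similarity matrices, brain similarity matrices and group inference.

#' Similarity matrix container
#'
#' @param values square symmetric numeric matrix.
#' @param word_ids ordered character vector of word identifiers.
#' @param kind one of `"brain"`, `"phonological"`, `"semantic"`.
#' @return object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, word_ids, kind = c("brain", "phonological", "semantic")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- length(word_ids)
  if (nrow(values) != n || ncol(values) != n) {
    stop_invalid("similarity values must be %d x %d", n, n)
  }
  if (anyDuplicated(word_ids)) stop_invalid("word ids must be unique")
  finite <- is.finite(values)
  if (any(abs(values[finite] - t(values)[finite]) > 1e-8)) {
    stop_invalid("similarity matrix must be symmetric")
  }
  dimnames(values) <- list(word_ids, word_ids)
  structure(list(word_ids = as.character(word_ids), values = values, kind = kind),
            class = "similarity_matrix")
}

similarity_values <- function(x) {
  if (inherits(x, "similarity_matrix")) x$values else as.matrix(x)
}

#' Phonological form of a word
#'
#' @param word_id identifier.
#' @param phonemes ordered character vector of segment tokens.
#' @param feature_table numeric matrix of feature values with one row per
#'   segment (rownames are segment tokens); all forms entering a distance
#'   computation must share it.
#' @return object of class `phonological_form`.
#' @export
phonological_form <- function(word_id, phonemes, feature_table) {
  feature_table <- as.matrix(feature_table)
  unknown <- setdiff(phonemes, rownames(feature_table))
  if (length(unknown)) {
    stop_invalid("unknown segment(s) not in the feature inventory: %s",
                 paste(unknown, collapse = ", "))
  }
  structure(list(word_id = word_id, phonemes = as.character(phonemes),
                 feature_table = feature_table),
            class = "phonological_form")
}

#' Phonological feature edit distance
#'
#' Minimal-cost alignment of two phoneme strings by dynamic programming,
#' where substituting one segment for another costs the number of features on
#' which they differ, and inserting or deleting a segment costs `indel_cost`.
#' With binary features this counts the one-feature changes needed to
#' transform one phonological string into the other.
#'
#' @param a,b `phonological_form` objects over the same feature inventory.
#' @param indel_cost insertion/deletion cost; defaults to the number of
#'   feature dimensions (an inserted segment differs from nothing on every
#'   feature).
#' @return non-negative numeric distance.
#' @export
feature_edit_distance <- function(a, b, indel_cost = NULL) {
  stopifnot(inherits(a, "phonological_form"), inherits(b, "phonological_form"))
  ft <- a$feature_table
  if (!identical(dim(ft), dim(b$feature_table)) ||
      !identical(rownames(ft), rownames(b$feature_table))) {
    stop_invalid("forms must share one feature inventory")
  }
  indel_cost <- indel_cost %||% ncol(ft)
  sa <- a$phonemes; sb <- b$phonemes
  na <- length(sa); nb <- length(sb)
  sub_cost <- function(p, q) sum(ft[p, ] != ft[q, ])
  dmat <- matrix(0, na + 1, nb + 1)
  dmat[, 1] <- (0:na) * indel_cost
  dmat[1, ] <- (0:nb) * indel_cost
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      dmat[i + 1, j + 1] <- min(
        dmat[i, j] + sub_cost(sa[i], sb[j]),
        dmat[i, j + 1] + indel_cost,
        dmat[i + 1, j] + indel_cost
      )
    }
  }
  dmat[na + 1, nb + 1]
}

#' Phonological model similarity matrix
#'
#' Pairwise feature edit distances converted to similarities by negation; the
#' conversion is rank-preserving, which is all the downstream Spearman-based
#' statistics use.
#'
#' @param forms list of [phonological_form()] objects (unique word ids).
#' @param indel_cost passed to [feature_edit_distance()].
#' @return `similarity_matrix` of kind `"phonological"` (diagonal 0, the
#'   maximal value for a negated distance).
#' @export
phonological_model_matrix <- function(forms, indel_cost = NULL) {
  if (length(forms) < 2) stop_invalid("need at least two forms")
  ids <- vapply(forms, function(f) f$word_id, character(1))
  if (anyDuplicated(ids)) stop_invalid("duplicate word ids: %s",
                                       paste(ids[duplicated(ids)], collapse = ", "))
  n <- length(forms)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- feature_edit_distance(forms[[i]], forms[[j]], indel_cost)
    }
  }
  similarity_matrix(-d, ids, kind = "phonological")
}

#' Semantic model similarity matrix from word vectors
#'
#' Pairwise cosine similarity between supplied semantic vectors (for example
#' vectors from a distributional-semantics model).
#'
#' @param vectors numeric matrix, one row per word (rownames are word ids),
#'   or a named list of equal-length vectors.
#' @return `similarity_matrix` of kind `"semantic"`.
#' @export
semantic_model_matrix <- function(vectors) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  v <- as.matrix(vectors)
  if (is.null(rownames(v))) rownames(v) <- sprintf("word%02d", seq_len(nrow(v)))
  norms <- sqrt(rowSums(v^2))
  if (any(norms == 0)) {
    stop_invalid("zero semantic vector(s): %s", paste(rownames(v)[norms == 0], collapse = ", "))
  }
  u <- v / norms
  similarity_matrix(tcrossprod(u), rownames(v), kind = "semantic")
}

#' Synthetic semantic vectors
#'
#' Random unit-norm vectors standing in for distributional semantic vectors;
#' clearly synthetic, used by the simulator and examples when no external
#' semantic similarities are supplied.
#'
#' @param word_ids character vector of word ids.
#' @param dim vector dimensionality (default 50).
#' @param seed RNG seed.
#' @return numeric matrix (word x dim) with unit-norm rows.
#' @export
synthetic_semantic_vectors <- function(word_ids, dim = 50L, seed = 1L) {
  set.seed(seed)
  v <- matrix(stats::rnorm(length(word_ids) * dim), length(word_ids), dim)
  v <- v / sqrt(rowSums(v^2))
  rownames(v) <- word_ids
  v
}

#' Brain-derived similarity matrix for one ROI and subject
#'
#' Pairwise tie-corrected Spearman correlation (average ranks) between the
#' per-word beta-weight vectors over the voxels of an ROI. Pairs involving a
#' constant pattern have undefined rank correlation; they are returned as
#' `NA` and excluded downstream rather than raising an error.
#'
#' @param betas numeric matrix (word x voxel), e.g. mean-centered per-word
#'   beta maps restricted to one ROI.
#' @return `similarity_matrix` of kind `"brain"` (unit diagonal); the
#'   attribute `undefined_pairs` counts `NA` off-diagonal pairs.
#' @export
brain_similarity_matrix <- function(betas) {
  b <- as.matrix(betas)
  if (nrow(b) < 2) stop_invalid("need at least two words")
  if (ncol(b) < 2) stop_invalid("need at least two voxels per pattern")
  rho <- suppressWarnings(stats::cor(t(b), method = "spearman"))
  diag(rho) <- 1
  ids <- rownames(b) %||% sprintf("word%02d", seq_len(nrow(b)))
  out <- similarity_matrix(rho, ids, kind = "brain")
  attr(out, "undefined_pairs") <- sum(is.na(rho[lower.tri(rho)]))
  out
}

#' Correlate a brain similarity matrix with a model matrix
#'
#' Tie-corrected Spearman correlation over the lower-triangle entries
#' (diagonal excluded) of two similarity matrices over the same words in the
#' same order. Undefined (`NA`) pairs are excluded pairwise.
#'
#' @param brain,model `similarity_matrix` objects with identical word ids.
#' @return numeric scalar in `[-1, 1]` (`NA` when fewer than 3 defined pairs
#'   or a degenerate constant triangle).
#' @export
rsa_correlation <- function(brain, model) {
  b <- similarity_values(brain); m <- similarity_values(model)
  bi <- if (inherits(brain, "similarity_matrix")) brain$word_ids else rownames(b)
  mi <- if (inherits(model, "similarity_matrix")) model$word_ids else rownames(m)
  if (!identical(as.character(bi), as.character(mi))) {
    stop_invalid("brain and model matrices must cover the same words in the same order")
  }
  lb <- b[lower.tri(b)]; lm <- m[lower.tri(m)]
  ok <- is.finite(lb) & is.finite(lm)
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(stats::cor(lb[ok], lm[ok], method = "spearman"))
}

#' One-sample group test of RSA correlations
#'
#' Tests whether the mean per-subject brain-model correlation differs from
#' zero; one-tailed (greater) by default, matching the directional hypothesis
#' that a region carries model information.
#'
#' @param values per-subject correlation values (n >= 2).
#' @param tail `"greater"`, `"less"` or `"two.sided"`.
#' @return list with `t`, `dof`, `p`, `mean` and `degenerate` flag.
#' @export
group_rsa_test <- function(values, tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  values <- values[is.finite(values)]
  if (length(values) < 2) stop_invalid("need at least two values")
  if (stats::sd(values) == 0) {
    return(list(t = NA_real_, dof = length(values) - 1L, p = NA_real_,
                mean = mean(values), degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = 0, alternative = tail)
  list(t = unname(ht$statistic), dof = unname(ht$parameter), p = ht$p.value,
       mean = mean(values), degenerate = FALSE)
}

#' Two-sample comparison of RSA correlations between subgroups
#'
#' Pooled-variance (Student) two-sample t test of per-subject correlation
#' values between two groups; dof = n1 + n2 - 2.
#'
#' @param values per-subject values.
#' @param labels group labels (exactly two groups, each n >= 2).
#' @param tail test direction (default two-sided).
#' @return list with `t`, `dof`, `p`, `group_means`, `degenerate`.
#' @export
between_group_rsa_test <- function(values, labels,
                                   tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  ok <- is.finite(values)
  values <- values[ok]; labels <- labels[ok]
  gs <- unique(labels)
  if (length(gs) != 2) stop_invalid("need exactly two groups, got %d", length(gs))
  x <- values[labels == gs[1]]; y <- values[labels == gs[2]]
  if (length(x) < 2 || length(y) < 2) stop_invalid("each group needs at least two values")
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    return(list(t = NA_real_, dof = length(values) - 2L, p = NA_real_,
                group_means = c(mean(x), mean(y)), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE, alternative = tail)
  list(t = unname(ht$statistic), dof = unname(ht$parameter), p = ht$p.value,
       group_means = stats::setNames(c(mean(x), mean(y)), gs), degenerate = FALSE)
}

#' Load the packaged phoneme feature inventory
#'
#' A small binary feature table over an English-subset segment inventory
#' (ARPAbet-style segment codes), sufficient for the packaged stimulus list.
#'
#' @return numeric matrix, segments x features (0/1).
#' @export
load_phoneme_features <- function() {
  path <- system.file("extdata", "phoneme_features.csv", package = "readerclust")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Load the packaged stimulus word list
#'
#' 20 words and 10 pronounceable pseudowords with phoneme transcriptions.
#' Items named in the source literature are marked `attested`; the remainder
#' are synthetic padding and marked `synthetic`.
#'
#' @return data frame with `stimulus_id`, `condition`, `phonemes`
#'   (space-separated segment codes) and `origin`.
#' @export
load_stimulus_words <- function() {
  path <- system.file("extdata", "stimulus_words.csv", package = "readerclust")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Phonological forms for the packaged stimulus list
#'
#' @param words data frame as returned by [load_stimulus_words()] (default).
#' @param features feature table (default [load_phoneme_features()]).
#' @param condition optional filter, e.g. `"word"` for the RSA word set.
#' @return list of [phonological_form()] objects.
#' @export
stimulus_phonological_forms <- function(words = load_stimulus_words(),
                                        features = load_phoneme_features(),
                                        condition = NULL) {
  if (!is.null(condition)) words <- words[words$condition %in% condition, , drop = FALSE]
  lapply(seq_len(nrow(words)), function(i) {
    phonological_form(words$stimulus_id[i],
                      strsplit(words$phonemes[i], " ", fixed = TRUE)[[1]],
                      features)
  })
}
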