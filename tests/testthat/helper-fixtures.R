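# Small in-code fixtures shared across test files.

# A tiny raw extraction table covering every statistic kind.
tiny_raw <- function() {
  tibble::tibble(
    study_id = c("s1", "s1", "s2", "s3"),
    estimate_id = c("e1", "e2", "e3", "e4"),
    species = c("Homo sapiens", "Homo sapiens", "Parus major", "Parus major"),
    statistic_kind = c("slope_t", "correlation", "slope_ci", "estimate_ci"),
    value = c(0.12, 0.30, 0.095, -0.087),
    se = c(0.06, NA, NA, NA),
    ci_upper = c(NA, NA, 0.124, 0.094),
    t_value = c(2, NA, NA, NA),
    df = c(96, NA, 40, 30),
    n = c(100, 50, 45, 35),
    year = c(2015, 2015, 2019, 2021),
    parental_sex = c("father", "mother", "father", "mother"),
    lab_method = c("qPCR", "qPCR", "TRF_southern", "qPCR")
  )
}

# Standardised effects with known structure for design/fit tests.
toy_effects <- function(n = 12, seed = 1, v = NULL) {
  withr::with_seed(seed, {
    tibble::tibble(
      study_id = rep(sprintf("s%d", seq_len(ceiling(n / 2))),
                     each = 2, length.out = n),
      estimate_id = sprintf("e%02d", 1:n),
      species = rep(c("A", "B"), length.out = n),
      zr = rnorm(n, 0.1, 0.2),
      v_z = v %||% runif(n, 0.005, 0.05),
      year = sample(2005:2020, n, replace = TRUE),
      sex = sample(c("mother", "father"), n, replace = TRUE),
      method = sample(c("qPCR", "TRF"), n, replace = TRUE)
    )
  })
}

`%||%` <- rlang::`%||%`

# Independent path-walking computation of shared root-to-MRCA branch length:
# intersects the edge sets of the two root-to-tip paths.
shared_path_oracle <- function(tree, tip_a, tip_b) {
  edges <- tree$edge
  path_edges <- function(tip) {
    node <- which(tree$tip.label == tip)
    out <- integer(0)
    repeat {
      row <- which(edges[, 2] == node)
      if (!length(row)) break
      out <- c(out, row)
      node <- edges[row, 1]
    }
    out
  }
  shared <- intersect(path_edges(tip_a), path_edges(tip_b))
  sum(tree$edge.length[shared])
}

tip_depth_oracle <- function(tree, tip) shared_path_oracle(tree, tip, tip)
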