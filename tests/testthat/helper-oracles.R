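# Independent oracles and fixture builders, kept deliberately separate from
# the package's implementation paths.

classes3 <- c("TB", "PDC", "NEITHER")

# Literal loop-wise evaluation of the Fleiss kappa formula chain from an
# objects x raters character matrix.
fleiss_oracle <- function(ratings) {
  N <- nrow(ratings)
  n <- ncol(ratings)
  nij <- matrix(0, N, 3)
  for (i in seq_len(N)) {
    for (j in 1:3) nij[i, j] <- sum(ratings[i, ] == classes3[j])
  }
  P_i <- numeric(N)
  for (i in seq_len(N)) P_i[i] <- (sum(nij[i, ]^2) - n) / (n * (n - 1))
  Pbar <- mean(P_i)
  p_j <- colSums(nij) / (N * n)
  Pe <- sum(p_j^2)
  if (Pbar == 1) return(1)
  (Pbar - Pe) / (1 - Pe)
}

# Brute-force contingency-table evaluation of Cohen kappa.
cohen_oracle <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  tab <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e == 1) return(if (p_o == 1) 1 else p_o - p_e)
  (p_o - p_e) / (1 - p_e)
}

# Random complete panel as a bare character matrix.
random_ratings <- function(n_obj, n_raters, seed) {
  withr::with_seed(seed, {
    matrix(sample(classes3, n_obj * n_raters, replace = TRUE),
           n_obj, n_raters)
  })
}

# Vote-count patterns realizing the published IHC summary-table marginals
# (3000 objects x 7 raters).
table1_ihc_votes <- function() {
  rbind(
    matrix(rep(c(7, 0, 0), 612), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 7, 0), 15), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 0, 7), 386), ncol = 3, byrow = TRUE),
    matrix(rep(c(5, 1, 1), 398), ncol = 3, byrow = TRUE),
    matrix(rep(c(1, 5, 1), 37), ncol = 3, byrow = TRUE),
    matrix(rep(c(1, 1, 5), 317), ncol = 3, byrow = TRUE),
    matrix(rep(c(4, 2, 1), 1235), ncol = 3, byrow = TRUE))
}

# H&E arm marginals (150 objects x 11 raters).
table1_he_votes <- function() {
  rbind(
    matrix(rep(c(11, 0, 0), 8), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 11, 0), 1), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 0, 11), 13), ncol = 3, byrow = TRUE),
    matrix(rep(c(8, 2, 1), 31), ncol = 3, byrow = TRUE),
    matrix(rep(c(1, 8, 2), 10), ncol = 3, byrow = TRUE),
    matrix(rep(c(2, 1, 8), 68), ncol = 3, byrow = TRUE),
    matrix(rep(c(7, 2, 2), 19), ncol = 3, byrow = TRUE))
}

# Small scene spec used across image tests: quarter-size tile, scaled-down
# object counts, fast to generate.
small_scene <- function(seed, noise_sd = 0, classes = NULL) {
  if (is.null(classes)) {
    classes <- list(
      object_class("artifact", 2, c(5, 20), c(0.4, 0.9)),
      object_class("bud", 3, c(30, 500), c(0.6, 1.2)),
      object_class("pdc", 1, c(1100, 2500), c(0.6, 1.2)))
  }
  scene_spec(tile_size_px = c(512L, 512L), object_classes = classes,
             noise_sd = noise_sd, seed = seed)
}

summary_count <- function(smry, tier, class) {
  t <- smry$table
  if (tier == "no_agreement") return(t$count[t$tier == "no_agreement"])
  t$count[t$tier == tier & !is.na(t$class) & t$class == class]
}
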