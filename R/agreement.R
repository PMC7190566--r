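#' Fleiss kappa for a fixed-rater-count categorical panel
#'
#' Chance-corrected agreement for `n >= 2` raters assigning each of `N`
#' objects to one of the three categories. With `n_ij` raters placing
#' object `i` in class `j`:
#' per-object agreement `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`,
#' observed agreement `Pbar = mean_i P_i`, class shares
#' `p_j = sum_i n_ij / (N n)`, chance agreement `Pe = sum_j p_j^2`, and
#' `kappa = (Pbar - Pe) / (1 - Pe)`. Perfect agreement (`Pbar = 1`) returns
#' exactly 1 even when `Pe` saturates; a panel whose ratings all fall in a
#' single class is degenerate (the statistic is uninformative) and returns
#' 1 with a warning.
#'
#' @param panel A [rating_panel()], or an objects x classes matrix of vote
#'   counts with constant row sums.
#'
#' @return Kappa in `[-1, 1]`.
#' @export
fleiss_kappa <- function(panel) {
  counts <- if (inherits(panel, "rating_panel")) vote_counts(panel) else {
    stopifnot(is.matrix(panel), all(panel >= 0))
    panel
  }
  if (nrow(counts) < 1L) stop("panel must contain at least one object")
  n <- unique(rowSums(counts))
  if (length(n) != 1L) {
    stop("Fleiss kappa requires a constant rater count per object")
  }
  if (n < 2L) stop("Fleiss kappa requires at least 2 raters per object")
  N <- nrow(counts)
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(P_i)
  p_j <- colSums(counts) / (N * n)
  Pe <- sum(p_j^2)
  if (Pbar >= 1 - 1e-15) {
    if (max(p_j) >= 1 - 1e-15) {
      warning("all ratings fall in a single class; kappa is degenerate ",
              "(returned as 1)")
    }
    return(1)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Cohen kappa for two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement
#' fraction and `p_e = sum_j p_aj p_bj` from the two raters' marginal class
#' fractions (unweighted, nominal categories). Saturated chance agreement
#' (`p_e = 1`, both raters constant on one class) with perfect observed
#' agreement returns 1.
#'
#' @param ratings_a,ratings_b Equal-length categorical vectors over the
#'   shared object set.
#'
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have equal length")
  }
  if (length(ratings_a) < 1L) stop("at least one shared object is required")
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(ratings_a, levels = lev)
  b <- factor(ratings_b, levels = lev)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / length(a)) * (table(b) / length(b)))
  if (p_e >= 1 - 1e-15) {
    return(if (p_o >= 1 - 1e-15) 1 else (p_o - p_e))
  }
  (p_o - p_e) / (1 - p_e)
}

#' Pairwise Cohen kappa matrix over a panel's raters
#'
#' Entry `(a, b)` is the Cohen kappa of raters `a` and `b` over the objects
#' both rated (relevant when raters scored different subsets). Pairs with
#' no shared objects are `NA` — absence of data is not agreement — as is
#' the diagonal.
#'
#' @param panel A [rating_panel()] (may be incomplete).
#'
#' @return Symmetric rater x rater numeric matrix.
#' @export
pairwise_kappa_matrix <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  r <- panel$ratings
  k <- ncol(r)
  out <- matrix(NA_real_, k, k,
                dimnames = list(panel$rater_ids, panel$rater_ids))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      shared <- !is.na(r[, i]) & !is.na(r[, j])
      if (any(shared)) {
        out[i, j] <- out[j, i] <- cohen_kappa(r[shared, i], r[shared, j])
      }
    }
  }
  out
}

#' Landis-Koch verbal interpretation of a kappa value
#'
#' Bands: poor (kappa <= 0.20), fair (0.20, 0.40], moderate (0.40, 0.60],
#' good (0.60, 0.80], very good (> 0.80). Half-open upper-inclusive
#' intervals make the banding deterministic at the printed boundaries.
#'
#' @param k Numeric vector of kappa values in `[-1, 1]`.
#'
#' @return Character vector of band labels.
#' @examples
#' interpret_kappa(c(0.42, 0.51)) # both "moderate"
#' @export
interpret_kappa <- function(k) {
  stopifnot(is.numeric(k))
  if (any(is.na(k)) || any(k < -1) || any(k > 1)) {
    stop("kappa values must lie in [-1, 1]")
  }
  cut(k, breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
      labels = c("poor", "fair", "moderate", "good", "very good"),
      right = TRUE) |> as.character()
}

#' Full interobserver agreement report
#'
#' Fleiss kappa per rater group (or overall when no groups are set), the
#' pairwise Cohen kappa matrix, and Landis-Koch band labels for every
#' statistic.
#'
#' @param panel A [rating_panel()].
#'
#' @return Object of class `agreement_report`: list with `fleiss`
#'   (data.frame: `group`, `kappa`, `band`), `cohen_matrix` and
#'   `cohen_bands` (character matrix, `NA` where undefined).
#' @export
agreement_report <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  groups <- panel$rater_groups
  if (is.null(groups)) {
    groups <- setNames(rep("all", length(panel$rater_ids)), panel$rater_ids)
  }
  fl <- do.call(rbind, lapply(unique(groups), function(g) {
    sub <- panel$ratings[, names(groups)[groups == g], drop = FALSE]
    keep <- rowSums(!is.na(sub)) > 0
    kp <- fleiss_kappa(rating_panel(sub[keep, , drop = FALSE],
                                    allow_incomplete = TRUE))
    data.frame(group = g, kappa = kp, band = interpret_kappa(kp))
  }))
  cm <- pairwise_kappa_matrix(panel)
  bands <- cm
  bands[] <- NA_character_
  bands[!is.na(cm)] <- interpret_kappa(cm[!is.na(cm)])
  structure(list(fleiss = fl, cohen_matrix = cm, cohen_bands = bands),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Fleiss kappa per group:\n")
  for (i in seq_len(nrow(x$fleiss))) {
    cat(sprintf("  %s: %.3f (%s)\n", x$fleiss$group[i], x$fleiss$kappa[i],
                x$fleiss$band[i]))
  }
  off <- x$cohen_matrix[upper.tri(x$cohen_matrix)]
  off <- off[!is.na(off)]
  if (length(off)) {
    cat(sprintf("Pairwise Cohen kappa: %d pairs, range %.3f to %.3f\n",
                length(off), min(off), max(off)))
  }
  invisible(x)
}
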