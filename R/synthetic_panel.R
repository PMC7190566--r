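#' Construct a multi-observer rating panel
#'
#' A rating panel is an objects x raters matrix of categorical ratings over
#' the fixed alphabet `TB` / `PDC` / `NEITHER`. Panels are complete by
#' default (every rater rates every object); `NA` entries are allowed only
#' with `allow_incomplete = TRUE`, which models designs where raters score
#' different object subsets.
#'
#' @param ratings Character matrix (objects in rows, raters in columns) with
#'   values in [rating_classes()]; row names are object ids, column names
#'   rater ids (defaults are generated when absent).
#' @param rater_groups Optional vector (length = number of raters) assigning
#'   each rater to a group label.
#' @param allow_incomplete Permit `NA` entries.
#'
#' @return Object of class `rating_panel`: list with `ratings`,
#'   `object_ids`, `rater_ids`, `rater_groups`.
#' @export
rating_panel <- function(ratings, rater_groups = NULL,
                         allow_incomplete = FALSE) {
  stopifnot(is.matrix(ratings))
  ratings <- structure(as.character(ratings), dim = dim(ratings),
                       dimnames = dimnames(ratings))
  bad <- !(ratings %in% RATING_CLASSES) & !is.na(ratings)
  if (any(bad)) {
    stop("invalid rating token(s): ",
         paste(sQuote(unique(ratings[bad])), collapse = ", "),
         "; allowed: ", paste(RATING_CLASSES, collapse = ", "))
  }
  if (!allow_incomplete && anyNA(ratings)) {
    stop("panel is incomplete (NA ratings present); ",
         "use allow_incomplete = TRUE for partial designs")
  }
  if (is.null(rownames(ratings))) {
    rownames(ratings) <- sprintf("obj%04d", seq_len(nrow(ratings)))
  }
  if (is.null(colnames(ratings))) {
    colnames(ratings) <- sprintf("rater%02d", seq_len(ncol(ratings)))
  }
  if (anyDuplicated(rownames(ratings))) stop("duplicate object ids")
  if (anyDuplicated(colnames(ratings))) stop("duplicate rater ids")
  if (!is.null(rater_groups)) {
    stopifnot(length(rater_groups) == ncol(ratings))
    rater_groups <- setNames(as.character(rater_groups), colnames(ratings))
  }
  structure(list(ratings = ratings,
                 object_ids = rownames(ratings),
                 rater_ids = colnames(ratings),
                 rater_groups = rater_groups),
            class = "rating_panel")
}

#' @export
print.rating_panel <- function(x, ...) {
  cat("rating panel:", nrow(x$ratings), "objects x", ncol(x$ratings),
      "raters\n")
  if (anyNA(x$ratings)) cat("  (incomplete: contains NA ratings)\n")
  if (!is.null(x$rater_groups)) {
    cat("  rater groups:", paste(unique(x$rater_groups), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Specify a simulated rater panel
#'
#' Latent true classes are drawn per object from `class_prevalence`; each
#' rater then reports conditionally on the latent class through their own
#' row-stochastic confusion matrix (row = latent class, column = reported
#' class). Identity confusions give perfectly reliable raters; uniform rows
#' give raters whose reports carry no information about the object.
#'
#' @param n_objects,n_raters Positive integers.
#' @param class_prevalence Probability 3-vector over (TB, PDC, NEITHER);
#'   must sum to 1 within 1e-12.
#' @param rater_confusions Either one 3x3 row-stochastic matrix shared by
#'   all raters, or a list of `n_raters` such matrices.
#' @param seed Integer seed.
#'
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(n_objects, n_raters,
                       class_prevalence = c(0.45, 0.05, 0.50),
                       rater_confusions = diag(3),
                       seed = 1L) {
  stopifnot(n_objects >= 1, n_raters >= 1,
            length(class_prevalence) == 3L, all(class_prevalence >= 0))
  if (abs(sum(class_prevalence) - 1) > 1e-12) {
    stop("class_prevalence must sum to 1")
  }
  if (is.matrix(rater_confusions)) {
    rater_confusions <- rep(list(rater_confusions), n_raters)
  }
  stopifnot(is.list(rater_confusions), length(rater_confusions) == n_raters)
  for (cm in rater_confusions) {
    stopifnot(is.matrix(cm), all(dim(cm) == c(3L, 3L)), all(cm >= 0))
    if (any(abs(rowSums(cm) - 1) > 1e-12)) {
      stop("each confusion-matrix row must sum to 1")
    }
  }
  structure(list(n_objects = as.integer(n_objects),
                 n_raters = as.integer(n_raters),
                 class_prevalence = as.numeric(class_prevalence),
                 rater_confusions = rater_confusions,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Simulate a multi-observer rating panel with known latent truth
#'
#' @param spec A [panel_spec()].
#' @param rater_groups Optional rater-group labels passed through to the
#'   panel.
#'
#' @return List with `panel` (a complete [rating_panel()]) and `truth`
#'   (character vector of latent classes, one per object). Reproducible per
#'   seed.
#' @export
generate_rating_panel <- function(spec, rater_groups = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    truth <- sample(RATING_CLASSES, spec$n_objects, replace = TRUE,
                    prob = spec$class_prevalence)
    ratings <- matrix(NA_character_, spec$n_objects, spec$n_raters)
    truth_idx <- match(truth, RATING_CLASSES)
    for (r in seq_len(spec$n_raters)) {
      cm <- spec$rater_confusions[[r]]
      for (k in 1:3) {
        sel <- truth_idx == k
        if (any(sel)) {
          ratings[sel, r] <- sample(RATING_CLASSES, sum(sel), replace = TRUE,
                                    prob = cm[k, ])
        }
      }
    }
    rownames(ratings) <- sprintf("obj%04d", seq_len(spec$n_objects))
    colnames(ratings) <- sprintf("rater%02d", seq_len(spec$n_raters))
    list(panel = rating_panel(ratings, rater_groups = rater_groups),
         truth = setNames(truth, rownames(ratings)))
  })
}

#' Build a panel realizing given per-object vote-count patterns
#'
#' Expands an objects x 3 matrix of vote counts (columns TB, PDC, NEITHER;
#' rows summing to the rater count) into a complete rating panel whose
#' per-object vote marginals equal the given counts. Rater assignment of the
#' votes is deterministic (TB votes to the first raters, then PDC, then
#' NEITHER), which is immaterial for consensus summaries.
#'
#' @param votes Integer matrix with 3 columns; each row sums to `n_raters`.
#' @param n_raters Number of raters.
#' @return A [rating_panel()].
#' @export
panel_from_vote_counts <- function(votes, n_raters) {
  votes <- as.matrix(votes)
  stopifnot(ncol(votes) == 3L, all(votes >= 0),
            all(rowSums(votes) == n_raters))
  ratings <- t(apply(votes, 1, function(v) rep(RATING_CLASSES, times = v)))
  rating_panel(ratings)
}
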