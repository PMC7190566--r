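#' Minimum number of agreeing raters under a voting fraction
#'
#' Smallest integer `t` with `t / n_raters >= fraction`. With the study's
#' 70%-or-more rule this gives 5 of 7 raters (IHC) and 8 of 11 (H&E).
#' Fractions of 0.5 or below are rejected: uniqueness of the winning class
#' requires a strict majority.
#'
#' @param n_raters Positive integer.
#' @param fraction Voting fraction in (0.5, 1].
#'
#' @return Integer threshold.
#' @examples
#' vote_threshold(7)   # 5
#' vote_threshold(11)  # 8
#' @export
vote_threshold <- function(n_raters, fraction = 0.7) {
  stopifnot(n_raters >= 1, n_raters == round(n_raters))
  if (fraction <= 0.5 || fraction > 1) {
    stop("fraction must lie in (0.5, 1]")
  }
  t <- as.integer(ceiling(fraction * n_raters))
  # guard against floating-point rounding in ceiling()
  while (t > 1L && (t - 1L) / n_raters >= fraction) t <- t - 1L
  if (t / n_raters < fraction) t <- t + 1L
  t
}

#' Fuse one object's votes into a consensus label
#'
#' A class whose vote count reaches the [vote_threshold()] becomes the
#' fused "gold standard" label (it is unique, by pigeonhole, for any
#' fraction > 0.5). All votes on one class gives tier `uniform`; threshold
#' reached but not unanimously gives `majority`; otherwise the object has
#' `no_agreement` and label `NONE`.
#'
#' @param votes Integer 3-vector of counts for (TB, PDC, NEITHER); must sum
#'   to `n_raters`.
#' @param n_raters Number of raters.
#' @param fraction Voting fraction.
#'
#' @return List with `label` (`"TB"`, `"PDC"`, `"NEITHER"` or `"NONE"`),
#'   `tier` (`"uniform"`, `"majority"`, `"no_agreement"`) and `votes`.
#' @export
consensus_label <- function(votes, n_raters, fraction = 0.7) {
  stopifnot(length(votes) == 3L, all(votes >= 0))
  if (sum(votes) != n_raters) {
    stop("votes must sum to n_raters (", n_raters, "), got ", sum(votes))
  }
  thr <- vote_threshold(n_raters, fraction)
  mx <- max(votes)
  if (mx == n_raters) {
    list(label = RATING_CLASSES[which.max(votes)], tier = "uniform",
         votes = as.integer(votes))
  } else if (mx >= thr) {
    list(label = RATING_CLASSES[which.max(votes)], tier = "majority",
         votes = as.integer(votes))
  } else {
    list(label = "NONE", tier = "no_agreement", votes = as.integer(votes))
  }
}

# objects x 3 vote-count matrix for a complete panel
vote_counts <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  r <- panel$ratings
  counts <- vapply(RATING_CLASSES,
                   function(cl) rowSums(r == cl, na.rm = TRUE),
                   numeric(nrow(r)))
  if (nrow(r) == 1L) counts <- matrix(counts, 1L, 3L,
                                      dimnames = list(rownames(r),
                                                      RATING_CLASSES))
  storage.mode(counts) <- "integer"
  counts
}

#' Consensus labels for every object of a panel
#'
#' @param panel A complete [rating_panel()].
#' @param fraction Voting fraction (default 0.7).
#'
#' @return Object of class `consensus_result`: data.frame with `object_id`,
#'   vote counts `n_TB`, `n_PDC`, `n_NEITHER`, `tier` and `label`;
#'   attributes `n_raters`, `threshold`, `fraction`.
#' @export
consensus_labels <- function(panel, fraction = 0.7) {
  counts <- vote_counts(panel)
  n_raters <- if (nrow(counts) == 0L) ncol(panel$ratings) else
    unique(rowSums(counts))
  if (length(n_raters) != 1L) {
    stop("panel is not complete: objects have differing rating counts")
  }
  thr <- vote_threshold(n_raters, fraction)
  mx <- apply(counts, 1, max)
  winner <- RATING_CLASSES[apply(counts, 1, which.max)]
  tier <- ifelse(mx == n_raters, "uniform",
                 ifelse(mx >= thr, "majority", "no_agreement"))
  label <- ifelse(tier == "no_agreement", "NONE", winner)
  out <- data.frame(object_id = panel$object_ids,
                    n_TB = counts[, "TB"], n_PDC = counts[, "PDC"],
                    n_NEITHER = counts[, "NEITHER"],
                    tier = tier, label = label, row.names = NULL)
  structure(out, class = c("consensus_result", "data.frame"),
            n_raters = as.integer(n_raters), threshold = thr,
            fraction = fraction)
}

#' Summarize consensus tiers and classes across a panel
#'
#' Tabulates, per class, how many objects were classified unanimously
#' (`uniform`) or by the 70%-majority rule (`majority`), plus the count of
#' objects with no agreement — the layout of the study's per-group summary
#' table. "Definite" objects are those with a uniform or majority label.
#'
#' @param panel A [rating_panel()] or a `consensus_result`.
#' @param fraction Voting fraction (used when `panel` is a rating panel).
#'
#' @return List of class `consensus_summary` with:
#'   `table` (data.frame: `tier`, `class`, `count`, `percent`),
#'   `n_objects`, `n_uniform`, `n_majority`, `n_definite`,
#'   `n_no_agreement`, `pct_uniform`, `pct_definite`.
#' @export
summarize_consensus <- function(panel, fraction = 0.7) {
  res <- if (inherits(panel, "consensus_result")) panel else
    consensus_labels(panel, fraction)
  n <- nrow(res)
  cells <- expand.grid(class = RATING_CLASSES,
                       tier = c("uniform", "majority"),
                       stringsAsFactors = FALSE)[, c("tier", "class")]
  cells$count <- mapply(function(t, cl) sum(res$tier == t & res$label == cl),
                        cells$tier, cells$class)
  cells <- rbind(cells, data.frame(tier = "no_agreement", class = NA,
                                   count = sum(res$tier == "no_agreement")))
  cells$percent <- if (n > 0) 100 * cells$count / n else 0
  structure(list(
    table = cells,
    n_objects = n,
    n_uniform = sum(res$tier == "uniform"),
    n_majority = sum(res$tier == "majority"),
    n_definite = sum(res$tier != "no_agreement"),
    n_no_agreement = sum(res$tier == "no_agreement"),
    pct_uniform = if (n > 0) 100 * sum(res$tier == "uniform") / n else 0,
    pct_definite = if (n > 0) 100 * sum(res$tier != "no_agreement") / n else 0
  ), class = "consensus_summary")
}

#' @export
print.consensus_summary <- function(x, ...) {
  g <- function(t, cl) x$table$count[x$table$tier == t &
                                       (!is.na(x$table$class) &
                                          x$table$class == cl)]
  cat(sprintf("%d objects\n", x$n_objects))
  cat("             Bud    PDC    Neither\n")
  cat(sprintf("Uniform     %5d  %5d  %5d\n",
              g("uniform", "TB"), g("uniform", "PDC"),
              g("uniform", "NEITHER")))
  cat(sprintf("70%% majority%5d  %5d  %5d\n",
              g("majority", "TB"), g("majority", "PDC"),
              g("majority", "NEITHER")))
  cat(sprintf("No agreement%5d   (%.2f%%)\n", x$n_no_agreement,
              100 - x$pct_definite))
  invisible(x)
}

#' Per-rater class counts with group means and standard deviations
#'
#' For each rater, the number of objects they assigned to each class; per
#' rater group, the mean and standard deviation of those counts (sample sd
#' by default, population sd optionally). A group with a single rater has
#' no sample sd; it is reported as 0 and flagged.
#'
#' @param panel A [rating_panel()]; rater groups are taken from its
#'   `rater_groups` (all raters form one group when absent).
#' @param sd_type `"sample"` (n-1 denominator) or `"population"`.
#'
#' @return List with `per_rater` (data.frame: `rater_id`, `group`, `n_TB`,
#'   `n_PDC`, `n_NEITHER`) and `per_group` (data.frame: `group`, `class`,
#'   `mean`, `sd`, `n_raters`, `sd_degenerate`).
#' @export
per_rater_counts <- function(panel, sd_type = c("sample", "population")) {
  stopifnot(inherits(panel, "rating_panel"))
  sd_type <- match.arg(sd_type)
  groups <- panel$rater_groups
  if (is.null(groups)) {
    groups <- setNames(rep("all", length(panel$rater_ids)), panel$rater_ids)
  }
  per_rater <- data.frame(
    rater_id = panel$rater_ids,
    group = unname(groups[panel$rater_ids]),
    n_TB = as.integer(colSums(panel$ratings == "TB", na.rm = TRUE)),
    n_PDC = as.integer(colSums(panel$ratings == "PDC", na.rm = TRUE)),
    n_NEITHER = as.integer(colSums(panel$ratings == "NEITHER",
                                   na.rm = TRUE)),
    row.names = NULL)
  rows <- list()
  for (g in unique(per_rater$group)) {
    sub <- per_rater[per_rater$group == g, ]
    for (cl in RATING_CLASSES) {
      v <- sub[[paste0("n_", cl)]]
      s <- if (length(v) < 2L) 0 else if (sd_type == "sample") sd(v) else
        sqrt(mean((v - mean(v))^2))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, class = cl, mean = mean(v), sd = s,
        n_raters = length(v), sd_degenerate = length(v) < 2L)
    }
  }
  list(per_rater = per_rater, per_group = do.call(rbind, rows))
}
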