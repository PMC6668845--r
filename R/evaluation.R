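#' Discrete Fréchet distance between two curves
#'
#' The minimax coupling distance between two ordered point sequences,
#' computed with the Eiter-Mannila dynamic programme:
#' `ca(i, j) = max(d(a_i, b_j), min(ca(i-1, j), ca(i-1, j-1), ca(i, j-1)))`.
#' It respects point ordering (unlike the Hausdorff distance), is
#' symmetric, zero iff the curves are pointwise equal, and bounded below by
#' the distance between either pair of endpoints. Curves of different
#' lengths are allowed; no resampling is applied (an optional subsampling
#' `stride` is exposed for long curves).
#'
#' @param a,b Point sequences: n x 2 matrices or [trajectory()] objects.
#' @param stride Keep every `stride`-th point (default 1 = all points).
#' @return A list of class `frechet_dist` with `value` (meters) and the
#'   curve sizes `m`, `n`.
#' @examples
#' discrete_frechet(rbind(c(0, 0), c(1, 0)), rbind(c(0, 1), c(1, 1)))$value
#' @export
discrete_frechet <- function(a, b, stride = 1) {
  A <- if (inherits(a, "trajectory")) a$points else as.matrix(a)
  B <- if (inherits(b, "trajectory")) b$points else as.matrix(b)
  if (!nrow(A) || !nrow(B)) stop("empty curve")
  if (stride > 1) {
    A <- A[seq(1, nrow(A), by = stride), , drop = FALSE]
    B <- B[seq(1, nrow(B), by = stride), , drop = FALSE]
  }
  structure(list(value = cpp_frechet(A, B), m = nrow(A), n = nrow(B)),
            class = "frechet_dist")
}

#' @export
print.frechet_dist <- function(x, ...) {
  cat(sprintf("discrete Frechet distance: %.4f (curves %d / %d points)\n",
              x$value, x$m, x$n))
  invisible(x)
}

#' Batch score: mean plus standard deviation
#'
#' The summary used for a batch of coherent measurements:
#' `score(X) = mu(X) + sigma(X)` with the population convention for the
#' standard deviation (divide by n). A batch is good when both its mean
#' and its spread are low; unlike a Z-score this does not penalize low
#' standard deviations.
#'
#' @param x Numeric sample (length >= 1).
#' @return `mean(x) + sd_pop(x)`.
#' @examples
#' score(c(0, 2))  # 1 + 1 = 2
#' @export
score <- function(x) {
  if (!length(x)) stop("empty sample")
  mean(x) + sqrt(mean((x - mean(x))^2))
}

#' Compare groups of trajectory distances
#'
#' Kruskal-Wallis rank test across named groups of distance samples, with
#' the per-group [score()] summary.
#'
#' @param samples Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @param method Only `"kruskal_wallis"` is implemented.
#' @return An object of class `group_comparison`: list with `table` (one
#'   row per group: n, mean, sd, median, score), `statistic`, `p_value`,
#'   `method`.
#' @export
compare_groups <- function(samples, method = "kruskal_wallis") {
  method <- match.arg(method)
  if (length(samples) < 2) stop("need at least two groups")
  if (any(lengths(samples) < 2)) stop("each group needs at least two values")
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("groups must be named")
  values <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(names(samples), lengths(samples)),
                levels = names(samples))
  kw <- stats::kruskal.test(values, grp)
  tab <- data.frame(
    group = names(samples),
    n = lengths(samples),
    mean = vapply(samples, mean, numeric(1)),
    sd = vapply(samples, stats::sd, numeric(1)),
    median = vapply(samples, stats::median, numeric(1)),
    score = vapply(samples, score, numeric(1)),
    row.names = NULL)
  structure(list(table = tab, statistic = unname(kw$statistic),
                 p_value = kw$p.value, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, p = %.3g\n",
              x$statistic, x$p_value))
  print(x$table, digits = 4)
  invisible(x)
}

#' Write a group comparison to a delimited text file
#'
#' One row per group with columns group, n, mean, std, score, statistic, p.
#'
#' @param cmp A [compare_groups()] result.
#' @param path Output file path.
#' @export
write_comparison <- function(cmp, path) {
  out <- cmp$table[, c("group", "n", "mean", "sd", "score")]
  names(out)[4] <- "std"
  out$statistic <- cmp$statistic
  out$p <- cmp$p_value
  utils::write.csv(out, path, row.names = FALSE)
}

#' Reservoir state-space overlap
#'
#' Quantifies how much a set of snippet-driven reservoir state trajectories
#' overlaps the state trajectory of the complete sequence, in the
#' visualization space of the analysis: the top-2 principal components
#' fitted to the full-sequence states. The first `transient` steps of each
#' snippet trace are discarded (states still relaxing from the random
#' reset), then the overlap is the fraction of the remaining snippet states
#' whose nearest full-sequence state lies within `radius` in the projected
#' plane.
#'
#' `direction = "coverage"` measures the converse: the fraction of
#' full-sequence states approached within `radius` by some snippet state.
#' This is the quantity that grows as more snippets are replayed and the
#' state trajectory of the intact sequence fills in.
#'
#' @param snippet_states List of state matrices (see [collect_states()]).
#' @param full_states State matrix of the complete sequence.
#' @param transient Steps to drop at the start of each snippet. Default 3.
#' @param radius Overlap radius in the projected plane. Default 5% of the
#'   diagonal of the projected full-trajectory bounding box.
#' @param direction `"snippet"` (fraction of snippet states near the full
#'   trajectory, the default) or `"coverage"` (fraction of full states
#'   covered by snippet states).
#' @return Overlap fraction in \[0, 1\].
#' @export
state_overlap <- function(snippet_states, full_states, transient = 3,
                          radius = NULL,
                          direction = c("snippet", "coverage")) {
  direction <- match.arg(direction)
  if (!length(snippet_states) || !nrow(full_states)) stop("empty inputs")
  stopifnot(transient >= 0)
  pca <- stats::prcomp(full_states, center = TRUE, rank. = 2)
  full2 <- pca$x[, 1:2, drop = FALSE]
  trimmed <- if (transient == 0) snippet_states
             else lapply(snippet_states, function(m)
               if (nrow(m) > transient) m[-seq_len(transient), , drop = FALSE]
               else m[0, , drop = FALSE])
  snip <- do.call(rbind, trimmed)
  if (!nrow(snip)) stop("no snippet states left after transient removal")
  snip2 <- scale(snip, center = pca$center, scale = FALSE) %*%
    pca$rotation[, 1:2]
  if (is.null(radius)) {
    bbox <- apply(full2, 2, range)
    radius <- 0.05 * sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  }
  d2 <- outer(snip2[, 1], full2[, 1], "-")^2 +
    outer(snip2[, 2], full2[, 2], "-")^2
  if (direction == "snippet") {
    mean(sqrt(apply(d2, 1, min)) <= radius)
  } else {
    mean(sqrt(apply(d2, 2, min)) <= radius)
  }
}
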