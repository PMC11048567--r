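#' Sorensen similarity between two presence sets
#'
#' CC = 2a / (2a + b + c), where a is the number of shared species and b, c
#' the numbers unique to each set. Equals 1 only for identical sets and 0
#' for disjoint ones; values near 0.5 are a conventional rule-of-thumb
#' cutoff for "moderate" compositional similarity.
#'
#' @param presence_a,presence_b Character vectors of species names.
#' @return Similarity coefficient in [0, 1].
#' @examples
#' sorensen(c("x", "y", "z", "u", "v"), c("x", "y", "z", "w")) # 6/9
#' @export
sorensen <- function(presence_a, presence_b) {
  a <- unique(presence_a); b <- unique(presence_b)
  if (length(a) == 0L && length(b) == 0L)
    stop("Sorensen similarity undefined for two empty sets")
  shared <- length(intersect(a, b))
  2 * shared / (length(a) + length(b))
}

#' Group-pairwise Sorensen similarity matrix
#'
#' Pools each gradient group's presence set (the union over the group's
#' plots of species with cover > 0) and computes Sorensen similarity for
#' every group pair.
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param per_transect If \code{TRUE}, presence sets are built per transect
#'   and the group pair's coefficient is averaged over transects; the
#'   default pools across all transects.
#' @return Object of class \code{similarity_matrix}: a symmetric 5 x 5
#'   matrix with unit diagonal, rows/columns A-E.
#' @export
group_sorensen_matrix <- function(dataset, per_transect = FALSE) {
  stopifnot(inherits(dataset, "study_dataset"))
  groups <- c("A", "B", "C", "D", "E")
  presence_of <- function(ids) {
    cov <- dataset$cover[ids, , drop = FALSE]
    colnames(cov)[colSums(cov) > 0]
  }
  m <- diag(1, 5)
  dimnames(m) <- list(groups, groups)
  if (!per_transect) {
    sets <- lapply(groups, function(g) {
      ids <- dataset$plots$plot_id[dataset$plots$group == g]
      s <- presence_of(ids)
      if (length(s) == 0L) stop("group ", g, " has no species present")
      s
    })
    for (i in 1:4) for (j in (i + 1):5)
      m[i, j] <- m[j, i] <- sorensen(sets[[i]], sets[[j]])
  } else {
    trs <- unique(dataset$plots$transect_id)
    for (i in 1:4) for (j in (i + 1):5) {
      vals <- vapply(trs, function(tr) {
        pi <- dataset$plots$plot_id[dataset$plots$transect_id == tr &
                                      dataset$plots$group == groups[i]]
        pj <- dataset$plots$plot_id[dataset$plots$transect_id == tr &
                                      dataset$plots$group == groups[j]]
        sorensen(presence_of(pi), presence_of(pj))
      }, numeric(1))
      m[i, j] <- m[j, i] <- mean(vals)
    }
  }
  structure(m, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, digits = 2, ...) {
  cat("Pairwise Sorensen similarity (upper triangle)\n")
  y <- format(round(unclass(x), digits))
  y[lower.tri(y, diag = TRUE)] <- ""
  print(y, quote = FALSE)
  invisible(x)
}

#' Plot-by-plot dissimilarity matrix
#'
#' Default metric is 1 - Sorensen on plot presence sets (binary); the
#' quantitative alternative is the cover-weighted Bray-Curtis distance.
#' Plots with an empty community are dropped with a warning.
#'
#' @param dataset A \code{\link{study_dataset}} or a plot-by-species matrix.
#' @param plots Optional plot ids (for a \code{study_dataset} input).
#' @param metric \code{"sorensen"} (default) or \code{"bray"}.
#' @return A \code{dist} object over the retained plots.
#' @export
dissimilarity_matrix <- function(dataset, plots = NULL,
                                 metric = c("sorensen", "bray")) {
  metric <- match.arg(metric)
  cov <- if (inherits(dataset, "study_dataset"))
    subset_cover(dataset, plots) else as.matrix(dataset)
  empty <- rowSums(cov) == 0
  if (any(empty)) {
    warning("dropping plot(s) with empty community: ",
            paste(rownames(cov)[empty], collapse = ", "))
    cov <- cov[!empty, , drop = FALSE]
  }
  n <- nrow(cov)
  if (n < 2L) stop("need at least two non-empty plots")
  d <- matrix(0, n, n, dimnames = list(rownames(cov), rownames(cov)))
  if (metric == "sorensen") {
    occ <- cov > 0
    shared <- tcrossprod(occ * 1)
    sizes <- rowSums(occ)
    d <- 1 - 2 * shared / outer(sizes, sizes, `+`)
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(abs(cov[i, ] - cov[j, ])) /
        sum(cov[i, ] + cov[j, ])
    }
  }
  stats::as.dist(d)
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. All pairwise dissimilarities are
#' ranked (average ranks for ties) and
#' R = (mean between-group rank - mean within-group rank) / (M / 2),
#' with M the number of pairs; R is 1 when every between-group pair is more
#' dissimilar than every within-group pair and near 0 under no structure.
#' Significance is one-sided via random relabellings preserving group sizes,
#' with the add-one estimator p = (1 + #{R* >= R}) / (1 + permutations).
#'
#' @param dissim A \code{dist} or symmetric matrix of plot dissimilarities.
#' @param grouping Factor or character vector of group labels, one per plot.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Optional seed; identical seeds give identical p-values.
#' @return Object of class \code{anosim_test}: list with
#'   \code{r_statistic}, \code{p_value}, \code{n_permutations},
#'   \code{perm_stats} and \code{group_rank_summary} (per-group and
#'   "Between" boxplot five-number summaries of the dissimilarity ranks,
#'   whiskers at 1.5 IQR, outliers beyond).
#' @examples
#' ds <- generate_study(generator_config(n_transects = 4, seed = 2))
#' a <- anosim_test(dissimilarity_matrix(ds), ds$plots$group,
#'                  n_permutations = 99, seed = 1)
#' a$r_statistic
#' @export
anosim_test <- function(dissim, grouping, n_permutations = 1000, seed = NULL) {
  d <- stats::as.dist(dissim)
  n <- attr(d, "Size")
  grouping <- as.character(grouping)
  if (length(grouping) != n)
    stop("'grouping' must have one label per plot (", n, ")")
  tab <- table(grouping)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L))
    stop("every group needs at least two plots; too small: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (n_permutations < 1) stop("'n_permutations' must be at least 1")

  r <- rank(as.vector(d))          # average ranks for ties
  M <- length(r)
  pair_i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  pair_j <- sequence((n - 1L):1L) + pair_i
  stat_for <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  r_obs <- stat_for(grouping)

  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(b) stat_for(sample(grouping)), numeric(1))
  p <- (1 + sum(perm >= r_obs)) / (1 + n_permutations)

  within_obs <- grouping[pair_i] == grouping[pair_j]
  summaries <- c(
    list(Between = boxplot_summary(r[!within_obs])),
    lapply(stats::setNames(nm = sort(names(tab))), function(g)
      boxplot_summary(r[within_obs & grouping[pair_i] == g]))
  )
  structure(
    list(r_statistic = r_obs, p_value = p, n_permutations = n_permutations,
         perm_stats = perm, group_rank_summary = summaries,
         ranks = r, within = within_obs, grouping = grouping,
         pair_groups = ifelse(within_obs, grouping[pair_i], "Between")),
    class = "anosim_test"
  )
}

boxplot_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- x >= lo & x <= hi
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = if (any(inside)) min(x[inside]) else NA_real_,
       whisker_high = if (any(inside)) max(x[inside]) else NA_real_,
       outliers = sort(x[!inside]))
}

#' @export
print.anosim_test <- function(x, ...) {
  cat("Analysis of similarity (ANOSIM)\n")
  cat(sprintf("  R = %.4f, permutation p = %.4g (%d permutations, one-sided)\n",
              x$r_statistic, x$p_value, x$n_permutations))
  med <- vapply(x$group_rank_summary, `[[`, numeric(1), "median")
  cat("  median dissimilarity rank by class:\n")
  print(round(med, 1))
  invisible(x)
}

#' @export
plot.anosim_test <- function(x, ...) {
  grp <- factor(x$pair_groups,
                levels = c("Between", sort(unique(x$grouping))))
  graphics::boxplot(x$ranks ~ grp, varwidth = TRUE, notch = TRUE,
                    xlab = "", ylab = "dissimilarity rank", ...)
  invisible(x)
}
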