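#' Relative abundance of species over a set of plots
#'
#' Sums each species' mean cover over the chosen plots and normalises by the
#' community total, yielding a relative-abundance vector (proportions
#' summing to 1).
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param plots Optional character vector of plot ids (default: all plots).
#' @return Named numeric vector of proportions over the species with
#'   non-zero cover.
#' @examples
#' ds <- generate_study(generator_config(n_transects = 3))
#' sum(relative_abundance(ds)) # 1
#' @export
relative_abundance <- function(dataset, plots = NULL) {
  cov <- subset_cover(dataset, plots)
  tot <- colSums(cov)
  s <- sum(tot)
  if (s <= 0) stop("community has no cover; relative abundance undefined")
  p <- tot[tot > 0] / s
  p
}

subset_cover <- function(dataset, plots = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  cov <- dataset$cover
  if (!is.null(plots)) {
    bad <- setdiff(plots, rownames(cov))
    if (length(bad)) stop("unknown plot id(s): ", paste(bad, collapse = ", "))
    cov <- cov[plots, , drop = FALSE]
  }
  if (nrow(cov) == 0L) stop("empty plot set")
  cov
}

native_species_of <- function(dataset) {
  sp <- dataset$species
  sp$species[isTRUE_vec(sp$native) & !sp$species %in% dataset$target_invader]
}

#' Mean native species richness per plot
#'
#' Counts, in each plot, the native species present (mean cover > 0),
#' excluding the target invader and all non-natives, and averages the count
#' over the plot set.
#'
#' @inheritParams relative_abundance
#' @return Mean native species per plot (non-negative real).
#' @export
mean_native_richness <- function(dataset, plots = NULL) {
  cov <- subset_cover(dataset, plots)
  nat <- intersect(colnames(cov), native_species_of(dataset))
  mean(rowSums(cov[, nat, drop = FALSE] > 0))
}

#' Floristic quality index
#'
#' FQI = mean coefficient of conservatism times the square root of species
#' richness, computed over the species pooled across the plot set. By
#' default only native species qualify; species without an assigned C-value
#' are excluded from both the mean and the richness term (and reported via
#' a message).
#'
#' @inheritParams relative_abundance
#' @param native_only If \code{TRUE} (default) restrict to native species.
#' @return The FQI score (dimensionless, >= 0); 0 with a warning when no
#'   species qualifies.
#' @examples
#' # four natives all with C = 4: FQI = 4 * sqrt(4) = 8
#' @export
fqi <- function(dataset, plots = NULL, native_only = TRUE) {
  cov <- subset_cover(dataset, plots)
  present <- colnames(cov)[colSums(cov) > 0]
  if (native_only) present <- intersect(present, native_species_of(dataset))
  attrs <- dataset$species[match(present, dataset$species$species), ]
  no_c <- present[is.na(attrs$c_value)]
  if (length(no_c))
    message("excluding ", length(no_c), " species without C-values from FQI: ",
            paste(no_c, collapse = ", "))
  cvals <- attrs$c_value[!is.na(attrs$c_value)]
  if (length(cvals) == 0L) {
    warning("no species with C-values in plot set; FQI = 0")
    return(0)
  }
  mean(cvals) * sqrt(length(cvals))
}

#' Dominant species by the 50/20 rule
#'
#' Orders species by descending relative abundance and returns the minimal
#' leading set whose cumulative abundance reaches 50 percent, together with
#' every species whose individual abundance is at least 20 percent. Ties are
#' broken by descending abundance then species name, so the result is
#' deterministic.
#'
#' @param abund Named numeric relative-abundance vector (proportions
#'   summing to 1), e.g. from \code{\link{relative_abundance}}.
#' @return Character vector of dominant species, most abundant first.
#' @examples
#' dominants_50_20(c(a = 0.40, b = 0.25, c = 0.20, d = 0.15)) # a b c
#' @export
dominants_50_20 <- function(abund) {
  check_abundance(abund)
  ord <- order(-abund, names(abund))
  p <- abund[ord]
  k <- which(cumsum(p) >= 0.5 - 1e-12)[1L]
  sel <- seq_along(p) <= k | p >= 0.2 - 1e-12
  names(p)[sel]
}

check_abundance <- function(abund) {
  if (length(abund) == 0L || is.null(names(abund)))
    stop("'abund' must be a non-empty named abundance vector")
  if (any(abund < 0)) stop("abundances must be non-negative")
  if (abs(sum(abund) - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", format(sum(abund)), ")")
  invisible(abund)
}

#' Renyi diversity profile
#'
#' Evaluates the Renyi entropy H_alpha of a relative-abundance vector over a
#' sweep of scale values, unifying species richness (alpha = 0, H = log S),
#' Shannon diversity (alpha = 1), Simpson diversity (alpha = 2) and
#' dominance/evenness (alpha = Inf, H = -log max p) on one ordering scale.
#' The alpha = 1 and alpha = Inf values use the closed-form limits. Values
#' are in natural-log units and are non-increasing in alpha; the profile is
#' flat exactly for a perfectly even community.
#'
#' @param abund Named numeric relative-abundance vector (proportions summing
#'   to 1); zero entries are dropped.
#' @param alphas Non-negative scale values; \code{Inf} allowed.
#' @return Object of class \code{renyi_profile}: data frame with columns
#'   \code{alpha} and \code{value}.
#' @examples
#' renyi_profile(c(a = 0.5, b = 0.5), alphas = c(0, 1, 2, Inf))
#' @export
renyi_profile <- function(abund,
                          alphas = c(0, 0.25, 0.5, 1, 2, 4, 8, Inf)) {
  check_abundance(abund)
  if (any(alphas < 0)) stop("'alphas' must be non-negative")
  p <- abund[abund > 0]
  vals <- vapply(alphas, function(a) {
    if (a == 0) log(length(p))
    else if (a == 1) -sum(p * log(p))
    else if (is.infinite(a)) -log(max(p))
    else log(sum(p^a)) / (1 - a)
  }, numeric(1))
  structure(data.frame(alpha = alphas, value = vals),
            class = c("renyi_profile", "data.frame"))
}

#' @export
plot.renyi_profile <- function(x, ...) {
  xx <- x$alpha
  lab <- format(xx)
  xx[is.infinite(xx)] <- max(xx[is.finite(xx)]) * 1.3
  graphics::plot(xx, x$value, type = "b", xaxt = "n", xlab = "alpha",
                 ylab = expression(H[alpha]), ...)
  graphics::axis(1, at = xx, labels = lab)
  invisible(x)
}

#' Species accumulation curve
#'
#' Expected species richness as plots accumulate. The \code{exact} method
#' returns the analytic mean over all equally likely plot subsets of each
#' size (the hypergeometric occupancy form), with the matching analytic
#' standard deviation; the \code{permutation} method averages cumulative
#' richness over random plot orderings (default 1000, seeded).
#'
#' @param dataset A \code{\link{study_dataset}} or a plot-by-species cover
#'   (or presence) matrix.
#' @param plots Optional plot ids (for a \code{study_dataset} input).
#' @param method \code{"exact"} (default) or \code{"permutation"}.
#' @param n_perm Number of random orderings for the permutation method.
#' @param seed Optional seed for the permutation method.
#' @return Object of class \code{accumulation_curve}: data frame with
#'   columns \code{n_plots}, \code{richness} and \code{sd}. The terminal
#'   value equals the total observed richness.
#' @export
species_accumulation <- function(dataset, plots = NULL,
                                 method = c("exact", "permutation"),
                                 n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  cov <- if (inherits(dataset, "study_dataset"))
    subset_cover(dataset, plots) else as.matrix(dataset)
  occ <- cov > 0
  occ <- occ[, colSums(occ) > 0, drop = FALSE]
  n <- nrow(occ)
  if (n < 1L) stop("need at least one plot")
  ni <- colSums(occ)
  if (method == "exact") {
    rich <- sdv <- numeric(n)
    # P(species i absent from a random size-k subset) = C(n-ni, k)/C(n, k)
    labs_q <- function(m, k) ifelse(m >= k, exp(lchoose(m, k) - lchoose(n, k)), 0)
    # plots occupied by either of a species pair, for the joint-absence term
    both <- crossprod(occ * 1)
    either <- outer(ni, ni, `+`) - both
    for (k in seq_len(n)) {
      qi <- labs_q(n - ni, k)
      rich[k] <- sum(1 - qi)
      qij <- labs_q(n - either, k)
      pij <- 1 - outer(qi, qi, `+`) + qij  # P(both present); diagonal = pi
      pi <- 1 - qi
      v <- sum(pij - outer(pi, pi))        # Var(S_k), diagonal gives pi*qi
      sdv[k] <- sqrt(max(v, 0))
    }
  } else {
    if (n_perm < 1) stop("'n_perm' must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    acc <- matrix(0, n_perm, n)
    for (b in seq_len(n_perm)) {
      ord <- sample.int(n)
      seen <- apply(occ[ord, , drop = FALSE], 2, cummax)
      if (n == 1L) seen <- matrix(seen, nrow = 1L)
      acc[b, ] <- rowSums(seen)
    }
    rich <- colMeans(acc)
    sdv <- apply(acc, 2, stats::sd)
  }
  structure(data.frame(n_plots = seq_len(n), richness = rich, sd = sdv),
            class = c("accumulation_curve", "data.frame"))
}

#' @export
plot.accumulation_curve <- function(x, ...) {
  graphics::plot(x$n_plots, x$richness, type = "l", xlab = "plots",
                 ylab = "expected species richness", ...)
  graphics::lines(x$n_plots, x$richness + x$sd, lty = 3)
  graphics::lines(x$n_plots, pmax(x$richness - x$sd, 0), lty = 3)
  invisible(x)
}

#' Per-group gradient summary
#'
#' Tabulates, for each gradient group A-E: plot count, mean native species
#' richness, floristic quality index (species pooled across the group's
#' plots) and mean invader relative abundance (computed per plot -- invader
#' cover over the plot's total cover -- then averaged; set
#' \code{pooled = TRUE} to divide summed invader cover by summed total
#' cover instead).
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param pooled Use the pooled-ratio variant of group invader abundance.
#' @return Data frame with one row per group.
#' @export
group_summary <- function(dataset, pooled = FALSE) {
  stopifnot(inherits(dataset, "study_dataset"))
  groups <- c("A", "B", "C", "D", "E")
  out <- lapply(groups, function(g) {
    ids <- dataset$plots$plot_id[dataset$plots$group == g]
    inv <- if (pooled) {
      cov <- subset_cover(dataset, ids)
      ti <- intersect(dataset$target_invader, colnames(cov))
      100 * sum(cov[, ti, drop = FALSE]) / sum(cov)
    } else {
      mean(invader_abundance(dataset, ids))
    }
    data.frame(group = g, n_plots = length(ids),
               mean_native_richness = mean_native_richness(dataset, ids),
               fqi = suppressMessages(fqi(dataset, ids)),
               invader_relabund = inv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-plot invader relative abundance
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param plots Optional plot ids.
#' @param invaders Invader taxa to cumulate (default: the dataset's target
#'   invader set).
#' @return Named numeric vector, percent in [0, 100]: summed invader cover
#'   over the plot's total cover, 0 where the invader is absent.
#' @export
invader_abundance <- function(dataset, plots = NULL, invaders = NULL) {
  cov <- subset_cover(dataset, plots)
  if (is.null(invaders)) invaders <- dataset$target_invader
  bad <- setdiff(invaders, dataset$species$species)
  if (length(bad)) stop("unknown invader name(s): ", paste(bad, collapse = ", "))
  ti <- intersect(invaders, colnames(cov))
  tot <- rowSums(cov)
  if (any(tot <= 0)) stop("plot(s) with zero total cover: ",
                          paste(rownames(cov)[tot <= 0], collapse = ", "))
  inv <- if (length(ti)) rowSums(cov[, ti, drop = FALSE]) else 0
  100 * inv / tot
}
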