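#' Configuration for the synthetic-community generator
#'
#' Defines the statistical structure of a simulated invasion-gradient study:
#' five plots per transect spanning group-level target invader relative
#' abundances from completely invaded (A, above 20 percent) to uninvaded
#' (E, below 5 percent), a unimodal ("hump-shaped") expected native richness
#' curve peaking at moderate invasion, a rank-lognormal species pool, and
#' noise terms for within-group abundance, subplot cover heterogeneity and
#' plot richness counts.
#'
#' The default group means (60, 26, 7, 1, 0 percent) sit inside the ranges
#' observed across invaders in comparable field studies, and the default
#' richness curve peaks at 10 percent invader relative abundance with an
#' expected 12 native species per plot there, so the downstream threshold
#' detector has a known truth to recover.
#'
#' @param n_transects Number of transects (>= 2); each contributes 5 plots.
#' @param group_invader_mean Named numeric: target invader relative abundance
#'   (percent) per group A-E, non-increasing, with A > 20 and E < 5.
#' @param peak_abundance Invader relative abundance (percent) at which
#'   expected native richness is maximal.
#' @param peak_richness Expected native species per plot at the peak.
#' @param richness_shift,richness_width Shape parameters of the lognormal
#'   richness curve (horizontal shift in percent and log-scale width); the
#'   shift keeps expected richness at zero invasion close to, but below, the
#'   peak, as uninvaded plots are species-rich but not maximal.
#' @param pool_native,pool_exotic Sizes of the native and non-target exotic
#'   species pools.
#' @param native_budget Total absolute native cover (percent, summed over
#'   species) around which plot covers are scaled before discretization.
#' @param exotic_rate Mean number of incidental non-target exotic species
#'   per plot (Poisson).
#' @param abundance_sd_frac,abundance_sd_min Within-group SD of the plot
#'   invader abundance draw, as a fraction of the group mean and as a floor
#'   (percentage points).
#' @param cover_sdlog Log-scale SD of the multiplicative lognormal noise
#'   applied to species covers within each subplot before cover-class
#'   discretization.
#' @param invader_name Name of the target invader taxon in the pool.
#' @param seed Integer seed; drives a per-transect stream so that transect k
#'   is identical whatever the total transect count.
#' @return An object of class \code{generator_config} (a list).
#' @seealso [generate_study()], [expected_richness()]
#' @export
generator_config <- function(n_transects = 12,
                             group_invader_mean = c(A = 60, B = 26, C = 7,
                                                    D = 1, E = 0),
                             peak_abundance = 10,
                             peak_richness = 12,
                             richness_shift = 10,
                             richness_width = 1.2,
                             pool_native = 80,
                             pool_exotic = 15,
                             native_budget = 60,
                             exotic_rate = 0.6,
                             abundance_sd_frac = 0.25,
                             abundance_sd_min = 0.5,
                             cover_sdlog = 0.35,
                             invader_name = "target_invader",
                             seed = 1L) {
  gm <- group_invader_mean
  if (!all(c("A", "B", "C", "D", "E") %in% names(gm)))
    stop("'group_invader_mean' must name groups A-E")
  gm <- gm[c("A", "B", "C", "D", "E")]
  if (any(diff(gm) > 0))
    stop("group invader means must be non-increasing from A to E")
  if (gm["A"] <= 20)
    stop("group A must be completely invaded (mean relative abundance > 20)")
  if (gm["E"] >= 5)
    stop("group E must be uninvaded (mean relative abundance < 5)")
  if (n_transects < 2) stop("'n_transects' must be at least 2")
  if (peak_abundance <= 0 || peak_abundance >= 100)
    stop("'peak_abundance' must lie strictly inside (0, 100)")
  if (peak_richness <= 0) stop("'peak_richness' must be positive")
  stopifnot(pool_native >= 1, richness_width > 0, richness_shift > 0,
            cover_sdlog >= 0, abundance_sd_frac >= 0, abundance_sd_min >= 0)
  structure(
    list(n_transects = as.integer(n_transects), group_invader_mean = gm,
         peak_abundance = peak_abundance, peak_richness = peak_richness,
         richness_shift = richness_shift, richness_width = richness_width,
         pool_native = as.integer(pool_native),
         pool_exotic = as.integer(pool_exotic),
         native_budget = native_budget, exotic_rate = exotic_rate,
         abundance_sd_frac = abundance_sd_frac,
         abundance_sd_min = abundance_sd_min,
         cover_sdlog = cover_sdlog, invader_name = invader_name,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Expected native richness along the invasion gradient
#'
#' Unimodal curve relating invader relative abundance to the expected count
#' of native species per plot: a shifted-lognormal bump with its maximum at
#' \code{cfg$peak_abundance} and height \code{cfg$peak_richness}. At zero
#' invasion it evaluates below the peak (uninvaded plots are rich but not
#' maximal) and it declines towards heavy invasion.
#'
#' @param invader_relabund Invader relative abundance, percent in [0, 100].
#' @param cfg A \code{\link{generator_config}}.
#' @return Expected native species count (positive real), vectorised.
#' @examples
#' cfg <- generator_config()
#' expected_richness(cfg$peak_abundance, cfg) # the configured peak height
#' @export
expected_richness <- function(invader_relabund, cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  x <- invader_relabund
  if (any(x < 0 | x > 100)) stop("invader relative abundance must be in [0, 100]")
  s <- cfg$richness_shift
  z <- log((x + s) / (cfg$peak_abundance + s))
  cfg$peak_richness * exp(-z^2 / (2 * cfg$richness_width^2))
}

# deterministic per-transect seed so transect k is reproducible independently
# of how many transects are generated (splittable stream)
transect_seed <- function(seed, k) {
  (as.double(seed) * 10007 + as.double(k) * 7919 + 12345) %% 2147483629
}

# rank-lognormal species-abundance weights for the native pool
pool_weights <- function(n, sigma = 1) {
  exp(-sigma * stats::qnorm(seq_len(n) / (n + 1)))
}

# species pool and attributes table; deterministic given cfg
species_pool <- function(cfg) {
  set.seed(transect_seed(cfg$seed, 0))
  natives <- sprintf("native_sp_%03d", seq_len(cfg$pool_native))
  exotics <- if (cfg$pool_exotic > 0)
    sprintf("exotic_sp_%02d", seq_len(cfg$pool_exotic)) else character(0)
  c_vals <- sample(0:10, cfg$pool_native, replace = TRUE,
                   prob = stats::dbinom(0:10, 10, 0.45))
  species <- data.frame(
    species = c(natives, exotics, cfg$invader_name),
    native = c(rep(TRUE, length(natives)), rep(FALSE, length(exotics)), FALSE),
    c_value = c(c_vals, rep(NA_real_, length(exotics)), NA_real_),
    invader = c(rep(FALSE, length(natives) + length(exotics)), TRUE),
    stringsAsFactors = FALSE
  )
  list(natives = natives, exotics = exotics,
       weights = pool_weights(cfg$pool_native), species = species)
}

#' Generate one five-plot transect
#'
#' Draws, for each gradient position A-E: a plot-level target invader
#' relative abundance around the group mean (truncated normal; exactly zero
#' when the group mean is zero), a native richness count (Poisson around the
#' expected-richness curve, truncated at 1), a weighted sample of natives
#' from the pool with rank-lognormal covers scaled to the native budget, and
#' occasional incidental exotics. Raw covers are then perturbed per subplot,
#' discretized to cover classes, and the four subplot class midpoints are
#' averaged into the plot's mean cover -- the same pathway field data take.
#'
#' @param cfg A \code{\link{generator_config}}.
#' @param transect Transect index (positive integer) selecting the seeded
#'   per-transect random stream.
#' @return A list with elements \code{plots} (metadata rows) and
#'   \code{cover} (5 x species matrix of mean midpoint covers).
#' @export
generate_transect <- function(cfg, transect = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  pool <- species_pool(cfg)
  generate_transect_impl(cfg, pool, transect)
}

generate_transect_impl <- function(cfg, pool, transect) {
  set.seed(transect_seed(cfg$seed, transect))
  scale <- cover_class_scale()
  groups <- c("A", "B", "C", "D", "E")
  tid <- sprintf("T%03d", transect)
  rows <- vector("list", 5L)
  covers <- vector("list", 5L)
  for (i in seq_along(groups)) {
    g <- groups[i]
    mu <- cfg$group_invader_mean[[g]]
    if (mu == 0) {
      ra <- 0
    } else {
      sdev <- max(cfg$abundance_sd_frac * mu, cfg$abundance_sd_min)
      ra <- min(max(stats::rnorm(1, mu, sdev), 0), 95)
    }
    s_exp <- expected_richness(ra, cfg)
    s <- max(1L, stats::rpois(1, s_exp))
    if (s > cfg$pool_native)
      stop("species pool smaller than requested richness (", s, " > ",
           cfg$pool_native, ")")
    natives <- sample(pool$natives, s, prob = pool$weights)
    raw <- pool$weights[match(natives, pool$natives)] *
      stats::rlnorm(s, 0, cfg$cover_sdlog)
    raw <- raw / sum(raw) * cfg$native_budget
    names(raw) <- natives
    n_ex <- if (cfg$pool_exotic > 0) stats::rpois(1, cfg$exotic_rate) else 0L
    if (n_ex > 0) {
      ex <- sample(pool$exotics, min(n_ex, cfg$pool_exotic))
      raw <- c(raw, stats::setNames(stats::runif(length(ex), 0.5, 4), ex))
    }
    if (ra > 0) {
      inv_cover <- sum(raw) * ra / (100 - ra)
      raw <- c(raw, stats::setNames(inv_cover, cfg$invader_name))
    }
    # four subplots: multiplicative heterogeneity, discretize, average midpoints
    mids <- matrix(0, nrow = 4L, ncol = length(raw),
                   dimnames = list(NULL, names(raw)))
    for (sub in 1:4) {
      c_sub <- pmin(raw * stats::rlnorm(length(raw), 0, cfg$cover_sdlog), 100)
      mids[sub, ] <- midpoint_of(cover_class_of(c_sub, scale), scale)
    }
    covers[[i]] <- colMeans(mids)
    rows[[i]] <- data.frame(plot_id = paste0(tid, "_", g), transect_id = tid,
                            group = g, stringsAsFactors = FALSE)
  }
  species <- sort(unique(unlist(lapply(covers, names))))
  cover <- matrix(0, nrow = 5L, ncol = length(species),
                  dimnames = list(vapply(rows, `[[`, "", "plot_id"), species))
  for (i in 1:5) cover[i, names(covers[[i]])] <- covers[[i]]
  list(plots = do.call(rbind, rows), cover = cover)
}

#' Generate a full synthetic gradient study
#'
#' @param cfg A \code{\link{generator_config}}.
#' @return A \code{\link{study_dataset}} with \code{cfg$n_transects}
#'   transects of five plots each; identical seeds yield identical datasets.
#' @examples
#' ds <- generate_study(generator_config(n_transects = 4, seed = 7))
#' nrow(ds$plots) # 20
#' @export
generate_study <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  pool <- species_pool(cfg)
  parts <- lapply(seq_len(cfg$n_transects), function(k)
    generate_transect_impl(cfg, pool, k))
  plots <- do.call(rbind, lapply(parts, `[[`, "plots"))
  species <- sort(unique(unlist(lapply(parts, function(p) colnames(p$cover)))))
  cover <- matrix(0, nrow = nrow(plots), ncol = length(species),
                  dimnames = list(plots$plot_id, species))
  for (p in parts) cover[rownames(p$cover), colnames(p$cover)] <- p$cover
  study_dataset(cover, plots, pool$species,
                target_invader = cfg$invader_name)
}
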