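# Fixtures and independent oracles used across the suite.

# A tiny hand-built two-transect study: invader dominant in A, absent in E.
tiny_study <- function() {
  plots <- data.frame(
    plot_id = c(paste0("T1_", LETTERS[1:5]), paste0("T2_", LETTERS[1:5])),
    transect_id = rep(c("T1", "T2"), each = 5),
    group = rep(LETTERS[1:5], 2),
    stringsAsFactors = FALSE
  )
  species <- data.frame(
    species = c("inv", "nat1", "nat2", "nat3", "nat4", "exo1"),
    native = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    c_value = c(NA, 4, 6, 2, 8, NA),
    invader = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  cover <- rbind(
    T1_A = c(inv = 63, nat1 = 3,  nat2 = 0,  nat3 = 1,  nat4 = 0, exo1 = 1),
    T1_B = c(inv = 15, nat1 = 15, nat2 = 3,  nat3 = 0,  nat4 = 0, exo1 = 0),
    T1_C = c(inv = 3,  nat1 = 15, nat2 = 15, nat3 = 3,  nat4 = 1, exo1 = 0),
    T1_D = c(inv = 1,  nat1 = 15, nat2 = 15, nat3 = 3,  nat4 = 0, exo1 = 0),
    T1_E = c(inv = 0,  nat1 = 15, nat2 = 3,  nat3 = 3,  nat4 = 0, exo1 = 0),
    T2_A = c(inv = 85, nat1 = 1,  nat2 = 1,  nat3 = 0,  nat4 = 0, exo1 = 0),
    T2_B = c(inv = 15, nat1 = 3,  nat2 = 15, nat3 = 1,  nat4 = 0, exo1 = 1),
    T2_C = c(inv = 3,  nat1 = 15, nat2 = 15, nat3 = 15, nat4 = 3, exo1 = 0),
    T2_D = c(inv = 0,  nat1 = 15, nat2 = 3,  nat3 = 15, nat4 = 1, exo1 = 0),
    T2_E = c(inv = 0,  nat1 = 3,  nat2 = 15, nat3 = 3,  nat4 = 1, exo1 = 0)
  )
  study_dataset(cover, plots, species)
}

# Exhaustive species-accumulation oracle: mean richness over all C(n, k)
# subsets of each size, by full enumeration.
oracle_accumulation <- function(occ) {
  occ <- occ > 0
  n <- nrow(occ)
  vapply(seq_len(n), function(k) {
    subsets <- utils::combn(n, k)
    mean(apply(subsets, 2, function(rows)
      sum(colSums(occ[rows, , drop = FALSE]) > 0)))
  }, numeric(1))
}

# Independent ANOSIM R computation (explicit loops, no shared code).
oracle_anosim_R <- function(dmat, labels) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  dv <- numeric(0); wl <- logical(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dv <- c(dv, dmat[i, j])
    wl <- c(wl, labels[i] == labels[j])
  }
  rk <- rank(dv)
  (mean(rk[!wl]) - mean(rk[wl])) / (length(rk) / 2)
}

# Exhaustive permutation p for two groups: enumerate every relabelling that
# preserves group sizes and count those with R >= observed.
oracle_anosim_exhaustive_p <- function(dmat, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  stopifnot(length(lev) == 2L)
  n <- length(labels)
  k <- sum(labels == lev[1])
  r_obs <- oracle_anosim_R(dmat, labels)
  picks <- utils::combn(n, k)
  stats <- apply(picks, 2, function(rows) {
    lab <- rep(lev[2], n)
    lab[rows] <- lev[1]
    oracle_anosim_R(dmat, lab)
  })
  mean(stats >= r_obs - 1e-12)
}

# random abundance vector over s species
random_abundance <- function(s) {
  p <- stats::rexp(s)
  stats::setNames(p / sum(p), paste0("sp", seq_len(s)))
}
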