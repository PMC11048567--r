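test_that("relative abundance normalises summed covers", {
  ds <- tiny_study()
  one <- relative_abundance(ds, "T1_A")
  expect_equal(sum(one), 1)
  expect_equal(unname(one["inv"]), 63 / 68)
  # hand case {a:15, b:5} -> {0.75, 0.25}
  plots <- data.frame(plot_id = paste0("P_", LETTERS[1:5]),
                      transect_id = "P", group = LETTERS[1:5])
  sp <- data.frame(species = c("a", "b"), native = TRUE,
                   c_value = c(5, 5), invader = c(TRUE, FALSE))
  cov <- matrix(c(15, 5, rep(1, 8)), nrow = 5, ncol = 2, byrow = TRUE,
                dimnames = list(plots$plot_id, c("a", "b")))
  ds2 <- study_dataset(cov, plots, sp)
  expect_equal(relative_abundance(ds2, "P_A"), c(a = 0.75, b = 0.25))
  # sums to 1 for whole generated datasets
  g <- generate_study(generator_config(n_transects = 3, seed = 2))
  expect_equal(sum(relative_abundance(g)), 1)
  # all-zero plot set is an error
  cov0 <- cov; cov0["P_B", ] <- 0
  ds0 <- study_dataset(cov0, plots, sp)
  expect_error(relative_abundance(ds0, "P_B"), "no cover")
})

test_that("mean native richness counts natives only, invader excluded", {
  ds <- tiny_study()
  # T1_A: natives present nat1, nat3 (inv and exo1 don't count)
  expect_equal(mean_native_richness(ds, "T1_A"), 2)
  expect_equal(mean_native_richness(ds, c("T1_A", "T1_C")), 3) # (2 + 4) / 2
  # plot with zero natives contributes 0
  cov <- ds$cover; cov["T1_A", c("nat1", "nat3")] <- 0
  ds2 <- study_dataset(cov, ds$plots, ds$species)
  expect_equal(mean_native_richness(ds2, "T1_A"), 0)
})

test_that("FQI follows mean C times root richness", {
  plots <- data.frame(plot_id = paste0("Q_", LETTERS[1:5]),
                      transect_id = "Q", group = LETTERS[1:5])
  mk <- function(cvals, extra_native = TRUE) {
    nm <- paste0("s", seq_along(cvals))
    sp <- data.frame(species = c(nm, "inv"),
                     native = c(rep(extra_native, length(cvals)), FALSE),
                     c_value = c(cvals, NA),
                     invader = c(rep(FALSE, length(cvals)), TRUE))
    cov <- matrix(1, nrow = 5, ncol = length(nm) + 1,
                  dimnames = list(plots$plot_id, c(nm, "inv")))
    study_dataset(cov, plots, sp)
  }
  expect_equal(fqi(mk(c(4, 4, 4, 4))), 8)             # 4 * sqrt(4)
  expect_equal(fqi(mk(7)), 7)                          # single species
  expect_equal(fqi(mk(c(3, 5, 8, 2, 6, 0, 4, 7, 1))), 12)  # mean 4, S = 9
  # sqrt(S) scaling at fixed mean C
  expect_equal(fqi(mk(rep(4, 16))) / fqi(mk(rep(4, 4))), 2)
  # species without C-values are excluded from both terms
  ds <- mk(c(4, 4, 4, 4))
  ds$species$c_value[1] <- NA
  expect_message(v <- fqi(ds), "without C-values")
  expect_equal(v, 4 * sqrt(3))
  # no qualifying species -> 0 with warning
  ds$species$c_value[1:4] <- NA
  expect_warning(v0 <- suppressMessages(fqi(ds)), "FQI = 0")
  expect_equal(v0, 0)
  # non-natives enter only when native_only = FALSE
  ds2 <- mk(c(4, 4, 4, 4), extra_native = FALSE)
  expect_warning(fqi(ds2), "FQI = 0")
  expect_equal(suppressMessages(fqi(ds2, native_only = FALSE)), 8)
})

test_that("FQI is invariant to plot order", {
  ds <- generate_study(generator_config(n_transects = 3, seed = 6))
  ids <- ds$plots$plot_id
  expect_equal(suppressMessages(fqi(ds, ids)),
               suppressMessages(fqi(ds, rev(ids))))
})

test_that("the 50/20 rule returns the dominance set", {
  expect_equal(dominants_50_20(c(a = 0.40, b = 0.25, c = 0.20, d = 0.15)),
               c("a", "b", "c"))
  expect_equal(dominants_50_20(c(a = 1)), "a")
  # c reaches the 20% clause even though a + b already pass 50%
  expect_equal(dominants_50_20(c(a = 0.30, b = 0.30, c = 0.25, d = 0.15)),
               c("a", "b", "c"))
  # deterministic tie order: descending abundance then name; every species
  # at 25% qualifies under the 20% clause
  expect_equal(dominants_50_20(c(z = 0.25, a = 0.25, m = 0.25, b = 0.25)),
               c("a", "b", "m", "z"))
  # property: non-empty, cumulative abundance >= 50%
  set.seed(77)
  for (i in 1:50) {
    p <- random_abundance(sample(2:12, 1))
    dom <- dominants_50_20(p)
    expect_gt(length(dom), 0)
    expect_gte(sum(p[dom]), 0.5 - 1e-9)
  }
})

test_that("Renyi profiles hit the closed forms and order correctly", {
  u <- rep(1 / 8, 8); names(u) <- letters[1:8]
  pr <- renyi_profile(u)
  expect_equal(pr$value, rep(log(8), nrow(pr)))  # flat iff uniform
  pr2 <- renyi_profile(c(a = 0.5, b = 0.5), alphas = 2)
  expect_equal(pr2$value, -log(0.5))
  pr3 <- renyi_profile(c(a = 0.7, b = 0.2, c = 0.1), alphas = c(0, 1, 2, Inf))
  expect_equal(pr3$value[1], log(3))
  expect_equal(pr3$value[2], -sum(c(0.7, 0.2, 0.1) * log(c(0.7, 0.2, 0.1))))
  expect_equal(pr3$value[3], -log(0.54))
  expect_equal(pr3$value[4], -log(0.7))
  expect_error(renyi_profile(c(a = 1), alphas = -1), "non-negative")
})

test_that("Renyi alpha = 1 matches Shannon and profiles are non-increasing", {
  set.seed(123)
  for (i in 1:40) {
    p <- random_abundance(sample(2:20, 1))
    pr <- renyi_profile(p, alphas = c(0, 0.5, 0.9999, 1, 2, 5, 16, Inf))
    expect_equal(pr$value[pr$alpha == 1], -sum(p * log(p)), tolerance = 1e-9)
    expect_true(all(diff(pr$value) <= 1e-9))
  }
})

test_that("Renyi profile agrees with vegan's implementation", {
  set.seed(9)
  p <- random_abundance(12)
  al <- c(0, 0.5, 1, 2, 4, Inf)
  ours <- renyi_profile(p, alphas = al)
  ref <- suppressMessages(as.numeric(vegan::renyi(p, scales = al)))
  expect_equal(ours$value, ref, tolerance = 1e-8)
})

test_that("exact accumulation equals exhaustive subset enumeration", {
  set.seed(21)
  for (rep in 1:5) {
    occ <- matrix(rbinom(6 * 9, 1, 0.45), nrow = 6,
                  dimnames = list(paste0("p", 1:6), paste0("s", 1:9)))
    occ[1, ] <- pmax(occ[1, ], rbinom(9, 1, 0.5))  # avoid all-empty traps
    if (all(colSums(occ) == 0)) occ[1, 1] <- 1
    cur <- species_accumulation(occ, method = "exact")
    expect_equal(cur$richness, oracle_accumulation(occ), tolerance = 1e-12)
    expect_equal(cur$richness[6], sum(colSums(occ) > 0))
  }
  # the documented 4-plot incidence case {a:1110, b:1000, c:0011}
  occ <- cbind(a = c(1, 1, 1, 0), b = c(1, 0, 0, 0), c = c(0, 0, 1, 1))
  rownames(occ) <- paste0("p", 1:4)
  cur <- species_accumulation(occ, method = "exact")
  expect_equal(cur$richness, oracle_accumulation(occ), tolerance = 1e-12)
})

test_that("accumulation terminal and single-plot values have closed forms", {
  ds <- generate_study(generator_config(n_transects = 3, seed = 13))
  occ <- cover_matrix(ds) > 0
  cur <- species_accumulation(ds, method = "exact")
  expect_equal(cur$richness[nrow(occ)], sum(colSums(occ) > 0))
  expect_equal(cur$richness[1], mean(rowSums(occ)))
  expect_true(all(diff(cur$richness) >= -1e-12))  # non-decreasing
  perm <- species_accumulation(ds, method = "permutation", n_perm = 400,
                               seed = 3)
  expect_equal(perm$richness[nrow(occ)], cur$richness[nrow(occ)])
  expect_lt(max(abs(perm$richness - cur$richness)), 0.6)  # Monte-Carlo error
  expect_error(species_accumulation(ds, method = "permutation", n_perm = 0),
               "at least 1")
})

test_that("exact accumulation matches vegan's exact estimator", {
  ds <- generate_study(generator_config(n_transects = 3, seed = 4))
  cur <- species_accumulation(ds, method = "exact")
  ref <- vegan::specaccum(cover_matrix(ds), method = "exact")
  expect_equal(cur$richness, as.numeric(ref$richness), tolerance = 1e-8)
})

test_that("exact accumulation sd equals the exhaustive subset spread", {
  set.seed(25)
  occ <- matrix(rbinom(5 * 7, 1, 0.5), nrow = 5,
                dimnames = list(paste0("p", 1:5), paste0("s", 1:7)))
  if (all(colSums(occ) == 0)) occ[1, 1] <- 1
  cur <- species_accumulation(occ, method = "exact")
  # population sd of richness over every subset of each size
  sd_oracle <- vapply(1:5, function(k) {
    rich <- apply(utils::combn(5, k), 2, function(rows)
      sum(colSums(occ[rows, , drop = FALSE] > 0) > 0))
    sqrt(mean((rich - mean(rich))^2))
  }, numeric(1))
  expect_equal(cur$sd, sd_oracle, tolerance = 1e-10)
})

test_that("group summary mirrors the per-group table layout", {
  ds <- tiny_study()
  gs <- group_summary(ds)
  expect_equal(gs$group, c("A", "B", "C", "D", "E"))
  expect_equal(gs$n_plots, rep(2, 5))
  # group A invader relabund: mean of per-plot ratios
  expect_equal(gs$invader_relabund[1], mean(c(100 * 63 / 68, 100 * 85 / 87)))
  # pooled variant divides summed invader by summed cover
  gp <- group_summary(ds, pooled = TRUE)
  expect_equal(gp$invader_relabund[1], 100 * (63 + 85) / (68 + 87))
  expect_equal(gs$invader_relabund[5], 0)
})
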