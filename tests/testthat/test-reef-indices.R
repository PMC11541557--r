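test_that("bleaching severity matches hand-evaluated cases and bounds", {
  expect_equal(bleaching_severity(100, 0, 0, 0), 0)
  expect_equal(bleaching_severity(50, 0, 0, 50), 100)
  expect_equal(bleaching_severity(100, 30, 0, 0), 10)
  expect_equal(bleaching_severity(100, 0, 0, 28), 28)  # percent-affected reading
  expect_error(bleaching_severity(10, 5, 5, 5), "exceed")
  expect_error(bleaching_severity(0, 0, 0, 0), ">= 1")
})

test_that("moving a colony to a heavier category strictly increases severity", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    split3 <- c(0, sort(sample(0:n, 2)), n)
    c2 <- split3[2] - split3[1]
    c3 <- split3[3] - split3[2]
    c4 <- n - split3[3]
    c1 <- n - c2 - c3 - c4
    b0 <- bleaching_severity(n, c2, c3, c4)
    if (c1 > 0) expect_gt(bleaching_severity(n, c2 + 1, c3, c4), b0)
    if (c2 > 0) expect_gt(bleaching_severity(n, c2 - 1, c3 + 1, c4), b0)
    if (c3 > 0) expect_gt(bleaching_severity(n, c2, c3 - 1, c4 + 1), b0)
  }
})

test_that("species severity table pools colonies across surveys", {
  s1 <- colonies_df("Acropora palmata", c("normal", "pale"), c(30, 10))
  s2 <- colonies_df("Acropora palmata", c("normal", "fully_bleached"), c(40, 20))
  tab <- species_bsi_table(rbind(s1, s2), min_colonies = 10)
  # pooled Eq on summed counts, NOT the mean of per-survey values
  expect_equal(tab$bsi_sp, ((10 + 3 * 20) / 3) / 100, tolerance = 1e-12)
  expect_equal(tab$n_colonies, 100L)
  per_survey_mean <- mean(c(survey_bsi(s1, scale = 1), survey_bsi(s2, scale = 1)))
  expect_false(isTRUE(all.equal(tab$bsi_sp, per_survey_mean)))
  # single species, all pale
  tab2 <- species_bsi_table(colonies_df("A b", "pale", 60), min_colonies = 10)
  expect_equal(tab2$bsi_sp, 1 / 3, tolerance = 1e-12)
  # pooling floor excludes sparse species
  mix <- rbind(s1, colonies_df("Porites porites", "pale", 5))
  tab3 <- species_bsi_table(mix, min_colonies = 20)
  expect_identical(tab3$species, "Acropora palmata")
  expect_identical(attr(tab3, "excluded_species"), "Porites porites")
})

test_that("reef sensitivity is the abundance-weighted severity", {
  tab <- data.frame(species = c("A a", "B b"), bsi_sp = c(0.2, 0.4),
                    n_colonies = c(100L, 100L))
  obs <- colonies_df(c("A a", "B b"), "normal", c(50, 50))
  expect_equal(si_reef(obs, tab), 0.30, tolerance = 1e-12)
  mono <- colonies_df("B b", "pale", 80)
  expect_equal(si_reef(mono, tab), 0.4, tolerance = 1e-12)
  # species missing from the table are excluded from both sides of the ratio
  obs2 <- colonies_df(c("A a", "B b", "C c"), "normal", c(50, 50, 900))
  expect_equal(si_reef(obs2, tab), 0.30, tolerance = 1e-12)
  expect_error(si_reef(colonies_df("Z z", "normal", 10), tab), "no surveyed species")
})

test_that("reef sensitivity is a convex combination of species severities", {
  set.seed(9)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    tab <- data.frame(species = paste0("sp", 1:k), bsi_sp = runif(k),
                      n_colonies = 100L)
    obs <- colonies_df(paste0("sp", 1:k), "normal", sample(1:50, k, replace = TRUE))
    v <- si_reef(obs, tab)
    expect_gte(v, min(tab$bsi_sp) - 1e-12)
    expect_lte(v, max(tab$bsi_sp) + 1e-12)
  }
})

test_that("functional index applies congener fallback and drops unassignable colonies", {
  fc <- data.frame(species = c("Solenastrea hyades", "Porites porites"),
                   fc = c(0.5, 0.3))
  expect_equal(as.numeric(rfi(colonies_df("Solenastrea hyades", "normal", 10), fc)), 0.5)
  r <- rfi(colonies_df("Solenastrea bournoni", "pale", 10), fc)
  expect_equal(as.numeric(r), 0.5)
  expect_identical(attr(r, "fallback"),
                   c("Solenastrea bournoni" = "Solenastrea hyades"))
  both <- colonies_df(c("Solenastrea hyades", "Porites porites", "Oculina diffusa"),
                      "normal", c(20, 20, 500))
  expect_equal(as.numeric(rfi(both, fc)), 0.4, tolerance = 1e-12)
  expect_error(rfi(colonies_df("Oculina diffusa", "normal", 5), fc), "functional")
  expect_error(rfi(both, data.frame(species = "X y", fc = -1)), "> 0")
})

test_that("Hill N1 diversity has its closed-form identities", {
  expect_equal(hill_n1(rep(10, 8)), 8, tolerance = 1e-12)
  expect_equal(hill_n1(c(42)), 1, tolerance = 1e-12)
  expect_equal(hill_n1(c(0.5, 0.5)), 2, tolerance = 1e-12)
  expect_equal(hill_n1(c(3, 3, 0, 0)), 2, tolerance = 1e-12)  # zeros ignored
  # scale invariance and the richness bound
  set.seed(4)
  for (rep in 1:20) {
    x <- rgamma(sample(2:15, 1), 1)
    expect_equal(hill_n1(x), hill_n1(10 * x), tolerance = 1e-9)
    expect_lte(hill_n1(x), richness(x) + 1e-9)
    expect_gte(hill_n1(x), 1)
  }
})

test_that("richness counts positive species and warns when empty", {
  expect_identical(richness(c(3, 0, 1, 2)), 3L)
  expect_warning(r <- richness(numeric(0)), "empty")
  expect_identical(r, 0L)
})

test_that("ordination recovers a 1-D gradient from unimodal communities", {
  gc <- gradient_community(30, 20, seed = 2)
  sc <- dca_axis1(gc$comm)
  expect_gte(abs(cor(sc, gc$gradient, method = "spearman")), 0.9)
})

test_that("ordination is equivariant to site permutation and duplication", {
  gc <- gradient_community(15, 10, seed = 6)
  sc <- dca_axis1(gc$comm)
  perm <- sample(nrow(gc$comm))
  sc_p <- dca_axis1(gc$comm[perm, ])
  expect_equal(unname(sc_p), unname(sc[perm]), tolerance = 1e-8)
  dup <- rbind(gc$comm, dup_site = gc$comm[4, ])
  sc_d <- dca_axis1(dup)
  expect_equal(unname(sc_d[["dup_site"]]), unname(sc_d[[4]]), tolerance = 1e-8)
})

test_that("with detrending disabled the axis matches an eigen CA oracle", {
  set.seed(12)
  M <- matrix(rpois(30, 8) * matrix(runif(30) > 0.2, 6, 5), 6, 5)
  M[M == 0] <- 0.5
  dimnames(M) <- list(paste0("r", 1:6), paste0("c", 1:5))
  sc <- dca_axis1(M, detrend = FALSE)
  oracle <- ca_axis1_oracle(M)
  r <- cor(sc, oracle, method = "spearman")
  expect_equal(abs(r), 1, tolerance = 1e-9)
})

test_that("degenerate community matrices are rejected, zero rows dropped", {
  M <- matrix(1, 4, 4)  # rank 1 after centering
  dimnames(M) <- list(paste0("r", 1:4), paste0("c", 1:4))
  expect_error(dca_axis1(M), "degenerate")
  gc <- gradient_community(10, 6, seed = 3)
  M2 <- rbind(gc$comm, empty = 0)
  expect_warning(sc <- dca_axis1(M2), "all-zero")
  expect_length(sc, 10)
})

test_that("the per-observation index bundle honors its invariants", {
  tab <- data.frame(species = c("A a", "B b"), bsi_sp = c(0.2, 0.4),
                    n_colonies = 100L)
  fc <- data.frame(species = c("A a", "B b"), fc = c(0.4, 0.6))
  obs <- colonies_df(c("A a", "A a", "B b"), c("normal", "pale", "fully_bleached"),
                     c(60, 20, 20))
  out <- reef_index_set(obs, tab, fc, dca_score = 0.7, site_id = "s1",
                        date = as.Date("2016-10-01"), depth = 12)
  expect_gte(out$bsi, 0); expect_lte(out$bsi, 100)
  expect_gte(out$diversity_n1, 1)
  expect_lte(out$diversity_n1, out$richness)
  expect_gte(out$si_reef, 0.2); expect_lte(out$si_reef, 0.4)
  # monospecific survey collapses the indices
  mono <- colonies_df("B b", "pale", 160)
  out2 <- reef_index_set(mono, tab, fc)
  expect_identical(out2$richness, 1L)
  expect_equal(out2$diversity_n1, 1)
  expect_equal(out2$si_reef, 0.4)
})
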