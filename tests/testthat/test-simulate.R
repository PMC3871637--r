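test_that("plant generation is deterministic and respects trait ranges", {
  cfg <- simulation_config()
  p1 <- generate_plants(cfg, seed = 5L)
  p2 <- generate_plants(cfg, seed = 5L)
  expect_identical(p1, p2)
  f2 <- p1[p1$class == "f2_hybrid", ]
  expect_true(all(f2$tepal_color >= 3 & f2$tepal_color <= 23))
  expect_error(
    simulation_config(trait_model = within_range <- local({
      tm <- pollensel:::default_trait_model()
      tm$asd$range <- c(5, 1)
      tm
    })), "impossible truncation")
})

test_that("F2 trait mean matches the truncated-normal expectation", {
  cfg <- simulation_config(n_parental = 1L, n_f2 = 10000L,
                           grid = c(101L, 100L))
  f2 <- generate_plants(cfg, seed = 9L)
  f2 <- f2[f2$class == "f2_hybrid", ]
  # closed-form truncated-normal mean/SD as the independent oracle
  tm <- pollensel:::default_trait_model()$tepal_color
  a <- (tm$range[1] - tm$f2_mean) / tm$f2_sd
  b <- (tm$range[2] - tm$f2_mean) / tm$f2_sd
  zc <- pnorm(b) - pnorm(a)
  mu_tr <- tm$f2_mean + tm$f2_sd * (dnorm(a) - dnorm(b)) / zc
  var_tr <- tm$f2_sd^2 *
    (1 + (a * dnorm(a) - b * dnorm(b)) / zc - ((dnorm(a) - dnorm(b)) / zc)^2)
  expect_lt(abs(mean(f2$tepal_color) - mu_tr),
            3 * sqrt(var_tr / nrow(f2)))
})

test_that("F2 genotypes are Mendelian draws through the F1 pair", {
  cfg <- simulation_config(n_parental = 2L, n_f2 = 10000L,
                           grid = c(101L, 100L))
  plants <- generate_plants(cfg, seed = 2L)
  geno <- generate_genotypes(cfg, plants, seed = 21L)
  f1 <- attr(geno, "f1_pair")
  f2_ids <- plants$genet_id[plants$class == "f2_hybrid"]
  g_f2 <- geno[geno$genet_id %in% f2_ids, ]
  for (loc in names(cfg$panel)) {
    rows <- g_f2[g_f2$locus == loc, ]
    allowed <- sort(unique(unlist(f1[[loc]])))
    expect_true(all(c(rows$allele1, rows$allele2) %in% allowed))
  }
  # a locus whose two F1s carry the same heterozygous pair segregates 1:2:1
  same <- names(Filter(function(p) setequal(p[[1]], p[[2]]) &&
                                   length(unique(p[[1]])) == 2L, f1))
  expect_gt(length(same), 0L)  # 10 loci, P(same pair) >= 1/16 each
  loc <- same[1]
  rows <- g_f2[g_f2$locus == loc, ]
  a <- sort(unique(f1[[loc]][[1]]))
  n_aa <- sum(rows$allele1 == a[1] & rows$allele2 == a[1])
  n_ab <- sum(rows$allele1 == a[1] & rows$allele2 == a[2])
  n_bb <- sum(rows$allele1 == a[2] & rows$allele2 == a[2])
  expect_equal(n_aa + n_ab + n_bb, nrow(rows))
  p <- suppressWarnings(stats::chisq.test(c(n_aa, n_ab, n_bb),
                                          p = c(1, 2, 1) / 4)$p.value)
  expect_gt(p, 0.001)
})

test_that("visit choice is uniform when all preference coefficients are 0", {
  zero <- stats::setNames(numeric(5), pollensel:::trait_names())
  cfg <- small_config()
  cfg$preference <- list(b = zero, g = zero)
  cfg$transport$grains_per_pickup <- 0L
  cfg$bout_model$mean_visits <- 1
  plants <- generate_plants(cfg, seed = 1L)
  plants$flower_id <- paste0(plants$genet_id, ".B1")
  first <- vapply(seq_len(4000L), function(i)
    simulate_bout(plants, cfg, seed = 10000L + i)$visits$flower_id[1], "")
  tab <- table(factor(first, levels = plants$flower_id))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("full per-visit deposition gives single-step carryover only", {
  cfg <- small_config()
  cfg$transport <- list(grains_per_pickup = 10L, d = 1, s = 0)
  cfg$bout_model$mean_visits <- 10
  plants <- generate_plants(cfg, seed = 1L)
  plants$flower_id <- paste0(plants$genet_id, ".B1")
  sim <- simulate_bout(plants, cfg, seed = 4L)
  expect_gt(nrow(sim$events), 0L)
  vseq <- sim$visits$flower_id
  genet_of <- stats::setNames(plants$genet_id, plants$flower_id)
  for (i in seq_len(nrow(sim$events))) {
    v <- sim$events$visit_index[i]
    expect_gt(v, 1L)
    expect_equal(sim$events$true_donor_id[i],
                 unname(genet_of[vseq[v - 1L]]))
  }
})

test_that("a single-visit bout deposits no outcross pollen", {
  cfg <- small_config()
  cfg$bout_model$mean_visits <- 0.0001  # forced to the 1-visit minimum
  plants <- generate_plants(cfg, seed = 1L)
  plants$flower_id <- paste0(plants$genet_id, ".B1")
  sim <- simulate_bout(plants, cfg, seed = 8L)
  expect_equal(nrow(sim$visits), 1L)
  genet_of <- stats::setNames(plants$genet_id, plants$flower_id)
  outcross <- sim$events$true_donor_id !=
    genet_of[sim$events$stigma_flower_id]
  expect_equal(sum(outcross), 0L)
})

test_that("per-flower visit counts stay within 0..2 under the default bout model", {
  exp <- default_exp()
  per_flower <- table(paste(exp$bouts$bout_id, exp$bouts$flower_id))
  expect_true(all(per_flower <= 2L))
})

test_that("genotyping noise has the configured marginal behaviour", {
  panel <- tiny_panel()
  geno <- data.frame(genet_id = "D", locus = c("L1", "L2"),
                     allele1 = c(100L, 150L), allele2 = c(100L, 150L))
  ev <- data.frame(grain_id = sprintf("g%05d", 1:10000),
                   true_donor_id = "D", stigma_flower_id = "F1",
                   bout_id = "B1", visit_index = 2L)
  # noise-free homozygous donor: grain equals the donor allele everywhere
  g0 <- apply_genotyping_noise(ev[1:50, ], geno, panel, noise_free(),
                               seed = 1L)
  expect_true(all(vapply(g0$alleles[g0$locus == "L1"],
                         identical, TRUE, 100L)))
  expect_true(all(vapply(g0$alleles[g0$locus == "L2"],
                         identical, TRUE, 150L)))
  # dropout 0.2 on a 10-locus panel: mean typed loci ~ 8
  panel10 <- default_panel()
  geno10 <- data.frame(genet_id = "D", locus = names(panel10),
                       allele1 = vapply(panel10, `[`, 1L, 1L),
                       allele2 = vapply(panel10, `[`, 1L, 1L))
  gd <- apply_genotyping_noise(ev, geno10, panel10,
                               list(dropout = 0.2, contamination = 0,
                                    error = 0), seed = 2L)
  nt <- grain_summary(gd)$n_typed
  se <- sqrt(10 * 0.2 * 0.8 / length(nt))
  expect_lt(abs(mean(nt) - 8), 3 * se)
})

test_that("certain contamination merges grains into multi-allele records", {
  panel <- tiny_panel()
  geno <- data.frame(genet_id = c("D1", "D1", "D2", "D2"),
                     locus = rep(c("L1", "L2"), 2),
                     allele1 = c(100L, 150L, 104L, 154L),
                     allele2 = c(100L, 150L, 104L, 154L))
  ev <- data.frame(grain_id = c("g1", "g2"),
                   true_donor_id = c("D1", "D2"),
                   stigma_flower_id = "F1", bout_id = "B1",
                   visit_index = 2L)
  g <- apply_genotyping_noise(ev, geno, panel,
                              list(dropout = 0, contamination = 1,
                                   error = 0), seed = 3L)
  s <- grain_summary(g)
  expect_true(all(s$multiallelic))
})

test_that("simulated experiments are reproducible and internally consistent", {
  cfg <- small_config()
  e1 <- simulate_experiment(cfg, seed = 42L)
  e2 <- simulate_experiment(cfg, seed = 42L)
  expect_equal(e1$grains$alleles, e2$grains$alleles)
  expect_identical(e1$truth, e2$truth)
  # every grain record corresponds to one ground-truth deposition event
  expect_setequal(unique(e1$grains$grain_id), e1$truth$grain_id)
})
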