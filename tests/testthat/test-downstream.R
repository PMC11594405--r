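test_that("two-region RMSD is zero for the reference and flags missing
           regions", {
  tm <- build_template("helix-bundle", 60, seed = 11)
  regions <- list(region_spec("r1", c(10, 20)), region_spec("r2", c(30, 40)))
  tab <- two_region_rmsd(list(tm), tm, regions)
  expect_equal(unlist(tab[1, c("r1", "r2")]), c(r1 = 0, r2 = 0),
               tolerance = 1e-12)
  # switch-open conformer: planted rotation dominates region 1 and matches
  # the closed-form rotation oracle under a core-only fit
  open1 <- apply_flap(tm, c(10, 20), 40)
  sup <- superpose_instances(open1, tm, fit_positions = c(1:10, 20:60))
  ca <- ca_xyz(tm)
  k <- ca["A:20", ] - ca["A:10", ]; k <- k / sqrt(sum(k^2))
  rel <- sweep(ca[paste0("A:", 11:19), ], 2, ca["A:10", ])
  radii <- sqrt(rowSums((rel - outer(as.numeric(rel %*% k), k))^2))
  analytic <- sqrt(mean((2 * radii * sin(20 * pi / 180))^2))
  expect_equal(region_rmsd(sup, c(11, 19)), analytic, tolerance = 1e-6)
  tab2 <- suppressWarnings(two_region_rmsd(list(open1), tm, regions))
  expect_gt(tab2$r1, 3 * tab2$r2)
  # region 1 unresolved: flagged incomplete
  miss <- tm
  miss$atoms <- miss$atoms[!(miss$atoms$resno %in% 10:20), ]
  tab3 <- suppressWarnings(two_region_rmsd(list(miss), tm, regions))
  expect_false(tab3$complete)
  expect_error(region_spec("bad", c(10, 5)), class = "fc_validation_error")
})

test_that("conformation clustering recovers planted structure and is order
           invariant", {
  set.seed(12)
  blob1 <- cbind(rnorm(10, 0.5, 0.05), rnorm(10, 0.5, 0.05))
  blob2 <- cbind(rnorm(10, 4, 0.05), rnorm(10, 1, 0.05))
  tab <- data.frame(instance_id = sprintf("i%02d", 1:20),
                    r1 = c(blob1[, 1], blob2[, 1]),
                    r2 = c(blob1[, 2], blob2[, 2]), complete = TRUE)
  cl <- cluster_conformations(tab)
  expect_equal(cl$k, 2L)
  # brute-force nearest-centre oracle agrees with the labels
  centers <- cl$centers
  near <- apply(as.matrix(tab[, 2:3]), 1, function(p)
    which.min(colSums((t(centers) - p)^2)))
  expect_equal(cluster_agreement(cl$labels, near), 1)
  # permuting rows permutes nothing of substance
  perm <- sample(20)
  cl2 <- cluster_conformations(tab[perm, ])
  expect_equal(cl2$k, 2L)
  expect_equal(cluster_agreement(cl$labels[tab$instance_id],
                                 cl2$labels[tab$instance_id]), 1)
  # identical points collapse to one cluster
  flat <- data.frame(instance_id = letters[1:5], r1 = 1, r2 = 2,
                     complete = TRUE)
  expect_equal(cluster_conformations(flat)$k, 1L)
  expect_error(cluster_conformations(flat[1, ]), class = "fc_validation_error")
})

test_that("planted six-pattern switch archetypes are recovered", {
  tm <- build_template("helix-bundle", 60, seed = 11)
  regions <- list(region_spec("s1", c(10, 20)), region_spec("s2", c(30, 40)))
  sw <- generate_switch_ensemble(tm, regions, seed = 5)
  tab <- two_region_rmsd(sw$conformers, tm, regions)
  cl <- cluster_conformations(tab)
  expect_equal(cl$k, 6L)
  expect_gte(cluster_agreement(cl$labels[tab$instance_id], sw$truth), 0.95)
})

test_that("threshold fractions count instances with both regions within", {
  tab <- data.frame(instance_id = letters[1:4],
                    r1 = c(0.5, 2.0, 1.0, 6.0), r2 = c(0.3, 1.5, 3.0, 2.0),
                    complete = TRUE)
  fr <- threshold_fractions(tab)
  expect_equal(unname(fr), c(0.25, 0.5, 0.75))
  expect_true(all(diff(fr) >= 0))
  zero <- data.frame(instance_id = "a", r1 = 0, r2 = 0, complete = TRUE)
  expect_equal(unname(threshold_fractions(zero)), c(1, 1, 1))
})

test_that("protein set selection applies the median and decile rules", {
  census <- data.frame(group_id = sprintf("g%02d", 1:10),
                       median_rmsd = 1:10)
  gp <- data.frame(group_id = census$group_id,
                   protein_acc = sprintf("P%02d", 1:10))
  sets <- select_protein_sets(census, gp)
  expect_setequal(sets$het, sprintf("P%02d", 3:10))   # medians > 2.5
  expect_setequal(sets$con, "P01")                    # lowest decile
  expect_equal(length(intersect(sets$het, sets$con)), 0)
  # a protein owning one rigid and one flexible group lands in het
  gp2 <- gp; gp2$protein_acc[1] <- "P10"
  sets2 <- select_protein_sets(census, gp2)
  expect_true("P10" %in% sets2$het)
  expect_false("P10" %in% sets2$con)
  all_low <- census; all_low$median_rmsd <- 0.5
  expect_equal(length(select_protein_sets(all_low, gp)$het), 0)
})

test_that("hypergeometric enrichment equals exact enumeration", {
  het <- sprintf("H%d", 1:5); con <- sprintf("C%d", 1:5)
  ann <- data.frame(protein_acc = het, term = "t1")
  res <- hypergeom_enrich(het, con, ann)
  row <- res[res$direction == "het" & res$term == "t1", ]
  expect_equal(row$p_value, 1 / 252, tolerance = 1e-12)
  expect_equal(row$count_diff, -5)
  # a term annotating everything is never enriched
  ann2 <- data.frame(protein_acc = c(het, con), term = "all")
  res2 <- hypergeom_enrich(het, con, ann2)
  expect_equal(res2$p_value, c(1, 1))
  # tail probabilities match combinatorial counting for universes <= 20
  set.seed(13)
  for (rep in 1:25) {
    N <- sample(6:20, 1); nh <- sample(2:(N - 2), 1)
    prot <- sprintf("U%02d", 1:N)
    h <- prot[1:nh]; c_ <- prot[(nh + 1):N]
    K <- sample(1:N, 1)
    withterm <- sample(prot, K)
    ann3 <- data.frame(protein_acc = withterm, term = "t")
    r <- hypergeom_enrich(h, c_, ann3)
    k_het <- sum(h %in% withterm)
    expect_equal(r$p_value[r$direction == "het"],
                 hyper_tail_count(k_het, K, N, nh), tolerance = 1e-12)
  }
  # full draw enumeration on a small universe confirms the tail definition
  combs <- utils::combn(10, 5)
  hits <- colSums(combs <= 5)           # term annotates proteins 1..5
  expect_equal(mean(hits >= 5), 1 / 252)
  # monotone: more annotated het proteins cannot raise the p-value
  ps <- vapply(0:5, function(k) {
    ann4 <- data.frame(protein_acc = c(head(het, k), head(con, 5 - k)),
                       term = "t")
    r <- hypergeom_enrich(het, con, ann4)
    r$p_value[r$direction == "het"]
  }, 1.0)
  expect_true(all(diff(ps) <= 1e-12))
})
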