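test_that("PDB and mmCIF fixtures parse to identical models", {
  pdb <- write_tiny_pdb(tempfile(fileext = ".pdb"))
  cif <- write_tiny_cif(tempfile(fileext = ".cif"))
  s1 <- read_structure(pdb)
  s2 <- read_structure(cif)
  expect_equal(length(unique(s1$atoms$key)), 3)
  expect_equal(length(unique(s1$atoms$chain)), 1)
  expect_equal(nrow(s1$atoms), nrow(s2$atoms))
  expect_equal(length(unique(s2$atoms$key)), 3)
  expect_equal(s1$atoms[, c("x", "y", "z")], s2$atoms[, c("x", "y", "z")])
  # HETATM Mg routed to het groups, chains unaffected
  expect_equal(nrow(s1$het_atoms), 1)
  expect_equal(s1$het_atoms$elesy, "MG")
  expect_equal(s1$resolution, 1.8)
  expect_match(s1$method, "X-RAY")
  expect_error(read_structure(tempfile()), class = "fc_io_error")
})

test_that("domain definitions parse codes, segments and reject bad input", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("domain_id\tcath_code\tprotein_acc\tsegments",
               "d1\t3.40.50.300\tP1\tA:5-120",
               "d2\t1.10.10.10\tP2\tA:5-60,A:70-120"), tsv)
  defs <- read_domain_definitions(tsv)
  expect_equal(defs[[1]]$topology_code, "3.40.50")
  expect_equal(nrow(defs[[2]]$segments), 2)
  expect_error(domain_definition("x", "3.40.50", "P", "A:1-10"),
               class = "fc_validation_error")
  expect_error(domain_definition("x", "3.40.50.300", "P", "A:5-60,A:50-80"),
               class = "fc_validation_error")
})

test_that("domain extraction respects segments and unresolved gaps", {
  tm <- build_template("extended", 20, seed = 1)
  s <- as_structure_model(tm, "src")
  full <- extract_domain_instance(
    s, domain_definition("d", "2.1.1.1", "P", "A:1-20"))
  expect_equal(full$n_res, 20)
  part <- extract_domain_instance(
    s, domain_definition("d", "2.1.1.1", "P", "A:5-8"))
  expect_equal(part$n_res, 4)
  # unresolved gap: residues 6-7 removed from the model
  s2 <- s
  s2$atoms <- s2$atoms[!(s2$atoms$resno %in% 6:7), ]
  gap <- extract_domain_instance(
    s2, domain_definition("d", "2.1.1.1", "P", "A:5-8"))
  expect_equal(gap$n_res, 2)
  expect_error(extract_domain_instance(
    s, domain_definition("d", "2.1.1.1", "P", "A:30-40")),
    class = "fc_empty_domain")
})

test_that("written domains round-trip through the PDB reader", {
  tm <- build_template("mixed", 30, seed = 9)
  f <- tempfile(fileext = ".pdb")
  write_domain_pdb(tm, f)
  back <- extract_domain_instance(
    read_structure(f), domain_definition("d", "1.1.1.1", "P", "A:1-30"))
  expect_equal(back$n_res, tm$n_res)
  expect_equal(residue_table(back)$key, residue_table(tm)$key)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               round(as.matrix(tm$atoms[, c("x", "y", "z")]), 3),
               ignore_attr = TRUE)
})

test_that("curation applies rules in fixed order and partitions the input", {
  mk <- function(id, acc, src, n_res = 50, pid = 100, resol = 2,
                 term = FALSE) {
    tm <- build_template("extended", max(n_res, 20), seed = 1,
                         group_id = id, protein_acc = acc)
    if (n_res < tm$n_res) {
      tm$atoms <- tm$atoms[tm$atoms$resno <= n_res, ]
      tm$n_res <- n_res
      tm$seq <- substr(tm$seq, 1, n_res)
    }
    tm$instance_id <- id; tm$source <- src
    tm$pid <- pid; tm$resolution <- resol; tm$extended_termini <- term
    tm
  }
  # protein A has 3 sources (fails the count rule at threshold 3? no: passes
  # at min 3); protein B has 1 source (fails); one bad resolution; one short
  insts <- list(mk("i1", "A", "s1"), mk("i2", "A", "s2"),
                mk("i3", "A", "s3", resol = 3.2),
                mk("i4", "A", "s4", n_res = 10),
                mk("i5", "B", "s5"),
                mk("i6", "A", "s6", pid = 95, resol = 3.5))
  cfg <- curation_config(min_structures_per_protein = 3)
  out <- apply_curation(insts, cfg)
  expect_equal(length(out$kept) + nrow(out$rejected), length(insts))
  expect_setequal(vapply(out$kept, function(x) x$instance_id, ""),
                  c("i1", "i2"))
  reasons <- setNames(out$rejected$reason, out$rejected$instance_id)
  expect_equal(reasons[["i3"]], "resolution")
  expect_equal(reasons[["i4"]], "length")
  expect_equal(reasons[["i5"]], "counts")
  expect_equal(reasons[["i6"]], "pid")   # first failing rule wins
  # order independence
  out2 <- apply_curation(rev(insts), cfg)
  expect_setequal(vapply(out2$kept, function(x) x$instance_id, ""),
                  vapply(out$kept, function(x) x$instance_id, ""))
  empty <- apply_curation(list(), cfg)
  expect_equal(length(empty$kept), 0)
})

test_that("extended termini are flagged for gross arms only", {
  tm <- build_template("helix-bundle", 60, seed = 2)
  expect_false(detect_extended_termini(tm, tm))
  # 15-residue N-terminal arm rotated 90 degrees from the matched core:
  # oracle check on the per-residue deviations after core-only superposition
  arm <- tm
  ca <- ca_xyz(tm)
  sel <- arm$atoms$resno <= 15
  arm$atoms[sel, c("x", "y", "z")] <- foldcensus:::rotate_about_axis(
    as.matrix(arm$atoms[sel, c("x", "y", "z")]),
    ca["A:16", ], ca["A:17", ] - ca["A:16", ], 90)
  sup_core <- superpose_instances(arm, tm, fit_positions = 16:60)
  expect_gt(sum(head(sup_core$dev, 15) > 5), 5)   # the arm really deviates
  expect_true(detect_extended_termini(arm, tm))
  # deviation confined to an internal loop does not flag
  fl <- apply_flap(tm, c(25, 35), 60)
  expect_false(detect_extended_termini(fl, tm))
  # rigid-body transforms never flag
  rg <- tm
  rg$atoms[, c("x", "y", "z")] <- foldcensus:::rotate_about_axis(
    as.matrix(tm$atoms[, c("x", "y", "z")]), c(1, 2, 3), c(1, 1, 1), 77)
  expect_false(detect_extended_termini(rg, tm))
  # map shorter than twice the window: warning + FALSE
  short <- tm
  short$atoms <- short$atoms[short$atoms$resno <= 8, ]
  expect_warning(flag <- detect_extended_termini(short, short))
  expect_false(flag)
})

test_that("confidence filter thresholds the pLDDT fraction", {
  tm <- build_template("extended", 20, seed = 1)
  tm$atoms <- tm$atoms[tm$atoms$resno <= 10, ]
  tm$is_predicted <- TRUE
  set_plddt <- function(inst, vals) {
    inst$atoms$b <- vals[inst$atoms$resno]
    inst
  }
  expect_true(confidence_filter(set_plddt(tm, rep(95, 10))))
  expect_false(confidence_filter(set_plddt(tm, c(rep(85, 8), 50, 50))))
  expect_true(confidence_filter(set_plddt(tm, c(rep(85, 9), 50))))
  tm$is_predicted <- FALSE
  expect_error(confidence_filter(tm), class = "fc_validation_error")
})
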