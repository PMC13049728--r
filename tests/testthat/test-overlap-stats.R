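test_that("DEG filtering applies both thresholds symmetrically", {
  tab <- toy_gene_table()
  # exactly the (padj 0.05, FC 2.0) and (padj 0.10, FC 1.6) rows survive
  expect_setequal(filter_degs(tab), c("g1", "g2"))
  # down-regulation counts through |FC|
  tab$padj[5] <- 0.05
  expect_setequal(filter_degs(tab), c("g1", "g2", "g5"))
  expect_identical(filter_degs(tab[0, ]), character())
  # boundary behaviour
  expect_identical(filter_degs(tab, padj_max = 0, fc_min = Inf), character())
  expect_setequal(filter_degs(tab, padj_max = 1, fc_min = 1 - 1e-9),
                  tab$gene_id)
  expect_error(filter_degs(tab[, 1, drop = FALSE]), "lacks required")
})

test_that("DEP filtering uses the 1.2-fold and alpha thresholds", {
  tab <- data.frame(gene_id = paste0("p", 1:4),
                    log2fc = c(log2(1.3), log2(1.1), log2(1.5), log2(2.0)),
                    p = c(0.01, 0.01, 0.20, 0.049))
  expect_setequal(filter_deps(tab), c("p1", "p4"))
  flat <- data.frame(gene_id = paste0("p", 1:4), log2fc = 0,
                     p = rep(0.001, 4))
  expect_identical(filter_deps(flat), character())
})

test_that("planted protein shifts are recalled at the designed power", {
  recalls <- vapply(1:5, function(s) {
    sim <- simulate_gene_table(sim_config(seed = 500 + s))
    pt <- protein_ttest(sim$proteins$ids, sim$proteins$control,
                        sim$proteins$mutant)
    hits <- filter_deps(pt)
    length(intersect(hits, sim$truth$changed_proteins)) /
      length(sim$truth$changed_proteins)
  }, numeric(1))
  expect_gte(mean(recalls), 0.6)
  expect_lte(mean(recalls), 0.95)
})

test_that("hypergeometric overlap matches hand-computed cases", {
  u <- letters[1:10]
  res <- hypergeometric_overlap(u[1:5], u[2:5], u)
  expect_equal(res$overlap_size, 4)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  # zero overlap has probability one of being at least matched
  res0 <- hypergeometric_overlap(u[1:3], u[8:10], u)
  expect_equal(res0$p_value, 1)
  # symmetry in the two sets
  r1 <- hypergeometric_overlap(u[1:6], u[4:8], u)
  r2 <- hypergeometric_overlap(u[4:8], u[1:6], u)
  expect_equal(r1$p_value, r2$p_value)
  expect_error(hypergeometric_overlap(c(u[1], "zzz"), u[1:3], u),
               "not a subset")
})

test_that("overlap p-values agree with exhaustive enumeration (spot set)", {
  for (case in list(c(8, 3, 4, 2), c(10, 5, 4, 4), c(12, 6, 6, 3),
                    c(7, 2, 5, 1))) {
    u <- seq_len(case[1]); a <- case[2]; b <- case[3]; k <- case[4]
    set_a <- as.character(seq_len(a))
    set_b <- as.character(seq(a - k + 1, a - k + b))
    res <- hypergeometric_overlap(set_a, set_b, as.character(u))
    expect_equal(res$overlap_size, k)
    expect_equal(res$p_value, oracle_hyper_enum(case[1], a, b, k),
                 tolerance = 1e-12)
  }
})

test_that("filters are monotone in their thresholds", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    tab <- data.frame(gene_id = paste0("g", seq_len(n)),
                      log2fc = rnorm(n, 0, 1.2),
                      padj = runif(n), p = runif(n))
    loose <- filter_degs(tab, padj_max = 0.3, fc_min = 1.2)
    tight <- filter_degs(tab, padj_max = 0.1, fc_min = 1.8)
    expect_true(all(tight %in% loose))
    loose_p <- filter_deps(tab, fc_min = 1.1, alpha = 0.2)
    tight_p <- filter_deps(tab, fc_min = 1.5, alpha = 0.01)
    expect_true(all(tight_p %in% loose_p))
  }
})

test_that("top-k ranking by mean fold change is deterministic", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc_mac = c(2.5, 0.5, -1.5),
                    log2fc_bac = c(1.5, -0.5, -0.5))
  r <- rank_top_migration(tab, tab$gene_id, k = 1)
  expect_equal(r$up$gene_id, "a")
  expect_equal(r$down$gene_id, "c")
  expect_false(r$truncated)
  # permuting rows changes nothing
  r2 <- rank_top_migration(tab[c(3, 1, 2), ], tab$gene_id, k = 1)
  expect_identical(r$up, r2$up)
  # k beyond the table is flagged, everything returned
  r3 <- rank_top_migration(tab, tab$gene_id, k = 10)
  expect_true(r3$truncated)
  expect_equal(nrow(r3$up), 3)
  # ties break lexicographically
  tied <- data.frame(gene_id = c("zz", "aa"), log2fc_mac = c(1, 1),
                     log2fc_bac = c(1, 1))
  rt <- rank_top_migration(tied, tied$gene_id, k = 1)
  expect_equal(rt$up$gene_id, "aa")
})

test_that("a planted top set is returned exactly", {
  set.seed(72)
  n <- 200
  tab <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    log2fc_mac = runif(n, -1, 1),
                    log2fc_bac = runif(n, -1, 1))
  top <- sample(n, 25)
  tab$log2fc_mac[top] <- runif(25, 4, 5)
  tab$log2fc_bac[top] <- runif(25, 4, 5)
  r <- rank_top_migration(tab, tab$gene_id, k = 25)
  expect_setequal(r$up$gene_id, tab$gene_id[top])
})

test_that("gene tables and target lists round-trip through text files", {
  sim <- simulate_gene_table(sim_config(seed = 74))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_gene_table(sim$table, csv)
  back <- read_gene_table(csv)
  expect_equal(back$gene_id, sim$table$gene_id)
  expect_equal(back$log2fc_bac, sim$table$log2fc_bac, tolerance = 1e-12)
  expect_identical(filter_degs(back, log2fc_col = "log2fc_bac",
                               padj_col = "padj_bac"),
                   filter_degs(sim$table, log2fc_col = "log2fc_bac",
                               padj_col = "padj_bac"))
  lst <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# putative targets", sim$targets, ""), lst)
  expect_identical(read_target_list(lst), sim$targets)
})

test_that("overlap operations are pure functions", {
  sim <- simulate_gene_table(sim_config(seed = 73))
  d1 <- filter_degs(sim$table, log2fc_col = "log2fc_bac",
                    padj_col = "padj_bac")
  d2 <- filter_degs(sim$table, log2fc_col = "log2fc_bac",
                    padj_col = "padj_bac")
  expect_identical(d1, d2)
  o1 <- hypergeometric_overlap(d1, sim$targets, sim$universe)
  o2 <- hypergeometric_overlap(d1, sim$targets, sim$universe)
  expect_identical(o1$p_value, o2$p_value)
})
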