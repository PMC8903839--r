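test_that("delta-delta-Ct definitions: fold 1 at ddCt 0, fold 2 per cycle, exact inversion", {
  genes <- c("Sox9", "Col2a")
  groups <- c("ctrl", "tm")
  fc <- matrix(c(1, 1, 3.5, 2), 2, 2, byrow = TRUE,
               dimnames = list(groups, genes))
  tab <- gen_ct_table(genes, groups, fc, ref_gene = "RPL13a", replicates = 4)
  r <- delta_delta_ct(tab, "RPL13a", "ctrl")
  s <- r$summary
  expect_equal(s$mean_fold[s$group == "ctrl"], c(1, 1))
  expect_equal(s$mean_fold[s$gene == "Sox9" & s$group == "tm"], 3.5)
  expect_equal(s$mean_fold[s$gene == "Col2a" & s$group == "tm"], 2)
  # a target Ct exactly one cycle lower than control (ref unchanged) is fold 2
  manual <- data.frame(
    sample = c("c1", "c2", "t1", "t2"),
    group = c("g0", "g0", "g1", "g1"),
    gene = "X", ct = c(20, 20, 19, 19))
  ref <- data.frame(sample = manual$sample, group = manual$group,
                    gene = "H", ct = 15)
  rm2 <- delta_delta_ct(rbind(manual, ref), "H", "g0")
  expect_equal(rm2$summary$mean_fold[rm2$summary$group == "g1"], 2)
})

test_that("plate shifts cancel and label swap inverts folds", {
  genes <- "Sox9"; groups <- c("a", "b")
  fc <- matrix(c(1, 4), 2, 1, dimnames = list(groups, genes))
  tab <- gen_ct_table(genes, groups, fc, replicates = 3,
                      noise = noise_spec(0.2, seed = 2))
  r1 <- delta_delta_ct(tab, "RPL13a", "a")
  # add a per-sample constant (plate shift) to every Ct of some samples
  tab2 <- tab
  shift <- ifelse(tab2$sample %in% c("a_r1", "b_r2"), 1.7, 0)
  tab2$ct <- tab2$ct + shift
  r2 <- delta_delta_ct(tab2, "RPL13a", "a")
  expect_equal(r2$per_replicate$fold, r1$per_replicate$fold, tolerance = 1e-12)
  # swapping control and treatment inverts the summary fold
  r_swap <- delta_delta_ct(tab, "RPL13a", "b")
  f_ab <- r1$summary$mean_fold[r1$summary$group == "b"]
  f_ba <- r_swap$summary$mean_fold[r_swap$summary$group == "a"]
  expect_equal(f_ba, 1 / f_ab, tolerance = 1e-12)
})

test_that("samples without a reference Ct are excluded with a warning", {
  genes <- "Sox9"; groups <- c("a", "b")
  fc <- matrix(c(1, 2), 2, 1, dimnames = list(groups, genes))
  tab <- gen_ct_table(genes, groups, fc, replicates = 3)
  tab <- tab[!(tab$gene == "RPL13a" & tab$sample == "b_r1"), ]
  expect_warning(r <- delta_delta_ct(tab, "RPL13a", "a"), "lacking")
  expect_false("b_r1" %in% r$per_replicate$sample)
})

test_that("Welch comparison matches the hand-computed statistic", {
  # build a table whose per-replicate log2 folds are known exactly:
  # ref Ct constant, so log2 fold = -(ct - mean(ct of control))
  xa <- c(0.3, -0.2, 0.1, 0.4)       # target log2 folds, group a (control-side)
  xb <- c(1.5, 1.1, 1.9, 1.2, 1.6)
  tab <- data.frame(
    sample = c(paste0("a", 1:4), paste0("b", 1:5)),
    group = c(rep("a", 4), rep("b", 5)),
    gene = "G", ct = 20 - c(xa, xb))
  ref <- transform(tab, gene = "H", ct = 15)
  r <- delta_delta_ct(rbind(tab, ref), "H", "a")
  out <- compare_groups(r, "a", "b")
  # independent manual Welch computation on the log2 folds
  la <- xa - mean(xa); lb <- xb - mean(xa)   # ddct-centered values
  se2 <- var(la) / length(la) + var(lb) / length(lb)
  t_manual <- (mean(la) - mean(lb)) / sqrt(se2)
  df_manual <- se2^2 / ((var(la) / length(la))^2 / (length(la) - 1) +
                          (var(lb) / length(lb))^2 / (length(lb) - 1))
  p_manual <- 2 * stats::pt(-abs(t_manual), df_manual)
  expect_equal(out$t, t_manual, tolerance = 1e-4)
  expect_equal(out$df, df_manual, tolerance = 1e-4)
  expect_equal(out$p, p_manual, tolerance = 1e-4)
  expect_true(out$significant)
})

test_that("identical groups are non-significant; degenerate zero-variance case is p = 1", {
  tab <- data.frame(
    sample = paste0("s", 1:6),
    group = rep(c("a", "b"), each = 3),
    gene = "G", ct = rep(20, 6))
  ref <- transform(tab, gene = "H", ct = 15)
  r <- delta_delta_ct(rbind(tab, ref), "H", "a")
  out <- compare_groups(r, "a", "b")
  expect_equal(out$p, 1)
  expect_false(out$significant)
})

test_that("pipeline p-values equal the Welch formula on arbitrary null tables", {
  # the group comparison must reduce exactly to a Welch t-test on the raw
  # delta-Ct values, whatever the noise draw
  genes <- "G"; groups <- c("a", "b")
  fc <- matrix(c(1, 1), 2, 1, dimnames = list(groups, genes))
  for (seed in 1:50) {
    tab <- gen_ct_table(genes, groups, fc, replicates = 5,
                        noise = noise_spec(0.3, seed = seed))
    r <- delta_delta_ct(tab, "RPL13a", "a")
    out <- compare_groups(r, "a", "b")
    dct <- r$per_replicate$dct
    grp <- r$per_replicate$group
    oracle <- stats::t.test(-dct[grp == "a"], -dct[grp == "b"],
                            var.equal = FALSE)$p.value
    expect_equal(out$p, oracle, tolerance = 1e-12)
  }
})

test_that("primer table is complete and efficiencies sit in the valid band", {
  tab <- primer_table()
  expect_setequal(tab$gene, c("RPL13", "Agc", "Twist", "Comp", "SOX9",
                              "COL1A1", "Col2a", "TRPV4"))
  expect_true(all(tab$efficiency_pct >= 80 & tab$efficiency_pct <= 115))
  expect_equal(tab$efficiency_pct[tab$gene == "RPL13"], 96)
  expect_equal(tab$efficiency_pct[tab$gene == "SOX9"], 108)
})
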