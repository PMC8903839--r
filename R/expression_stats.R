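#' qPCR primer reference table
#'
#' The primer set used for the chondrogenic marker panel (reference gene
#' RPL13, targets Agc, Twist, Comp, SOX9, COL1A1, Col2a, TRPV4) with
#' forward/reverse sequences, concentration (ng), amplification efficiency
#' (%), and annealing temperature (degC). Efficiencies are validated
#' against the 80-115 % band; they are stored for reference and for the
#' optional efficiency-corrected quantification mode, but the default
#' analysis is the comparative delta-delta-Ct method, which assumes ~100 %
#' efficiency.
#'
#' @return A data frame with one row per primer pair.
#' @export
primer_table <- function() {
  tab <- data.frame(
    gene = c("RPL13", "Agc", "Twist", "Comp", "SOX9", "COL1A1", "Col2a", "TRPV4"),
    forward = c("TAAACAGGTACTGCTGGGCCG", "GGTACCAGTGCACAGAGGGGTT",
                "AGCAGGGCCGGAGACCTAGATGTCA", "TGCTTCGGGAACTGCAGGAAAC",
                "TGGAAACTTCAGTGGCGCGGA", "CCTGCGTACAGAACGGCCTCA",
                "GGAATTCGGTGTGGACATAGG", "TCCACCCTATATGAGTCCTCG"),
    reverse = c("CTCGGGAAGGGTTGGTGTTC", "TGCAGGTGATCTGAGGCTCCTC",
                "ACGGGCCTGTCTCGCTTTCTCT", "GCACGCGTCACACTCCATCACC",
                "AGAGCAAAAGTGGGGGCGCTT", "CGTCATCGCACAACACCTTGCC",
                "ACTTGGGTCCTTTGGGTTTG", "TAGGTGCCGTAGTCAAACAGT"),
    concentration_ng = c(150, 175, 250, 250, 225, 150, 175, 250),
    efficiency_pct = c(96, 99, 95, 101, 108, 88, 96, 99),
    annealing_degC = c(60, 62, 60, 60, 64, 60, 60, 60),
    stringsAsFactors = FALSE
  )
  bad <- tab$efficiency_pct < 80 | tab$efficiency_pct > 115
  if (any(bad)) {
    warning("primer efficiencies outside the 80-115% band: ",
            paste(tab$gene[bad], collapse = ", "))
  }
  tab
}

#' Comparative delta-delta-Ct fold-change analysis
#'
#' For every sample, `dCt = Ct_target - Ct_ref` (normalization to the
#' reference gene cancels loading/plate shifts); `ddCt = dCt -
#' mean(dCt of the control group)` per gene; per-replicate fold change
#' `2^(-ddCt)`. The summary fold per gene x group is the geometric mean
#' `2^(-mean(ddCt))`, so the control group's summary fold is 1 by
#' construction. Samples missing a reference-gene Ct are excluded with a
#' warning.
#'
#' @param table A `"ct_table"` (see [gen_ct_table()]) or data frame with
#'   columns `sample`, `group`, `gene`, `ct`.
#' @param ref_gene Reference (housekeeping) gene name.
#' @param control_group Label of the control group.
#' @return A `"fold_change_result"`: list with `per_replicate` (sample,
#'   group, gene, dct, ddct, fold) and `summary` (gene, group, mean_fold
#'   (geometric), sd_log2_fold, n).
#' @examples
#' fc <- matrix(c(1, 2), 2, 1, dimnames = list(c("ctrl", "trt"), "Sox9"))
#' tab <- gen_ct_table("Sox9", c("ctrl", "trt"), fc, replicates = 3)
#' delta_delta_ct(tab, "RPL13a", "ctrl")$summary
#' @export
delta_delta_ct <- function(table, ref_gene, control_group) {
  stopifnot(is.data.frame(table),
            all(c("sample", "group", "gene", "ct") %in% names(table)))
  if (!ref_gene %in% table$gene) {
    stop(sprintf("reference gene '%s' absent from the table", ref_gene), call. = FALSE)
  }
  if (!control_group %in% table$group) {
    stop(sprintf("control group '%s' absent from the table", control_group), call. = FALSE)
  }
  if (any(table$ct < 5 | table$ct > 40)) {
    warning("Ct values outside the 5-40 cycle plausibility band")
  }
  ref <- table[table$gene == ref_gene, c("sample", "ct")]
  names(ref)[2] <- "ct_ref"
  if (anyDuplicated(ref$sample)) {
    ref <- stats::aggregate(ct_ref ~ sample, data = ref, FUN = mean)
  }
  tgt <- table[table$gene != ref_gene, , drop = FALSE]
  missing_ref <- !tgt$sample %in% ref$sample
  if (any(missing_ref)) {
    warning(sprintf("excluding %d record(s) lacking a reference-gene Ct: %s",
                    sum(missing_ref),
                    paste(unique(tgt$sample[missing_ref]), collapse = ", ")))
    tgt <- tgt[!missing_ref, , drop = FALSE]
  }
  m <- merge(tgt, ref, by = "sample", sort = FALSE)
  m$dct <- m$ct - m$ct_ref
  ctrl_mean <- stats::aggregate(dct ~ gene, data = m[m$group == control_group, ],
                                FUN = mean)
  names(ctrl_mean)[2] <- "dct_ctrl"
  m <- merge(m, ctrl_mean, by = "gene", sort = FALSE)
  m$ddct <- m$dct - m$dct_ctrl
  m$fold <- 2^(-m$ddct)
  summ <- stats::aggregate(ddct ~ gene + group, data = m, FUN = function(v) {
    c(mean = mean(v), sd = sd(v), n = length(v))
  })
  summary_df <- data.frame(gene = summ$gene, group = summ$group,
                           mean_fold = 2^(-summ$ddct[, "mean"]),
                           sd_log2_fold = summ$ddct[, "sd"],
                           n = as.integer(summ$ddct[, "n"]),
                           stringsAsFactors = FALSE)
  structure(list(
    per_replicate = m[, c("sample", "group", "gene", "ct", "dct", "ddct", "fold")],
    summary = summary_df,
    ref_gene = ref_gene, control_group = control_group
  ), class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("delta-delta-Ct fold changes (ref %s, control '%s'):\n",
              x$ref_gene, x$control_group))
  print(x$summary)
  invisible(x)
}

#' Welch comparison of fold changes between two groups
#'
#' Two-sided Welch (unequal-variance) t-test per gene on the per-replicate
#' log2 fold changes (equivalently on -ddCt), with Welch-Satterthwaite
#' degrees of freedom; a gene is flagged significant when `p < alpha`.
#' Tests run on the log scale because fold changes are multiplicative and
#' log folds are closer to normal. When both groups have zero variance and
#' equal means the comparison is uninformative and `p = 1` by convention.
#' An optional Benjamini-Hochberg adjustment is available but off by
#' default (conventionally, per-gene p < alpha is reported unadjusted).
#'
#' @param result A `"fold_change_result"` from [delta_delta_ct()].
#' @param group_a,group_b Group labels to compare.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame per gene: `t`, `df`, `p`, `p_adj`, `significant`,
#'   and the two group mean log2 folds.
#' @export
compare_groups <- function(result, group_a, group_b, alpha = 0.05,
                           adjust = c("none", "BH")) {
  stopifnot(inherits(result, "fold_change_result"))
  adjust <- match.arg(adjust)
  pr <- result$per_replicate
  for (g in c(group_a, group_b)) {
    if (!g %in% pr$group) stop(sprintf("group '%s' not present", g), call. = FALSE)
  }
  genes <- sort(unique(pr$gene))
  rows <- lapply(genes, function(gene) {
    xa <- log2(pr$fold[pr$gene == gene & pr$group == group_a])
    xb <- log2(pr$fold[pr$gene == gene & pr$group == group_b])
    if (length(xa) < 2 || length(xb) < 2) {
      stop(sprintf("gene %s: need >= 2 replicates per group", gene), call. = FALSE)
    }
    if (var(xa) == 0 && var(xb) == 0) {
      p <- if (mean(xa) == mean(xb)) 1 else 0
      return(data.frame(gene = gene, t = if (p == 1) 0 else Inf, df = NA_real_,
                        p = p, mean_log2_a = mean(xa), mean_log2_b = mean(xb)))
    }
    ht <- stats::t.test(xa, xb, var.equal = FALSE)
    data.frame(gene = gene, t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value, mean_log2_a = mean(xa), mean_log2_b = mean(xb))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- out$p_adj < alpha
  out
}
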