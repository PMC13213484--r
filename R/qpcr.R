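#' Per-sample delta-Ct
#'
#' dCt of the target gene against the mean of the reference genes:
#' `dCt = Ct(target) - mean(Ct(reference genes))`, computed per sample.
#'
#' @param table A qPCR data frame with columns `sample`, `group`, `gene`,
#'   `ct` (e.g. from [simulate_qpcr()] or [read_qpcr_table()]).
#' @param target_gene Target gene name; defaults to the table's
#'   `target_gene` attribute.
#' @param reference_genes Reference gene names; default from the table's
#'   attribute.
#' @return Data frame with one row per sample: `sample`, `group`,
#'   `delta_ct`.
#' @export
#' @examples
#' tb <- simulate_qpcr(3, 0.5, ct_noise_sd = 0)
#' delta_ct(tb)
delta_ct <- function(table, target_gene = NULL, reference_genes = NULL) {
  target_gene <- target_gene %||% attr(table, "target_gene")
  reference_genes <- reference_genes %||% attr(table, "reference_genes")
  stopifnot(!is.null(target_gene), length(reference_genes) >= 1L,
            all(c("sample", "group", "gene", "ct") %in% names(table)))
  if (!all(is.finite(table$ct))) stop("non-finite Ct values", call. = FALSE)
  samples <- unique(table$sample)
  rows <- lapply(samples, function(s) {
    sub <- table[table$sample == s, ]
    tgt <- sub$ct[sub$gene == target_gene]
    if (length(tgt) != 1L) {
      stop("sample ", s, ": expected exactly one Ct for target gene ",
           target_gene, call. = FALSE)
    }
    refs <- vapply(reference_genes, function(g) {
      ct <- sub$ct[sub$gene == g]
      if (!length(ct)) stop("sample ", s, ": missing reference gene ", g,
                            call. = FALSE)
      mean(ct)
    }, numeric(1L))
    data.frame(sample = s, group = sub$group[1L],
               delta_ct = tgt - mean(refs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative expression from delta-Ct values
#'
#' `2^-(ddCt)` with `ddCt = dCt(treatment) - dCt(control)`; the control
#' term is typically the mean dCt of the vehicle-control samples.
#'
#' @param delta_ct_treatment Numeric dCt value(s).
#' @param delta_ct_control Control dCt (scalar reference, e.g. the control
#'   group mean).
#' @return Fold change(s), strictly decreasing in ddCt.
#' @export
#' @examples
#' rel_expression(5, 4)  # 0.5: one extra cycle halves the expression
rel_expression <- function(delta_ct_treatment, delta_ct_control) {
  stopifnot(all(is.finite(delta_ct_treatment)),
            all(is.finite(delta_ct_control)))
  2^(-(delta_ct_treatment - delta_ct_control))
}

#' Geometric mean and geometric SD of fold changes
#'
#' @param x Positive fold changes.
#' @return List with `geo_mean` and `geo_sd` (`exp(mean(log x))` and
#'   `exp(sd(log x))`; `geo_sd` is `NA` for a single value).
#' @export
#' @examples
#' summarize_expression(c(0.5, 2))  # geometric mean 1
summarize_expression <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x) | x <= 0)) {
    stop("fold changes must be positive and finite", call. = FALSE)
  }
  lx <- log(x)
  list(geo_mean = exp(mean(lx)),
       geo_sd = if (length(x) > 1L) exp(sd(lx)) else NA_real_)
}

#' ANOVA with Dunnett many-to-one comparisons on delta-Ct values
#'
#' One-way ANOVA over treatment groups followed by Dunnett's post-hoc test
#' of every treatment against the control, performed on the dCt scale.
#' Adjusted p-values come from the multivariate-t distribution of the
#' comparison statistics.
#'
#' @param dct Data frame with columns `group` and `delta_ct` (as returned
#'   by [delta_ct()]).
#' @param control Name of the control group.
#' @return List with `anova_f`, `anova_p`, and `comparisons`: a data frame
#'   (`group`, `estimate`, `p_adjusted`) of each treatment vs control.
#' @export
test_vs_control <- function(dct, control = "control") {
  stopifnot(all(c("group", "delta_ct") %in% names(dct)))
  if (!control %in% dct$group) stop("control group '", control,
                                    "' not present", call. = FALSE)
  counts <- table(dct$group)
  if (length(counts) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(counts < 2L)) {
    stop("every group needs >= 2 replicates (",
         paste(names(counts)[counts < 2L], collapse = ", "), ")",
         call. = FALSE)
  }
  dct$group <- stats::relevel(factor(dct$group), ref = control)
  if (all(tapply(dct$delta_ct, dct$group, stats::var) == 0)) {
    # degenerate: zero within-group variance; identical groups get p = 1,
    # exactly separated ones p = 0
    grand <- tapply(dct$delta_ct, dct$group, mean)
    trt <- setdiff(levels(dct$group), control)
    est <- grand[trt] - grand[control]
    sep <- any(est != 0)
    return(list(anova_f = if (sep) Inf else 0, anova_p = if (sep) 0 else 1,
                comparisons = data.frame(group = trt,
                                         estimate = unname(est),
                                         p_adjusted = ifelse(est == 0, 1, 0),
                                         stringsAsFactors = FALSE)))
  }
  fit <- aov(delta_ct ~ group, data = dct)
  an <- summary(fit)[[1L]]
  dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett")))
  cmp <- data.frame(
    group = sub(" - .*$", "", names(dn$test$coefficients)),
    estimate = as.numeric(dn$test$coefficients),
    p_adjusted = as.numeric(dn$test$pvalues),
    stringsAsFactors = FALSE
  )
  list(anova_f = an[["F value"]][1L], anova_p = an[["Pr(>F)"]][1L],
       comparisons = cmp)
}

#' Full relative-expression analysis of a qPCR table
#'
#' Runs the 2^-ddCt workflow: per-sample dCt against the reference-gene
#' mean, ddCt against the mean dCt of the control group, per-sample fold
#' changes, geometric mean / geometric SD per group, and ANOVA + Dunnett
#' testing on the dCt scale.
#'
#' @param table qPCR data frame (see [delta_ct()]).
#' @param target_gene,reference_genes Gene designation; defaults from the
#'   table's attributes.
#' @param control_group Control group name; defaults from the table's
#'   attribute, else `"control"`.
#' @return List of class `qpcr_analysis` with `delta_ct` (per-sample table
#'   including `rel_expression`), `summary` (per-group geometric mean/SD),
#'   and `tests` (from [test_vs_control()]; `NULL` if any group has a
#'   single replicate).
#' @export
#' @examples
#' analyze_qpcr(simulate_qpcr(3, 0.75, ct_noise_sd = 0))$summary
analyze_qpcr <- function(table, target_gene = NULL, reference_genes = NULL,
                         control_group = NULL) {
  control_group <- control_group %||% attr(table, "control_group") %||%
    "control"
  dct <- delta_ct(table, target_gene, reference_genes)
  if (!control_group %in% dct$group) {
    stop("control group '", control_group, "' not present", call. = FALSE)
  }
  ctrl_mean <- mean(dct$delta_ct[dct$group == control_group])
  dct$rel_expression <- rel_expression(dct$delta_ct, ctrl_mean)
  groups <- unique(dct$group)
  summ <- do.call(rbind, lapply(groups, function(g) {
    s <- summarize_expression(dct$rel_expression[dct$group == g])
    data.frame(group = g, n = sum(dct$group == g), geo_mean = s$geo_mean,
               geo_sd = s$geo_sd, stringsAsFactors = FALSE)
  }))
  tests <- if (all(table(dct$group) >= 2L) && length(groups) >= 2L) {
    test_vs_control(dct, control = control_group)
  } else NULL
  structure(list(delta_ct = dct, summary = summ, tests = tests,
                 control_group = control_group),
            class = "qpcr_analysis")
}

#' @export
print.qpcr_analysis <- function(x, ...) {
  cat("<qpcr_analysis> control =", x$control_group, "\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat(sprintf("ANOVA F = %.3g (p = %.3g); Dunnett vs control:\n",
                x$tests$anova_f, x$tests$anova_p))
    print(x$tests$comparisons, row.names = FALSE)
  }
  invisible(x)
}
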