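#' Per-trait descriptive statistics
#'
#' Line-level values are the replicate means (when a `rep_id` column is
#' present); mean, SD, min and max are then taken over lines.
#'
#' @param table phenotype data.frame with `line_id`, optional `rep_id`, and
#'   one numeric column per trait.
#' @return data.frame with columns `trait`, `mean`, `sd`, `min`, `max`,
#'   `n_lines`.
#' @export
descriptive_stats <- function(table) {
  traits <- trait_columns(table)
  line_means <- line_mean_table(table, traits)
  out <- do.call(rbind, lapply(traits, function(tr) {
    v <- line_means[[tr]]
    v <- v[!is.na(v)]
    if (!length(v)) stop(sprintf("trait '%s' has no observations", tr))
    data.frame(trait = tr, mean = mean(v), sd = sd(v),
               min = min(v), max = max(v), n_lines = length(v))
  }))
  rownames(out) <- NULL
  out
}

trait_columns <- function(table) {
  traits <- setdiff(names(table), c("line_id", "rep_id"))
  if (!length(traits)) stop("no trait columns found")
  for (tr in traits) {
    if (!is.numeric(table[[tr]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(table[[tr]]))) &
                     !is.na(table[[tr]]))[1]
      stop(sprintf("non-numeric entry in trait '%s' (row %s)", tr,
                   bad %||% "?"))
    }
  }
  traits
}

line_mean_table <- function(table, traits = trait_columns(table)) {
  if (!"rep_id" %in% names(table)) return(table[, c("line_id", traits)])
  agg <- stats::aggregate(table[traits], by = list(line_id = table$line_id),
                          FUN = mean, na.rm = TRUE)
  agg
}

#' Pairwise Pearson correlations between traits
#'
#' Correlations are computed on line means with pairwise-complete
#' observations; two-sided significance comes from the t-distribution test
#' on r, flagged at the 0.05 and 0.01 levels. Zero-variance traits yield
#' `NA` correlations (flagged, not an error).
#'
#' @param table phenotype data.frame (see [descriptive_stats()]).
#' @return list of class `trait_correlations` with matrices `r`, `p_value`,
#'   and logical `sig05`, `sig01`.
#' @export
trait_correlations <- function(table) {
  traits <- trait_columns(table)
  lm_tab <- line_mean_table(table, traits)
  if (nrow(lm_tab) < 3) stop("need at least 3 lines for correlations")
  k <- length(traits)
  r <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  p <- r
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- lm_tab[[traits[i]]]; y <- lm_tab[[traits[j]]]
      ok <- complete.cases(x, y)
      if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
        ct <- cor.test(x[ok], y[ok])
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p_value = p,
                 sig05 = !is.na(p) & p < 0.05,
                 sig01 = !is.na(p) & p < 0.01),
            class = "trait_correlations")
}

#' Narrow-sense heritability from variance components
#'
#' The printed convention for replicated inbred trials:
#' h2 = sigma2_g / (sigma2_g + sigma2_e), the ratio of the line (genetic)
#' variance to the total of line plus residual variance.
#'
#' @param genetic_var genetic variance component.
#' @param residual_var residual variance component.
#' @return heritability in \[0,1\].
#' @export
heritability <- function(genetic_var, residual_var) {
  genetic_var / (genetic_var + residual_var)
}

#' REML variance components and heritability for one trait
#'
#' Fits the one-way random-effects model y_ij = mu + g_i + e_ij by REML
#' (lines random; an optional fixed replicate/block effect) and returns the
#' genetic and residual variance components, heritability
#' h2 = sigma2_g/(sigma2_g + sigma2_e), and the ANOVA variance-ratio
#' F = MS_line / MS_error. Negative REML components are truncated at zero
#' by the fitter.
#'
#' @param table phenotype data.frame with replicate-level rows (`line_id`,
#'   `rep_id`, trait columns).
#' @param trait name of the trait column (default: the single trait
#'   present).
#' @param block_fixed include `rep_id` as a fixed block effect (default
#'   FALSE).
#' @return list of class `variance_components` with `genetic_var`,
#'   `residual_var`, `h2`, `f_value`, `f_p_value`, `n_lines`, `n_obs`.
#' @export
reml_variance_components <- function(table, trait = NULL, block_fixed = FALSE) {
  traits <- trait_columns(table)
  if (is.null(trait)) {
    if (length(traits) > 1) stop("multiple traits present; name one")
    trait <- traits
  }
  df <- data.frame(line_id = factor(table$line_id),
                   y = table[[trait]])
  if ("rep_id" %in% names(table)) df$rep_id <- factor(table$rep_id)
  df <- df[!is.na(df$y), , drop = FALSE]
  reps_per_line <- table(df$line_id)
  if (sum(reps_per_line >= 2) < 2) {
    stop("need >= 2 replicates for >= 2 lines to separate the residual variance")
  }
  form <- if (block_fixed && "rep_id" %in% names(df)) {
    y ~ rep_id + (1 | line_id)
  } else {
    y ~ (1 | line_id)
  }
  fit <- lme4::lmer(form, data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vg <- vc$vcov[vc$grp == "line_id"]
  ve <- vc$vcov[vc$grp == "Residual"]
  aform <- if (block_fixed && "rep_id" %in% names(df)) {
    y ~ rep_id + line_id
  } else {
    y ~ line_id
  }
  at <- anova(stats::lm(aform, data = df))
  fv <- at["line_id", "Mean Sq"] / at["Residuals", "Mean Sq"]
  structure(list(genetic_var = vg, residual_var = ve,
                 h2 = heritability(vg, ve),
                 f_value = fv,
                 f_p_value = at["line_id", "Pr(>F)"],
                 n_lines = nlevels(df$line_id), n_obs = nrow(df)),
            class = "variance_components")
}

#' Heritability summary table for all traits
#'
#' Convenience wrapper producing one row per trait with descriptive
#' statistics, REML variance components, heritability and the ANOVA F.
#'
#' @inheritParams reml_variance_components
#' @return data.frame with columns `trait`, `mean`, `sd`, `min`, `max`,
#'   `genetic_var`, `residual_var`, `h2`, `f_value`.
#' @export
heritability_table <- function(table, block_fixed = FALSE) {
  stats_tab <- descriptive_stats(table)
  rows <- lapply(stats_tab$trait, function(tr) {
    vc <- reml_variance_components(table, trait = tr,
                                   block_fixed = block_fixed)
    data.frame(genetic_var = vc$genetic_var, residual_var = vc$residual_var,
               h2 = vc$h2, f_value = vc$f_value)
  })
  cbind(stats_tab[, c("trait", "mean", "sd", "min", "max")],
        do.call(rbind, rows))
}
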