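#' Mixed-model likelihood-ratio trend test
#'
#' Tests whether a movement statistic responds to the systematically
#' manipulated variable of an experiment protocol.  The response is
#' modelled as a linear mixed model with the predictor's levels as a
#' categorical fixed effect and the simulation run (environment) as a
#' random intercept; the full model is compared with the null model
#' lacking the predictor by a likelihood-ratio test.  Both models are fit
#' by maximum likelihood (not REML), as required for a valid LRT on fixed
#' effects.  When the LRT is significant at `alpha`, all-pairs Tukey-style
#' post-hoc comparisons (single-step multivariate-t adjustment via
#' \pkg{multcomp}) explore the shape of the relationship; if that
#' adjustment fails numerically, Holm-adjusted Wald comparisons are used
#' and flagged in `posthoc_method`.
#'
#' @param table Results data frame (e.g. from [run_model1()]).
#' @param response Column name of the movement statistic
#'   (`"max_distance"`, `"n_switches"` or `"prop_wild"`).
#' @param predictor Column name of the manipulated variable (e.g.
#'   `"p_F"`, `"r"`, `"n_setasides"`, `"n_hedges_removed"`); treated as
#'   categorical.
#' @param run Column identifying the simulation run (random factor).
#' @param alpha Significance level gating the post-hoc tests.
#' @return An object of class `hw_trend_test`: list with `response`,
#'   `predictor`, `chi_square`, `df`, `p_value`, `posthoc` (data frame of
#'   pairwise contrasts, `NULL` when not computed), `posthoc_method`, and
#'   `degenerate` (TRUE when the response had no variance, reported as
#'   chi-square 0).
#' @examples
#' m1 <- run_model1(n_env = 8, width = 150, height = 150,
#'                  n_fields_range = c(20, 30), T = 300, seed = 2)
#' fit_trend_test(m1, "max_distance", "p_F")
#' @export
fit_trend_test <- function(table, response, predictor, run = "env",
                           alpha = 0.05) {
  df <- as.data.frame(table)
  for (col in c(response, predictor, run))
    if (!col %in% names(df)) stop("column `", col, "` not found in table")
  dat <- data.frame(y = df[[response]],
                    level = factor(df[[predictor]]),
                    run = factor(df[[run]]))
  k <- nlevels(dat$level)
  if (k < 2L) stop("predictor must have at least 2 levels")
  if (nlevels(dat$run) < 2L) stop("need at least 2 runs")
  out <- list(response = response, predictor = predictor,
              df = k - 1L, posthoc = NULL, posthoc_method = "none",
              degenerate = FALSE)
  if (stats::var(dat$y) == 0) {
    out$chi_square <- 0
    out$p_value <- 1
    out$degenerate <- TRUE
    class(out) <- "hw_trend_test"
    return(out)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(y ~ level + (1 | run), data = dat, REML = FALSE,
                     control = ctrl)
  null <- lme4::lmer(y ~ 1 + (1 | run), data = dat, REML = FALSE,
                     control = ctrl)
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(null))))
  out$chi_square <- chi2
  out$p_value <- stats::pchisq(chi2, df = k - 1L, lower.tail = FALSE)
  if (out$p_value < alpha) {
    ph <- tryCatch(tukey_posthoc(full), error = function(e) NULL)
    if (!is.null(ph)) {
      out$posthoc <- ph
      out$posthoc_method <- "single-step multivariate-t (Tukey)"
    } else {
      out$posthoc <- holm_posthoc(full, dat)
      out$posthoc_method <- "Holm-adjusted Wald"
    }
  }
  class(out) <- "hw_trend_test"
  out
}

tukey_posthoc <- function(full) {
  glht <- multcomp::glht(full, linfct = multcomp::mcp(level = "Tukey"))
  # the multivariate-t integration reports reduced accuracy for large
  # contrast sets; 1e-3 absolute error is ample for a 0.05 gate
  sm <- suppressWarnings(summary(glht))
  data.frame(contrast = names(sm$test$coefficients),
             estimate = as.numeric(sm$test$coefficients),
             se = as.numeric(sm$test$sigma),
             z = as.numeric(sm$test$tstat),
             p_adj = as.numeric(sm$test$pvalues),
             row.names = NULL)
}

# Fallback all-pairs comparisons from the fixed-effect estimates with
# Holm familywise adjustment.
holm_posthoc <- function(full, dat) {
  beta <- lme4::fixef(full)
  V <- as.matrix(stats::vcov(full))
  levs <- levels(dat$level)
  k <- length(levs)
  # cell means: intercept + level coefficients (treatment coding)
  L <- cbind(1, rbind(0, diag(k - 1L)))
  pairs <- utils::combn(k, 2L)
  est <- se <- numeric(ncol(pairs))
  lab <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    cvec <- L[pairs[2L, j], ] - L[pairs[1L, j], ]
    est[j] <- sum(cvec * beta)
    se[j] <- sqrt(drop(t(cvec) %*% V %*% cvec))
    lab[j] <- paste(levs[pairs[2L, j]], "-", levs[pairs[1L, j]])
  }
  z <- est / se
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = "holm")
  data.frame(contrast = lab, estimate = est, se = se, z = z, p_adj = p)
}

#' @export
print.hw_trend_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio trend test: %s ~ %s (run random factor)\n",
              x$response, x$predictor))
  cat(sprintf("  chi-square(%d) = %.2f, p = %s%s\n", x$df, x$chi_square,
              format.pval(x$p_value, digits = 3),
              if (x$degenerate) "  [degenerate: response constant]" else ""))
  if (!is.null(x$posthoc)) {
    cat(sprintf("  post-hoc (%s): %d of %d pairs significant at 0.05\n",
                x$posthoc_method, sum(x$posthoc$p_adj < 0.05),
                nrow(x$posthoc)))
  }
  invisible(x)
}

#' Direction-of-effect summary of a trend test
#'
#' Condenses a fitted trend test into the arrow notation used for
#' overview tables: the direction is the sign of the fitted difference
#' between the highest and lowest predictor level, and the strength is
#' the fraction of post-hoc pairs that reach significance.  `"up2"` /
#' `"down2"` (printed as a doubled arrow) mark a strong trend with most
#' pairwise comparisons significant; `"up"` / `"down"` a moderate one
#' with some pairs significant; `"extreme"` an effect confined to one end
#' of the range (only contrasts involving an extreme level are
#' significant); `"none"` no significant pattern.  The underlying
#' contrast pattern is always returned so the verbal classification can
#' be checked.
#'
#' @param test An `hw_trend_test` with post-hoc results.
#' @param strong Fraction of significant pairs at or above which a trend
#'   is called strong.
#' @return List with `arrow`, `direction`, `frac_significant`,
#'   `n_pairs`, and the post-hoc table.
#' @export
trend_summary <- function(test, strong = 2 / 3) {
  stopifnot(inherits(test, "hw_trend_test"))
  ph <- test$posthoc
  if (is.null(ph) || test$p_value >= 0.05)
    return(list(arrow = "none", direction = 0, frac_significant = 0,
                n_pairs = if (is.null(ph)) 0L else nrow(ph),
                posthoc = ph))
  sig <- ph$p_adj < 0.05
  frac <- mean(sig)
  parts <- do.call(rbind, strsplit(ph$contrast, " - ", fixed = TRUE))
  levs <- unique(as.vector(parts))
  num <- suppressWarnings(as.numeric(levs))
  if (!anyNA(num)) levs <- levs[order(num)]
  extreme <- levs[c(1L, length(levs))]
  touches_extreme <- parts[, 1L] %in% extreme | parts[, 2L] %in% extreme
  # the (highest level - lowest level) contrast sets the direction
  span_row <- which(parts[, 1L] %in% extreme & parts[, 2L] %in% extreme)
  span <- ph$estimate[nrow(ph)]
  flip <- 1
  if (length(span_row)) {
    span <- ph$estimate[span_row[1L]]
    if (parts[span_row[1L], 1L] == extreme[1L]) flip <- -1
  }
  direction <- sign(span) * flip
  arrow <- if (!any(sig)) "none"
           else if (all(which(sig) %in% which(touches_extreme)) && frac <= 0.25)
             "extreme"
           else if (frac >= strong) if (direction > 0) "up2" else "down2"
           else if (direction > 0) "up" else "down"
  list(arrow = arrow, direction = direction, frac_significant = frac,
       n_pairs = nrow(ph), posthoc = ph)
}
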